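#' Read a TPR-DB-style per-token table
#'
#' Tab-separated, UTF-8, header row, \code{"NA"} for missing values. Every
#' column is read as character so that reading and rewriting an untouched
#' table is byte-preserving; numeric interpretation happens at use sites.
#' Expected identifying columns: \code{participant}, \code{sent_id} and
#' \code{word_id} (0-based token position within its sentence); typical
#' further columns are \code{token}, \code{text_id}, \code{STid} (running
#' token number in the text) and an optional frequency covariate.
#'
#' @param path file path
#' @return data.frame of character columns
#' @export
readTokenTable <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                    na.strings = "NA", check.names = FALSE,
                    encoding = "UTF-8")
}

#' Write a per-token table
#'
#' @param table data.frame
#' @param path file path (TSV, UTF-8, \code{"NA"} for missing)
#' @export
writeTokenTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
}

#' Read per-sentence bundles from a JSON-lines file
#'
#' One JSON object per line describes one source sentence and its aligned
#' translations:
#' \preformatted{
#' {"sent_id": "s1",
#'  "source": ["they", "are", ...],
#'  "src_conllu": "1\tthey\t...\n2\t...",        # optional
#'  "versions": [
#'     {"translator": "P01",
#'      "target": ["ze", ...],
#'      "alignment": "0-0 1-1 ...",               # Pharaoh, 0-based
#'      "tgt_conllu": "..."}                      # optional
#'  ]}
#' }
#'
#' @param path file path (or character vector of lines with \code{text = TRUE})
#' @param text interpret \code{path} as the lines themselves
#' @return named list of bundles keyed by \code{sent_id}; each bundle holds
#'   \code{source}, \code{pairs} (named list of \linkS4class{SentencePair}
#'   per translator), \code{srcTree} (\linkS4class{DepTree} or NULL) and
#'   \code{tgtTrees} (named list per translator)
#' @export
readBundles <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    b <- jsonlite::fromJSON(ln, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
    if (is.null(b$sent_id) || is.null(b$source) || is.null(b$versions))
      stop("bundle line missing sent_id, source or versions", call. = FALSE)
    src <- as.character(b$source)
    pairs <- list(); tgtTrees <- list()
    for (v in b$versions) {
      id <- as.character(v$translator)
      pairs[[id]] <- sentencePair(src, as.character(v$target),
                                  if (is.null(v$alignment)) "" else
                                    v$alignment)
      if (!is.null(v$tgt_conllu))
        tgtTrees[[id]] <- readConllu(strsplit(v$tgt_conllu, "\n")[[1]],
                                     text = TRUE)[[1]]
    }
    srcTree <- if (!is.null(b$src_conllu))
      readConllu(strsplit(b$src_conllu, "\n")[[1]], text = TRUE)[[1]]
    out[[as.character(b$sent_id)]] <-
      list(source = src, pairs = pairs, srcTree = srcTree,
           tgtTrees = tgtTrees)
  }
  out
}

metricColumns <- c("cross", "abs_cross", "word_cross", "seq_cross",
                   "astred_change", "htra", "hcross", "hstc")

#' Augment a per-token table with all product metrics
#'
#' Adds the columns \code{cross}, \code{abs_cross}, \code{word_cross},
#' \code{seq_cross}, \code{astred_change}, \code{htra}, \code{hcross} and
#' \code{hstc} to a per-token table. Single-translation metrics are
#' computed from the sentence pair of the row's own participant (rows whose
#' participant has no version in the bundle get \code{NA}); the entropy
#' metrics are computed once per sentence over all versions in the bundle.
#' Rows of tokens that are unaligned in the relevant version get \code{NA}.
#' Existing columns are never silently overwritten.
#'
#' @param table data.frame from [readTokenTable()] with columns
#'   \code{participant}, \code{sent_id}, \code{word_id}
#' @param bundles named list from [readBundles()] (or built in code), keyed
#'   by \code{sent_id}
#' @param force overwrite pre-existing metric columns
#' @return the table with the eight metric columns appended; row order is
#'   preserved
#' @export
augmentTable <- function(table, bundles, force = FALSE) {
  need <- c("participant", "sent_id", "word_id")
  missingCols <- setdiff(need, names(table))
  if (length(missingCols) > 0)
    stop("table lacks required column(s): ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  collide <- intersect(metricColumns, names(table))
  if (length(collide) > 0) {
    if (!force)
      stop("column(s) already present (use force = TRUE to overwrite): ",
           paste(collide, collapse = ", "), call. = FALSE)
    table <- table[, setdiff(names(table), collide), drop = FALSE]
  }
  sentIds <- unique(as.character(table$sent_id))
  absent <- setdiff(sentIds, names(bundles))
  if (length(absent) > 0)
    stop("no bundle for sentence id(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  n <- nrow(table)
  newCols <- data.frame(cross = rep(NA_integer_, n), abs_cross = NA_integer_,
                        word_cross = NA_integer_, seq_cross = NA_integer_,
                        astred_change = NA, htra = NA_real_,
                        hcross = NA_real_, hstc = NA_real_)
  for (sid in sentIds) {
    b <- bundles[[sid]]
    rows <- which(as.character(table$sent_id) == sid)
    wid <- as.integer(table$word_id[rows])
    ent <- if (length(b$pairs) >= 2)
      entropyProfile(translationEnsemble(b$source, b$pairs))
    for (r in seq_along(rows)) {
      row <- rows[r]; i <- wid[r]
      if (is.na(i) || i < 0 || i >= length(b$source))
        stop("word_id out of range for sentence ", sid, call. = FALSE)
      if (!is.null(ent)) {
        newCols$htra[row] <- ent$htra[i + 1L]
        newCols$hcross[row] <- ent$hcross[i + 1L]
        newCols$hstc[row] <- ent$hstc[i + 1L]
      }
      p <- as.character(table$participant[row])
      pair <- b$pairs[[p]]
      if (is.null(pair)) next
      cv <- crossValues(pair)
      newCols$cross[row] <- cv$cross[i + 1L]
      newCols$abs_cross[row] <- cv$abs_cross[i + 1L]
      newCols$word_cross[row] <- wordCross(pair)[i + 1L]
      newCols$seq_cross[row] <- seqCross(pair)[i + 1L]
      if (!is.null(b$srcTree) && !is.null(b$tgtTrees[[p]])) {
        ac <- astredChange(pair, b$srcTree, b$tgtTrees[[p]])
        newCols$astred_change[row] <- ac$astred_change[i + 1L]
      }
    }
  }
  out <- cbind(table, newCols)
  rownames(out) <- NULL
  out
}

#' Per-token reordering metrics of a single pair
#'
#' @param pair a \linkS4class{SentencePair}
#' @return data.frame with \code{token_index}, \code{token}, \code{cross},
#'   \code{abs_cross}, \code{word_cross}, \code{seq_cross}
#' @export
reorderingProfile <- function(pair) {
  cv <- crossValues(pair)
  data.frame(token_index = cv$token_index, token = pair@source,
             cross = cv$cross, abs_cross = cv$abs_cross,
             word_cross = wordCross(pair), seq_cross = seqCross(pair))
}
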