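#' Parse a Pharaoh-style word alignment
#'
#' Reads the whitespace-separated \code{"i-j"} dialect used by word-alignment
#' tools and TPR-DB exports: \code{i} is a 0-based source token index,
#' \code{j} a 0-based target token index. Duplicate pairs are collapsed (the
#' alignment is a set) and the result is ordered by source then target index.
#'
#' @param text character scalar of whitespace-separated \code{"i-j"} pairs;
#'   the empty string denotes an empty (legal) alignment
#' @param nSrc,nTgt number of source / target tokens, for range checking
#' @return integer matrix with columns \code{src}, \code{tgt}; zero rows for
#'   an empty alignment
#' @examples
#' parsePharaoh("0-0 1-1", 2, 2)
#' parsePharaoh("", 3, 3)
#' @export
parsePharaoh <- function(text, nSrc, nTgt) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0)
    return(emptyLinks())
  parts <- regmatches(toks, regexec("^([0-9]+)-([0-9]+)$", toks))
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad))
    stop("malformed alignment pair(s): ",
         paste(toks[bad], collapse = ", "), call. = FALSE)
  src <- as.integer(vapply(parts, `[`, "", 2L))
  tgt <- as.integer(vapply(parts, `[`, "", 3L))
  oob <- src >= nSrc | tgt >= nTgt
  if (any(oob))
    stop("alignment pair(s) out of range: ",
         paste(toks[oob], collapse = ", "),
         sprintf(" (sentence is %d x %d)", nSrc, nTgt), call. = FALSE)
  canonicalLinks(cbind(src = src, tgt = tgt))
}

#' Serialize links back to Pharaoh format
#'
#' Inverse of [parsePharaoh()] on canonical (sorted, deduplicated) link sets.
#'
#' @param links integer link matrix with columns \code{src}, \code{tgt}
#' @return character scalar, \code{""} for an empty alignment
#' @export
serializePharaoh <- function(links) {
  links <- canonicalLinks(links)
  if (nrow(links) == 0) return("")
  paste(sprintf("%d-%d", links[, "src"], links[, "tgt"]), collapse = " ")
}

emptyLinks <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("src", "tgt")))
}

# sort by (src, tgt), drop duplicates: links form a set
canonicalLinks <- function(links) {
  if (is.null(links) || length(links) == 0) return(emptyLinks())
  links <- matrix(as.integer(links), ncol = 2,
                  dimnames = list(NULL, c("src", "tgt")))
  links <- unique(links)
  links[order(links[, 1], links[, 2]), , drop = FALSE]
}

#' Construct a SentencePair
#'
#' @param source,target character vectors of tokens (pre-tokenized; no
#'   tokenizer is shipped)
#' @param alignment either a Pharaoh string (\code{"0-0 1-2 ..."}, 0-based)
#'   or a two-column integer matrix of (src, tgt) indices
#' @return a validated \linkS4class{SentencePair}
#' @examples
#' sentencePair(c("a", "b"), c("x", "y"), "0-1 1-0")
#' @export
sentencePair <- function(source, target, alignment = "") {
  links <- if (is.character(alignment)) {
    parsePharaoh(alignment, length(source), length(target))
  } else {
    canonicalLinks(alignment)
  }
  new("SentencePair", source = as.character(source),
      target = as.character(target), links = links)
}

#' Diagnose invariant violations of a sentence pair
#'
#' Returns diagnostics instead of throwing: one message per violation
#' (out-of-range link endpoint, duplicate link, empty token form). An empty
#' character vector means the pair is valid.
#'
#' @param pair a \linkS4class{SentencePair} (or an object shaped like one)
#' @return character vector of diagnostics, empty if all invariants hold
#' @export
validatePair <- function(pair) {
  msgs <- character(0)
  src <- pair@source; tgt <- pair@target; links <- pair@links
  if (!is.matrix(links) || ncol(links) != 2)
    return("links must be a two-column matrix")
  if (length(src) > 0 && any(!nzchar(src)))
    msgs <- c(msgs, sprintf("empty source token at position %s",
      paste(which(!nzchar(src)) - 1L, collapse = ", ")))
  if (length(tgt) > 0 && any(!nzchar(tgt)))
    msgs <- c(msgs, sprintf("empty target token at position %s",
      paste(which(!nzchar(tgt)) - 1L, collapse = ", ")))
  if (nrow(links) > 0) {
    oob <- links[, 1] < 0 | links[, 1] >= length(src) |
           links[, 2] < 0 | links[, 2] >= length(tgt)
    if (any(oob))
      msgs <- c(msgs, sprintf("link out of range: %s",
        paste(sprintf("%d-%d", links[oob, 1], links[oob, 2]),
              collapse = ", ")))
    if (anyDuplicated(links))
      msgs <- c(msgs, "duplicate alignment links")
  }
  msgs
}

# incident target indices of a source token (0-based in, 0-based out)
targetsOf <- function(pair, i) {
  sort(pair@links[pair@links[, "src"] == i, "tgt"])
}

sourcesOf <- function(pair, j) {
  sort(pair@links[pair@links[, "tgt"] == j, "src"])
}
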