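#' Signed relative reordering (Cross) per source token
#'
#' Cross quantifies the reordering of a word's translation relative to the
#' position of the previous word's translation. Walking the source tokens
#' left to right, each aligned token points at the 1-based position of its
#' leftmost aligned target token; its Cross value is that position minus the
#' position pointed at by the previous aligned source token (0 before the
#' first). Positive values mean the translation is placed after the previous
#' one, negative values before it. In an absolutely literal translation —
#' monotone and one-to-one — every word has a Cross value of 1. Unaligned
#' tokens have no Cross value (\code{NA}).
#'
#' @param pair a \linkS4class{SentencePair}
#' @return data.frame with columns \code{token_index} (0-based),
#'   \code{cross} (signed integer or \code{NA}) and \code{abs_cross}
#' @examples
#' p <- sentencePair(c("a","b","c"), c("x","y","z"), "0-0 1-1 2-2")
#' crossValues(p)$cross  # 1 1 1
#' @export
crossValues <- function(pair) {
  stopIfInvalid(pair)
  n <- length(pair@source)
  cross <- rep(NA_integer_, n)
  p <- 0L
  for (i in seq_len(n) - 1L) {
    tg <- targetsOf(pair, i)
    if (length(tg) == 0) next
    t1 <- min(tg) + 1L           # 1-based leftmost aligned target
    cross[i + 1L] <- t1 - p
    p <- t1
  }
  data.frame(token_index = seq_len(n) - 1L, cross = cross,
             abs_cross = abs(cross))
}

# crossing test: links (i,j) and (i',j') cross iff source order is inverted
# on the target side, i.e. (i - i') * (j - j') < 0
linkCrossMatrix <- function(links) {
  L <- nrow(links)
  if (L == 0) return(matrix(logical(0), 0, 0))
  di <- outer(links[, "src"], links[, "src"], "-")
  dj <- outer(links[, "tgt"], links[, "tgt"], "-")
  di * dj < 0
}

#' Word-level alignment crossings (word_cross)
#'
#' The number of times an alignment link of a word crosses the alignment
#' link of any other word in the sentence pair; two links cross when the
#' order of the source words is inverted on the target side. A token aligned
#' to several words sums the crossing counts of its incident links; an
#' unaligned token has no value (\code{NA}).
#'
#' @param pair a \linkS4class{SentencePair}
#' @param side \code{"source"} (default) or \code{"target"}: which side's
#'   tokens to report
#' @return integer vector, one entry per token of the chosen side
#' @examples
#' swap <- sentencePair(c("a","b"), c("x","y"), "0-1 1-0")
#' wordCross(swap)  # 1 1
#' @export
wordCross <- function(pair, side = c("source", "target")) {
  side <- match.arg(side)
  stopIfInvalid(pair)
  links <- pair@links
  n <- if (side == "source") length(pair@source) else length(pair@target)
  out <- rep(NA_integer_, n)
  if (nrow(links) == 0) return(out)
  perLink <- rowSums(linkCrossMatrix(links))
  col <- if (side == "source") "src" else "tgt"
  for (i in seq_len(n) - 1L) {
    inc <- links[, col] == i
    if (any(inc)) out[i + 1L] <- as.integer(sum(perLink[inc]))
  }
  out
}

#' Build sequence groups (aligned word groups) for a sentence pair
#'
#' Partitions the aligned tokens into maximal word groups used by
#' [seqCross()]. A candidate group is a contiguous source span together with
#' a contiguous target span such that (a) no member aligns outside the group
#' (phrase consistency), (b) every member token is aligned, and (c) the
#' internal alignment is either monotone one-to-one, or — the multi-word
#' group (MWG) alternative — fully bipartite: every source member is aligned
#' with every target member. Groups are grown greedily left to right,
#' preferring larger source spans, so the output is deterministic. An
#' aligned token that fits no such group becomes a singleton group carrying
#' its original word-alignment links.
#'
#' @param pair a \linkS4class{SentencePair}
#' @return list of groups; each group is a list with \code{srcSpan} and
#'   \code{tgtSpan} (0-based integer vectors), \code{kind} (\code{"singleton"},
#'   \code{"contiguous"} or \code{"mwg"}) and \code{groupLinks} (an integer
#'   link matrix at group level: one representative link for contiguous/MWG
#'   groups, the word's own links for singletons)
#' @export
buildSequenceGroups <- function(pair) {
  stopIfInvalid(pair)
  links <- pair@links
  nSrc <- length(pair@source)
  groups <- list()
  i <- 0L
  while (i < nSrc) {
    if (length(targetsOf(pair, i)) == 0) { i <- i + 1L; next }
    found <- NULL
    for (b in (nSrc - 1L):i) {
      g <- classifySpan(pair, i, b)
      if (!is.null(g)) { found <- g; break }
    }
    if (is.null(found)) {
      # no valid span: singleton carrying the word's own alignment links
      tg <- targetsOf(pair, i)
      found <- list(srcSpan = i, tgtSpan = tg, kind = "singleton",
                    groupLinks = canonicalLinks(
                      cbind(src = rep(i, length(tg)), tgt = tg)))
    }
    groups[[length(groups) + 1L]] <- found
    i <- max(found$srcSpan) + 1L
  }
  groups
}

# validity + kind of the candidate source span [a, b]; NULL if invalid
classifySpan <- function(pair, a, b) {
  links <- pair@links
  srcSpan <- a:b
  inSrc <- links[, "src"] %in% srcSpan
  tg <- sort(unique(links[inSrc, "tgt"]))
  if (length(tg) == 0) return(NULL)
  tgtSpan <- min(tg):max(tg)
  # target span contiguity: every position in the range is aligned into it
  if (!all(tgtSpan %in% tg)) return(NULL)
  # every source member aligned
  if (!all(srcSpan %in% links[inSrc, "src"])) return(NULL)
  # consistency: nothing in the target span aligns outside the source span
  inTgt <- links[, "tgt"] %in% tgtSpan
  if (any(inTgt & !inSrc)) return(NULL)
  m <- length(srcSpan); n <- length(tgtSpan)
  sub <- canonicalLinks(links[inSrc, , drop = FALSE])
  monotone <- m == n && nrow(sub) == m &&
    all(sub[, "src"] == srcSpan) && all(sub[, "tgt"] == tgtSpan)
  bipartite <- nrow(sub) == m * n
  if (m == 1 && n == 1) {
    kind <- "singleton"
  } else if (monotone) {
    kind <- "contiguous"
  } else if (bipartite) {
    kind <- "mwg"
  } else {
    return(NULL)
  }
  groupLinks <- if (kind == "singleton") {
    sub
  } else {
    # one group-level link, anchored at the leftmost members
    canonicalLinks(cbind(src = a, tgt = min(tg)))
  }
  list(srcSpan = srcSpan, tgtSpan = tgtSpan, kind = kind,
       groupLinks = groupLinks)
}

#' Word-group alignment crossings (seq_cross)
#'
#' Computes crossings exactly as [wordCross()] does, but on the group-level
#' links produced by [buildSequenceGroups()]: a contiguous or multi-word
#' group contributes a single group link, a singleton contributes its word
#' links. The crossing count of a group is passed on to every word belonging
#' to that group, which is why MWGs can shrink a word's value dramatically:
#' a link that crosses all m x n word alignments of an MWG crosses only its
#' one group link. Unaligned tokens get \code{NA}.
#'
#' @param pair a \linkS4class{SentencePair}
#' @return integer vector, one entry per source token
#' @export
seqCross <- function(pair) {
  groups <- buildSequenceGroups(pair)
  n <- length(pair@source)
  out <- rep(NA_integer_, n)
  if (length(groups) == 0) return(out)
  allLinks <- do.call(rbind, lapply(groups, `[[`, "groupLinks"))
  owner <- rep(seq_along(groups),
               vapply(groups, function(g) nrow(g$groupLinks), 0L))
  crossing <- linkCrossMatrix(allLinks)
  for (k in seq_along(groups)) {
    mine <- owner == k
    # crossings of this group's links with links of other groups
    val <- as.integer(sum(crossing[mine, !mine, drop = FALSE]))
    out[groups[[k]]$srcSpan + 1L] <- val
  }
  out
}

stopIfInvalid <- function(pair) {
  msgs <- validatePair(pair)
  if (length(msgs) > 0)
    stop("invalid sentence pair: ", paste(msgs, collapse = "; "),
         call. = FALSE)
  invisible(pair)
}
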