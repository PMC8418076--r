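#' Shannon entropy of an event-count distribution, in bits
#'
#' \eqn{H(X) = -\sum_{e \in X} P(e) \log_2 P(e)} with probabilities taken as
#' relative frequencies of the counts and \eqn{0 \log 0 = 0}. Interpreted
#' over translators, low entropy means high agreement, high entropy low
#' agreement.
#'
#' @param counts positive integer vector of event counts (one entry per
#'   unique event)
#' @return entropy in bits, in \eqn{[0, \log_2 k]} for \eqn{k} events
#' @examples
#' entropyBits(c(4))      # 0
#' entropyBits(c(1, 1))   # 1
#' entropyBits(c(2, 1, 1))  # 1.5
#' @export
entropyBits <- function(counts) {
  if (length(counts) == 0)
    stop("empty distribution has no entropy", call. = FALSE)
  if (any(counts < 1))
    stop("event counts must be positive", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Construct a TranslationEnsemble
#'
#' @param source character vector of shared source tokens
#' @param versions named list of \linkS4class{SentencePair} objects (names
#'   are translator ids), each sharing \code{source}
#' @return a validated \linkS4class{TranslationEnsemble}
#' @export
translationEnsemble <- function(source, versions) {
  new("TranslationEnsemble", source = as.character(source),
      versions = versions)
}

# per-version event collector shared by the entropy metrics: applies fn to
# each version's pair, drops NULL events (token unaligned in that version,
# unless dropUnaligned = FALSE, in which case they become a distinct event)
collectEvents <- function(ensemble, fn, dropUnaligned = TRUE) {
  ev <- lapply(versions(ensemble), fn)
  if (dropUnaligned) {
    ev <- ev[!vapply(ev, is.null, TRUE)]
  } else {
    ev <- lapply(ev, function(e) if (is.null(e)) "<unaligned>" else e)
  }
  unlist(ev, use.names = FALSE)
}

entropyOfEvents <- function(events) {
  if (length(events) == 0) return(NA_real_)
  entropyBits(as.vector(table(events)))
}

#' Word translation entropy (HTra)
#'
#' Entropy of the lexical choices made for one source token across the
#' ensemble's translations. Per version, the event is the normalized
#' rendering of the target tokens aligned to the source token: lowercased,
#' joined with single spaces in target sentence order. High HTra means many
#' competing lexical options; full agreement yields 0 bits.
#'
#' @param ensemble a \linkS4class{TranslationEnsemble}
#' @param tokenIndex 0-based source token position
#' @param dropUnaligned drop versions in which the token is unaligned
#'   (default); if \code{FALSE} they contribute a distinct "untranslated"
#'   event
#' @return entropy in bits, or \code{NA} if no version aligns the token
#' @export
hTra <- function(ensemble, tokenIndex, dropUnaligned = TRUE) {
  checkTokenIndex(ensemble, tokenIndex)
  events <- collectEvents(ensemble, function(pair) {
    tg <- targetsOf(pair, tokenIndex)
    if (length(tg) == 0) return(NULL)
    tolower(paste(trimws(pair@target[tg + 1L]), collapse = " "))
  }, dropUnaligned)
  entropyOfEvents(events)
}

#' Reordering entropy (HCross)
#'
#' Entropy of a source token's signed Cross values across the ensemble's
#' translations. If translators reorder the source word in the same way,
#' HCross is low; disagreement about the repositioning of the translation
#' drives it up.
#'
#' @inheritParams hTra
#' @return entropy in bits, or \code{NA} if no version yields a Cross value
#' @export
hCross <- function(ensemble, tokenIndex, dropUnaligned = TRUE) {
  checkTokenIndex(ensemble, tokenIndex)
  events <- collectEvents(ensemble, function(pair) {
    cv <- crossValues(pair)$cross[tokenIndex + 1L]
    if (is.na(cv)) NULL else cv
  }, dropUnaligned)
  entropyOfEvents(events)
}

#' Alignment groups: connected components of the alignment graph
#'
#' An alignment group is a set of source and target words that are aligned
#' with each other — a connected component of the bipartite graph whose
#' vertices are tokens and whose edges are alignment links. Each component
#' carries a group-level Cross value obtained by applying the Cross pointer
#' convention to the component sequence (components ordered by leftmost
#' source index; a component's target position is the rank of its leftmost
#' target index), so all source words of a component share one Cross value.
#'
#' @param pair a \linkS4class{SentencePair}
#' @return list of components, each a list with \code{srcIndices},
#'   \code{tgtIndices} (0-based, sorted) and \code{groupCross}
#' @export
alignmentComponents <- function(pair) {
  stopIfInvalid(pair)
  links <- pair@links
  if (nrow(links) == 0) return(list())
  sv <- paste0("s", links[, "src"])
  tv <- paste0("t", links[, "tgt"])
  g <- igraph::graph_from_edgelist(cbind(sv, tv), directed = FALSE)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  comps <- lapply(seq_len(comp$no), function(k) {
    mem <- vnames[comp$membership == k]
    list(srcIndices = sort(as.integer(sub("s", "", mem[startsWith(mem, "s")]))),
         tgtIndices = sort(as.integer(sub("t", "", mem[startsWith(mem, "t")]))))
  })
  comps <- comps[order(vapply(comps, function(cp) min(cp$srcIndices), 0L))]
  # Cross pointer convention on the component sequence
  tgtRank <- rank(vapply(comps, function(cp) min(cp$tgtIndices), 0L))
  p <- 0L
  for (k in seq_along(comps)) {
    t1 <- as.integer(tgtRank[k])
    comps[[k]]$groupCross <- t1 - p
    p <- t1
  }
  comps
}

#' Joint source-target alignment/translation distortion entropy (HSTC)
#'
#' Per version, the event for a source token is the triplet (s, t, c) of its
#' alignment group: s and t are the lowercased, space-joined source and
#' target member forms in sentence order and c is the group's Cross value.
#' HSTC is the entropy of that triplet distribution over the ensemble; it
#' folds the lexical uncertainty of HTra and the reordering uncertainty of
#' HCross into one number.
#'
#' @inheritParams hTra
#' @return entropy in bits, or \code{NA} if no version aligns the token
#' @export
hSTC <- function(ensemble, tokenIndex, dropUnaligned = TRUE) {
  checkTokenIndex(ensemble, tokenIndex)
  events <- collectEvents(ensemble, function(pair) {
    trip <- stcTriplet(pair, tokenIndex)
    if (is.null(trip)) NULL else paste(trip, collapse = "\r")
  }, dropUnaligned)
  entropyOfEvents(events)
}

# (s, t, c) of the token's alignment component, or NULL if unaligned
stcTriplet <- function(pair, tokenIndex) {
  comps <- alignmentComponents(pair)
  for (cp in comps) {
    if (tokenIndex %in% cp$srcIndices) {
      return(c(
        s = tolower(paste(pair@source[cp$srcIndices + 1L], collapse = " ")),
        t = tolower(paste(pair@target[cp$tgtIndices + 1L], collapse = " ")),
        c = as.character(cp$groupCross)))
    }
  }
  NULL
}

#' All entropy metrics for every source token of an ensemble
#'
#' @param ensemble a \linkS4class{TranslationEnsemble}
#' @param dropUnaligned see [hTra()]
#' @return data.frame with columns \code{token_index}, \code{token},
#'   \code{htra}, \code{hcross}, \code{hstc}
#' @export
entropyProfile <- function(ensemble, dropUnaligned = TRUE) {
  n <- length(ensemble@source)
  idx <- seq_len(n) - 1L
  data.frame(
    token_index = idx,
    token = ensemble@source,
    htra = vapply(idx, function(i) hTra(ensemble, i, dropUnaligned), 0),
    hcross = vapply(idx, function(i) hCross(ensemble, i, dropUnaligned), 0),
    hstc = vapply(idx, function(i) hSTC(ensemble, i, dropUnaligned), 0))
}

checkTokenIndex <- function(ensemble, tokenIndex) {
  if (length(tokenIndex) != 1 || tokenIndex < 0 ||
      tokenIndex >= length(ensemble@source))
    stop("token index out of range: ", tokenIndex, call. = FALSE)
  invisible(tokenIndex)
}
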