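#' @import methods
#' @importFrom stats sd setNames
#' @importFrom utils read.delim write.table
NULL

#' SentencePair: a tokenized, word-aligned sentence pair
#'
#' The substrate of all word-level product metrics. Holds the tokenized
#' source and target sentences (character vectors; positions are 0-based in
#' all link bookkeeping) and a set of word-alignment links in Pharaoh
#' convention ("i-j", 0-based source and target indices). Tokens may be
#' unaligned (no incident link) or aligned to several tokens on the other
#' side; the link set never contains duplicates.
#'
#' @slot source character vector of source token surface forms
#' @slot target character vector of target token surface forms
#' @slot links two-column integer matrix, columns \code{src} and \code{tgt},
#'   0-based token indices; zero rows means an empty alignment
#'
#' @seealso [sentencePair()], [parsePharaoh()], [crossValues()], [wordCross()]
#' @export
setClass("SentencePair",
  representation(source = "character", target = "character",
                 links = "matrix"))

setValidity("SentencePair", function(object) {
  msgs <- validatePair(object)
  if (length(msgs) == 0) TRUE else msgs
})

#' TranslationEnsemble: one source sentence with multiple aligned translations
#'
#' Substrate of the entropy metrics (HTra, HCross, HSTC). Each version is a
#' \linkS4class{SentencePair} whose source tokens are identical to the
#' ensemble's source sequence; versions are keyed by a translator identifier.
#' At least two versions are needed for any entropy to be non-degenerate.
#'
#' @slot source character vector of the shared source tokens
#' @slot versions named list of \linkS4class{SentencePair}, names are
#'   translator ids
#'
#' @seealso [translationEnsemble()], [hTra()], [hCross()], [hSTC()]
#' @export
setClass("TranslationEnsemble",
  representation(source = "character", versions = "list"))

setValidity("TranslationEnsemble", function(object) {
  msgs <- character(0)
  if (length(object@versions) > 0) {
    if (is.null(names(object@versions)) ||
        any(!nzchar(names(object@versions))))
      msgs <- c(msgs, "versions must be a named list (translator ids)")
    if (anyDuplicated(names(object@versions)))
      msgs <- c(msgs, "translator ids must be unique")
    for (v in object@versions) {
      if (!is(v, "SentencePair")) {
        msgs <- c(msgs, "every version must be a SentencePair")
      } else if (!identical(v@source, object@source)) {
        msgs <- c(msgs, "every version must share the ensemble's source tokens")
      }
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' DepTree: an ordered dependency tree over a tokenized sentence
#'
#' One node per syntactic token, positions 0-based and identical to the
#' sentence-pair token positions. Exactly one node is the root
#' (\code{head == -1}); every other node is reachable from it, and sibling
#' order is word order. \code{deprel} carries the Universal Dependencies
#' relation label of each node.
#'
#' @slot form character vector of token forms
#' @slot head integer vector of 0-based head positions, -1 for the root
#' @slot deprel character vector of dependency relation labels
#'
#' @seealso [depTree()], [readConllu()], [astredChange()]
#' @export
setClass("DepTree",
  representation(form = "character", head = "integer", deprel = "character"))

setValidity("DepTree", function(object) {
  n <- length(object@form)
  msgs <- character(0)
  if (length(object@head) != n || length(object@deprel) != n)
    msgs <- c(msgs, "form, head and deprel must have equal length")
  if (n > 0) {
    if (sum(object@head == -1L) != 1L)
      msgs <- c(msgs, "tree must have exactly one root (head == -1)")
    if (any(object@head < -1L | object@head >= n))
      msgs <- c(msgs, "head indices out of range")
    if (length(msgs) == 0 && !allReachable(object@head))
      msgs <- c(msgs, "tree contains a cycle or unreachable node")
  }
  if (length(msgs) == 0) TRUE else msgs
})

# every node reaches the root without revisiting (no cycles)
allReachable <- function(head) {
  n <- length(head)
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (head[j] != -1L) {
      if (seen[j]) return(FALSE)
      seen[j] <- TRUE
      j <- head[j] + 1L
    }
  }
  TRUE
}

setMethod("show", "SentencePair", function(object) {
  cat(sprintf("SentencePair: %d source / %d target tokens, %d links\n",
              length(object@source), length(object@target),
              nrow(object@links)))
  cat("  source:", paste(object@source, collapse = " "), "\n")
  cat("  target:", paste(object@target, collapse = " "), "\n")
  if (nrow(object@links) > 0)
    cat("  links: ", serializePharaoh(object@links), "\n")
})

setMethod("show", "TranslationEnsemble", function(object) {
  cat(sprintf("TranslationEnsemble: %d source tokens, %d versions (%s)\n",
              length(object@source), length(object@versions),
              paste(names(object@versions), collapse = ", ")))
})

setMethod("show", "DepTree", function(object) {
  cat(sprintf("DepTree: %d nodes, root at position %d\n",
              length(object@form), which(object@head == -1L) - 1L))
  cat(" ", paste(sprintf("%s:%s", object@form, object@deprel),
                 collapse = " "), "\n")
})

#' @describeIn sentencePair number of source tokens
#' @export
setGeneric("sourceTokens", function(x) standardGeneric("sourceTokens"))
#' @describeIn sentencePair target tokens
#' @export
setGeneric("targetTokens", function(x) standardGeneric("targetTokens"))
#' @describeIn sentencePair alignment link matrix (0-based)
#' @export
setGeneric("alignmentLinks", function(x) standardGeneric("alignmentLinks"))

#' @export
setMethod("sourceTokens", "SentencePair", function(x) x@source)
#' @export
setMethod("sourceTokens", "TranslationEnsemble", function(x) x@source)
#' @export
setMethod("targetTokens", "SentencePair", function(x) x@target)
#' @export
setMethod("alignmentLinks", "SentencePair", function(x) x@links)

#' Versions of a translation ensemble
#'
#' @param x a \linkS4class{TranslationEnsemble}
#' @return named list of \linkS4class{SentencePair} objects
#' @export
setGeneric("versions", function(x) standardGeneric("versions"))
#' @export
setMethod("versions", "TranslationEnsemble", function(x) x@versions)
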