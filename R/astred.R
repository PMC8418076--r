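#' Construct a dependency tree
#'
#' @param form character vector of token forms
#' @param head integer vector of 0-based head positions, -1 marks the root
#' @param deprel character vector of Universal Dependencies relation labels
#' @return a validated \linkS4class{DepTree}
#' @export
depTree <- function(form, head, deprel) {
  new("DepTree", form = as.character(form), head = as.integer(head),
      deprel = as.character(deprel))
}

#' Read dependency trees from a CoNLL-U stream
#'
#' Parses Universal Dependencies CoNLL-U (v2 conventions): sentences
#' separated by blank lines, ten tab-separated columns per token line,
#' comments starting with \code{#}. Multiword-token ranges (\code{1-2}) and
#' empty nodes (\code{1.1}) are tolerated but skipped: they carry no head
#' and take no part in the tree. Token indices are converted to 0-based.
#' A sentence whose head column does not describe exactly one rooted,
#' acyclic tree is rejected with its \code{sent_id} when present.
#'
#' @param con a file path or connection, or a character vector of lines
#'   (when \code{text = TRUE})
#' @param text interpret \code{con} as the raw lines themselves
#' @return list of \linkS4class{DepTree}, one per sentence
#' @export
readConllu <- function(con, text = FALSE) {
  lines <- if (text) con else readLines(con, warn = FALSE)
  trees <- list()
  sent <- list(); sentId <- NA_character_
  flush <- function() {
    if (length(sent) == 0) return()
    trees[[length(trees) + 1L]] <<- buildConlluTree(sent, sentId)
    sent <<- list(); sentId <<- NA_character_
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*sent_id\\s*=\\s*(\\S+)", ln))[[1]]
      if (length(m) == 2) sentId <- m[2]
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("malformed CoNLL-U line: ", ln, call. = FALSE)
    if (grepl("[-.]", f[1])) next  # multiword range or empty node
    sent[[length(sent) + 1L]] <- f
  }
  flush()
  trees
}

buildConlluTree <- function(sent, sentId) {
  id <- vapply(sent, function(f) as.integer(f[1]), 0L)
  form <- vapply(sent, `[`, "", 2L)
  head1 <- vapply(sent, function(f) as.integer(f[7]), 0L)
  deprel <- vapply(sent, `[`, "", 8L)
  where <- if (is.na(sentId)) "" else paste0(" in sentence ", sentId)
  if (!identical(id, seq_along(id)))
    stop("non-consecutive token ids", where, call. = FALSE)
  if (anyNA(head1) || any(head1 < 0 | head1 > length(id)))
    stop("head index out of range", where, call. = FALSE)
  tr <- tryCatch(depTree(form, head1 - 1L, deprel), error = function(e) e)
  if (inherits(tr, "error"))
    stop("not a single rooted tree", where, ": ",
         conditionMessage(tr), call. = FALSE)
  tr
}

#' Merge node labels of a source and target tree via alignment components
#'
#' Prepares the two dependency trees for aligned tree edit distance: each
#' aligned node receives its alignment component's identifier as its match
#' label, so the nodes of aligned source and target words end up with the
#' same label in their respective trees, and only aligned words can match.
#' Unaligned nodes receive a side-prefixed label that cannot occur in the
#' other tree.
#'
#' @param srcTree,tgtTree \linkS4class{DepTree} objects covering the pair's
#'   token sequences
#' @param pair the \linkS4class{SentencePair} carrying the alignment
#' @return list with \code{src} and \code{tgt}: character vectors of match
#'   labels, one per node in sentence order
#' @export
mergeLabels <- function(pair, srcTree, tgtTree) {
  stopIfInvalid(pair)
  if (length(srcTree@form) != length(pair@source) ||
      length(tgtTree@form) != length(pair@target))
    stop("trees do not cover the sentence pair's token sequences",
         call. = FALSE)
  comps <- alignmentComponents(pair)
  srcLab <- paste0("S", seq_along(pair@source) - 1L)
  tgtLab <- paste0("T", seq_along(pair@target) - 1L)
  for (k in seq_along(comps)) {
    srcLab[comps[[k]]$srcIndices + 1L] <- paste0("C", k)
    tgtLab[comps[[k]]$tgtIndices + 1L] <- paste0("C", k)
  }
  list(src = srcLab, tgt = tgtLab)
}

# ordered children lists (1-based ids), sibling order = word order
childrenOf <- function(tree) {
  n <- length(tree@head)
  ch <- vector("list", n)
  for (i in seq_len(n)) ch[[i]] <- integer(0)
  for (i in seq_len(n)) {
    h <- tree@head[i]
    if (h != -1L) ch[[h + 1L]] <- c(ch[[h + 1L]], i)
  }
  ch
}

rootOf <- function(tree) which(tree@head == -1L)

#' Ordered tree edit distance with per-node edit script
#'
#' Minimal-cost script transforming the source tree into the target tree
#' under unit costs: match 0, rename 1, delete 1, insert 1. Deletion applies
#' to source nodes only and insertion to target nodes only. The distance is
#' computed by the Zhang-Shasha ordered-TED recurrence (rightmost-root
#' decomposition of sibling-ordered forests), evaluated with memoisation and
#' backtraced to recover one optimal script. Ties between equal-cost scripts
#' are broken deterministically: a substitution branch (match or rename) is
#' preferred over deletion, which is preferred over insertion.
#'
#' @param srcTree,tgtTree \linkS4class{DepTree} objects
#' @param srcLabels,tgtLabels node labels used for matching (defaults to the
#'   trees' dependency relation labels); aligned-TED passes the merged
#'   labels from [mergeLabels()]
#' @return list with \code{cost} (integer), \code{srcOps} and \code{tgtOps}
#'   (character vectors per node: \code{"match"}, \code{"rename"},
#'   \code{"delete"} / \code{"insert"}), and \code{mapping} (two-column
#'   matrix of matched/renamed 1-based node pairs)
#' @export
treeEditDistance <- function(srcTree, tgtTree,
                             srcLabels = srcTree@deprel,
                             tgtLabels = tgtTree@deprel) {
  n1 <- length(srcTree@form); n2 <- length(tgtTree@form)
  if (n1 == 0 || n2 == 0) stop("trees must be non-empty", call. = FALSE)
  ch1 <- childrenOf(srcTree); ch2 <- childrenOf(tgtTree)
  memo <- new.env(parent = emptyenv())

  # forest = integer vector of root ids, left-to-right
  fdist <- function(f1, f2) {
    key <- paste(paste(f1, collapse = ","), paste(f2, collapse = ","),
                 sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (length(f1) == 0 && length(f2) == 0) {
      res <- list(cost = 0L, op = "done")
    } else if (length(f1) == 0) {
      res <- list(cost = fdist(f1, dropRight(f2, ch2))$cost + 1L,
                  op = "insert")
    } else if (length(f2) == 0) {
      res <- list(cost = fdist(dropRight(f1, ch1), f2)$cost + 1L,
                  op = "delete")
    } else {
      v <- f1[length(f1)]; w <- f2[length(f2)]
      subCost <- if (srcLabels[v] == tgtLabels[w]) 0L else 1L
      cSub <- fdist(f1[-length(f1)], f2[-length(f2)])$cost +
        fdist(ch1[[v]], ch2[[w]])$cost + subCost
      cDel <- fdist(dropRight(f1, ch1), f2)$cost + 1L
      cIns <- fdist(f1, dropRight(f2, ch2))$cost + 1L
      # tie-break: substitution (match/rename) > delete > insert
      if (cSub <= cDel && cSub <= cIns) {
        res <- list(cost = cSub, op = "sub")
      } else if (cDel <= cIns) {
        res <- list(cost = cDel, op = "delete")
      } else {
        res <- list(cost = cIns, op = "insert")
      }
    }
    memo[[key]] <- res
    res
  }

  srcOps <- character(n1); tgtOps <- character(n2)
  mapping <- list()
  backtrace <- function(f1, f2) {
    while (length(f1) > 0 || length(f2) > 0) {
      op <- fdist(f1, f2)$op
      if (op == "sub") {
        v <- f1[length(f1)]; w <- f2[length(f2)]
        kind <- if (srcLabels[v] == tgtLabels[w]) "match" else "rename"
        srcOps[v] <<- kind; tgtOps[w] <<- kind
        mapping[[length(mapping) + 1L]] <<- c(v, w)
        backtrace(ch1[[v]], ch2[[w]])
        f1 <- f1[-length(f1)]; f2 <- f2[-length(f2)]
      } else if (op == "delete") {
        v <- f1[length(f1)]
        srcOps[v] <<- "delete"
        f1 <- dropRight(f1, ch1)
      } else {  # insert
        w <- f2[length(f2)]
        tgtOps[w] <<- "insert"
        f2 <- dropRight(f2, ch2)
      }
    }
  }
  r1 <- rootOf(srcTree); r2 <- rootOf(tgtTree)
  total <- fdist(r1, r2)$cost
  backtrace(r1, r2)
  mapping <- if (length(mapping)) do.call(rbind, mapping) else
    matrix(integer(0), ncol = 2)
  colnames(mapping) <- c("src", "tgt")
  list(cost = total, srcOps = srcOps, tgtOps = tgtOps, mapping = mapping)
}

# remove the rightmost root of a forest, promoting its children
dropRight <- function(f, children) {
  v <- f[length(f)]
  c(f[-length(f)], children[[v]])
}

#' Aligned syntactic tree edit distance change flags (astred_change)
#'
#' Runs [mergeLabels()] and then [treeEditDistance()] on the relabeled
#' trees, so that only aligned words can match, and reports per source
#' token whether its node survived as a match (\code{FALSE}) or required an
#' edit operation (\code{TRUE}); for source nodes that operation can only be
#' deletion or substitution, since insertion only happens for target words.
#'
#' @param pair a \linkS4class{SentencePair}
#' @param srcTree,tgtTree \linkS4class{DepTree} objects for the two
#'   sentences
#' @return data.frame with columns \code{token_index} (0-based),
#'   \code{astred_change} (logical) and \code{operation} (\code{"match"},
#'   \code{"rename"} or \code{"delete"}); the total script cost is attached
#'   as attribute \code{"cost"}
#' @export
astredChange <- function(pair, srcTree, tgtTree) {
  labs <- mergeLabels(pair, srcTree, tgtTree)
  ted <- treeEditDistance(srcTree, tgtTree, labs$src, labs$tgt)
  out <- data.frame(token_index = seq_along(pair@source) - 1L,
                    astred_change = ted$srcOps != "match",
                    operation = ted$srcOps)
  attr(out, "cost") <- ted$cost
  out
}
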