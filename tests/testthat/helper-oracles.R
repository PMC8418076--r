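# Independent oracles and random-instance generators used across the suite.
# These deliberately re-derive the quantities by direct enumeration, never
# through the package's own code paths.

# random aligned pair: each (i, j) link kept with probability `density`
randomPair <- function(nSrc, nTgt, density = 0.25) {
  keep <- which(matrix(runif(nSrc * nTgt) < density, nSrc, nTgt),
                arr.ind = TRUE)
  links <- if (nrow(keep) == 0) "" else
    cbind(src = keep[, 1] - 1L, tgt = keep[, 2] - 1L)
  sentencePair(paste0("s", seq_len(nSrc)), paste0("t", seq_len(nTgt)),
               links)
}

# monotone one-to-one pair of length n
monotonePair <- function(n) {
  sentencePair(paste0("s", seq_len(n)), paste0("t", seq_len(n)),
               cbind(src = seq_len(n) - 1L, tgt = seq_len(n) - 1L))
}

# full-reversal one-to-one pair of length n
reversalPair <- function(n) {
  sentencePair(paste0("s", seq_len(n)), paste0("t", seq_len(n)),
               cbind(src = seq_len(n) - 1L, tgt = rev(seq_len(n)) - 1L))
}

# O(L^2) crossing enumeration by explicit double loop over link pairs
bruteLinkCrossCounts <- function(links) {
  L <- nrow(links)
  counts <- integer(L)
  if (L < 2) return(counts)
  for (a in seq_len(L)) {
    for (b in seq_len(L)) {
      if (a == b) next
      if ((links[a, 1] - links[b, 1]) * (links[a, 2] - links[b, 2]) < 0)
        counts[a] <- counts[a] + 1L
    }
  }
  counts
}

# per-source-token word_cross by brute force
bruteWordCross <- function(pair, side = "source") {
  links <- alignmentLinks(pair)
  n <- if (side == "source") length(sourceTokens(pair)) else
    length(pair@target)
  out <- rep(NA_integer_, n)
  counts <- bruteLinkCrossCounts(links)
  col <- if (side == "source") 1L else 2L
  for (i in seq_len(n) - 1L) {
    inc <- which(links[, col] == i)
    if (length(inc) > 0) out[i + 1L] <- sum(counts[inc])
  }
  out
}

# per-source-token seq_cross by brute-force crossing enumeration over the
# group-level links (group construction is shared; the crossing count and
# inheritance are re-derived here)
bruteSeqCross <- function(pair) {
  groups <- buildSequenceGroups(pair)
  n <- length(sourceTokens(pair))
  out <- rep(NA_integer_, n)
  if (length(groups) == 0) return(out)
  links <- do.call(rbind, lapply(groups, `[[`, "groupLinks"))
  owner <- rep(seq_along(groups),
               vapply(groups, function(g) nrow(g$groupLinks), 0L))
  for (k in seq_along(groups)) {
    tot <- 0L
    for (a in which(owner == k)) {
      for (b in which(owner != k)) {
        if ((links[a, 1] - links[b, 1]) * (links[a, 2] - links[b, 2]) < 0)
          tot <- tot + 1L
      }
    }
    out[groups[[k]]$srcSpan + 1L] <- tot
  }
  out
}

# random ordered tree with n nodes: parent of node i drawn among nodes < i
randomTree <- function(n, labels = letters[1:3]) {
  head <- c(-1L, if (n > 1) vapply(2:n, function(i)
    sample.int(i - 1L, 1L) - 1L, 0L))
  depTree(paste0("w", seq_len(n)), head, sample(labels, n, replace = TRUE))
}

# exhaustive ordered tree edit distance: enumerate every one-to-one node
# mapping that preserves ancestry and left-to-right order; cost is unmapped
# nodes plus label mismatches among mapped pairs
bruteTreeEditDistance <- function(srcTree, tgtTree,
                                  srcLabels = srcTree@deprel,
                                  tgtLabels = tgtTree@deprel) {
  n1 <- length(srcTree@form); n2 <- length(tgtTree@form)
  anc1 <- ancestorMatrix(srcTree); anc2 <- ancestorMatrix(tgtTree)
  # left-right order between disjoint nodes comes from the ordered-tree
  # traversal (children sorted by token index), not raw token positions:
  # the two can differ when subtrees interleave
  post1 <- postorderPositions(srcTree); post2 <- postorderPositions(tgtTree)
  best <- Inf
  bestMaps <- list()
  consistent <- function(map, v, w) {
    for (k in seq_len(nrow(map))) {
      v2 <- map[k, 1]; w2 <- map[k, 2]
      if (anc1[v2, v] != anc2[w2, w]) return(FALSE)  # v2 ancestor of v?
      if (anc1[v, v2] != anc2[w, w2]) return(FALSE)
      if (!anc1[v2, v] && !anc1[v, v2] &&
          ((post1[v2] < post1[v]) != (post2[w2] < post2[w])))
        return(FALSE)
    }
    TRUE
  }
  rec <- function(v, map, usedTgt) {
    if (v > n1) {
      cost <- (n1 - nrow(map)) + (n2 - nrow(map))
      if (nrow(map) > 0)
        cost <- cost + sum(srcLabels[map[, 1]] != tgtLabels[map[, 2]])
      if (cost < best) { best <<- cost; bestMaps <<- list(map) }
      else if (cost == best) bestMaps[[length(bestMaps) + 1L]] <<- map
      return()
    }
    rec(v + 1L, map, usedTgt)  # v unmapped (deleted)
    for (w in seq_len(n2)) {
      if (usedTgt[w]) next
      if (nrow(map) == 0 || consistent(map, v, w))
        rec(v + 1L, rbind(map, c(v, w)), replace(usedTgt, w, TRUE))
    }
  }
  rec(1L, matrix(integer(0), ncol = 2), logical(n2))
  list(cost = best, mappings = bestMaps)
}

# position of each node in the postorder traversal of the ordered tree
postorderPositions <- function(tree) {
  n <- length(tree@head)
  ch <- vector("list", n)
  for (i in seq_len(n)) ch[[i]] <- integer(0)
  for (i in seq_len(n)) {
    h <- tree@head[i]
    if (h != -1L) ch[[h + 1L]] <- c(ch[[h + 1L]], i)
  }
  pos <- integer(n)
  counter <- 0L
  rec <- function(v) {
    for (c in ch[[v]]) rec(c)
    counter <<- counter + 1L
    pos[v] <<- counter
  }
  rec(which(tree@head == -1L))
  pos
}

# anc[i, j] is TRUE iff node i is a proper ancestor of node j
ancestorMatrix <- function(tree) {
  n <- length(tree@head)
  anc <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    h <- tree@head[j]
    while (h != -1L) {
      anc[h + 1L, j] <- TRUE
      h <- tree@head[h + 1L]
    }
  }
  anc
}

# small CoNLL-U builder for tree fixtures
conlluText <- function(forms, heads1, deprels, sentId = NULL) {
  hdr <- if (is.null(sentId)) character(0) else
    paste0("# sent_id = ", sentId)
  body <- sprintf("%d\t%s\t_\t_\t_\t_\t%d\t%s\t_\t_",
                  seq_along(forms), forms, heads1, deprels)
  c(hdr, body, "")
}
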