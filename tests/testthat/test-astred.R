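test_that("readConllu builds 0-based rooted trees and skips non-token lines", {
  txt <- c("# sent_id = s1",
           "1\tI\t_\t_\t_\t_\t2\tnsubj\t_\t_",
           "2\tsleep\t_\t_\t_\t_\t0\troot\t_\t_",
           "3\tnow\t_\t_\t_\t_\t2\tadvmod\t_\t_",
           "")
  trees <- readConllu(txt, text = TRUE)
  expect_length(trees, 1)
  tr <- trees[[1]]
  expect_equal(tr@head, c(1L, -1L, 1L))
  expect_equal(tr@deprel, c("nsubj", "root", "advmod"))
  # heads [2, 2, 0] (1-based) root at 0-based position 1
  expect_equal(which(tr@head == -1L) - 1L, 1L)
})

test_that("readConllu handles multiple sentences, ranges and empty nodes", {
  txt <- c(conlluText(c("a", "b"), c(2, 0), c("dep", "root")),
           c("1-2\tab\t_\t_\t_\t_\t_\t_\t_\t_",
             "1\ta\t_\t_\t_\t_\t0\troot\t_\t_",
             "1.1\tghost\t_\t_\t_\t_\t_\t_\t_\t_",
             "2\tb\t_\t_\t_\t_\t1\tdep\t_\t_",
             ""))
  trees <- readConllu(txt, text = TRUE)
  expect_length(trees, 2)
  expect_equal(length(trees[[2]]@form), 2L)  # range and empty node skipped
})

test_that("cyclic or multi-root sentences are rejected with their id", {
  cyc <- conlluText(c("a", "b"), c(2, 1), c("dep", "dep"), sentId = "bad1")
  expect_error(readConllu(cyc, text = TRUE), "bad1")
  tworoots <- conlluText(c("a", "b"), c(0, 0), c("root", "root"),
                         sentId = "bad2")
  expect_error(readConllu(tworoots, text = TRUE), "bad2")
})

test_that("mergeLabels gives aligned nodes shared component labels", {
  src <- depTree(c("a", "b"), c(-1, 0), c("root", "obj"))
  tgt <- depTree(c("x", "y"), c(-1, 0), c("root", "obj"))
  pair <- sentencePair(c("a", "b"), c("x", "y"), "0-0 1-1")
  labs <- mergeLabels(pair, src, tgt)
  expect_equal(labs$src, labs$tgt)  # one shared label per aligned pair
  expect_length(unique(labs$src), 2)

  # unaligned source node can match nothing in the target tree
  pair2 <- sentencePair(c("a", "b"), c("x", "y"), "0-0")
  labs2 <- mergeLabels(pair2, src, tgt)
  expect_false(labs2$src[2] %in% labs2$tgt)

  # all members of an MWG component share one label
  ex <- mwgExamplePair()
  srcT <- depTree(sourceTokens(ex), c(2, 2, -1, 4, 2),
                  c("nsubj", "aux", "root", "amod", "obj"))
  tgtT <- depTree(targetTokens(ex), c(6, 6, 6, 5, 5, 2, -1),
                  c("nsubj", "aux", "obj", "case", "det", "nmod", "root"))
  labs3 <- mergeLabels(ex, srcT, tgtT)
  expect_length(unique(c(labs3$src[4:5], labs3$tgt[3:6])), 1)

  expect_error(mergeLabels(pair, src, depTree("x", -1L, "root")),
               "cover")
})

test_that("tree edit distance: identical, renamed and degenerate cases", {
  t1 <- depTree(c("a", "b", "c"), c(-1, 0, 0), c("root", "l", "r"))
  ted0 <- treeEditDistance(t1, t1)
  expect_equal(ted0$cost, 0L)
  expect_true(all(ted0$srcOps == "match"))
  expect_true(all(ted0$tgtOps == "match"))

  s1 <- depTree("a", -1L, "root")
  s2 <- depTree("b", -1L, "other")
  ted1 <- treeEditDistance(s1, s2)
  expect_equal(ted1$cost, 1L)
  expect_equal(ted1$srcOps, "rename")
})

test_that("tree edit distance respects the metric axioms on random trees", {
  set.seed(31)
  for (rep in 1:25) {
    a <- randomTree(sample(2:7, 1))
    b <- randomTree(sample(2:7, 1))
    dab <- treeEditDistance(a, b)$cost
    dba <- treeEditDistance(b, a)$cost
    expect_gte(dab, 0)
    expect_equal(dab, dba)  # symmetric with delete/insert exchanged
    na <- length(a@form); nb <- length(b@form)
    expect_lte(dab, na + nb)
    expect_gte(dab, abs(na - nb))
    expect_equal(treeEditDistance(a, a)$cost, 0L)
    c <- randomTree(sample(2:7, 1))
    expect_lte(treeEditDistance(a, c)$cost,
               dab + treeEditDistance(b, c)$cost)
  }
})

test_that("tree edit distance equals the exhaustive-mapping oracle", {
  set.seed(77)
  for (rep in 1:60) {
    a <- randomTree(sample(2:6, 1))
    b <- randomTree(sample(2:6, 1))
    expect_equal(treeEditDistance(a, b)$cost,
                 bruteTreeEditDistance(a, b)$cost)
  }
})

test_that("the edit script is internally consistent with its cost", {
  set.seed(13)
  for (rep in 1:20) {
    a <- randomTree(sample(2:7, 1)); b <- randomTree(sample(2:7, 1))
    ted <- treeEditDistance(a, b)
    expect_equal(ted$cost,
                 sum(ted$srcOps == "rename") + sum(ted$srcOps == "delete") +
                   sum(ted$tgtOps == "insert"))
    # every node is assigned exactly one operation
    expect_true(all(ted$srcOps %in% c("match", "rename", "delete")))
    expect_true(all(ted$tgtOps %in% c("match", "rename", "insert")))
    expect_equal(sum(ted$srcOps %in% c("match", "rename")),
                 nrow(ted$mapping))
  }
})

test_that("astred_change is all-FALSE on label-isomorphic aligned trees", {
  src <- depTree(c("a", "b", "c"), c(-1, 0, 0), c("root", "l", "r"))
  tgt <- depTree(c("x", "y", "z"), c(-1, 0, 0), c("root", "l", "r"))
  pair <- sentencePair(c("a", "b", "c"), c("x", "y", "z"), "0-0 1-1 2-2")
  ac <- astredChange(pair, src, tgt)
  expect_false(any(ac$astred_change))
  expect_equal(attr(ac, "cost"), 0L)
})

test_that("exactly the unaligned/divergent nodes are flagged TRUE", {
  # unaligned source token in otherwise identical trees
  src <- depTree(c("a", "b", "c"), c(-1, 0, 0), c("root", "l", "r"))
  tgt <- depTree(c("x", "y", "z"), c(-1, 0, 0), c("root", "l", "r"))
  pair <- sentencePair(c("a", "b", "c"), c("x", "y", "z"), "0-0 2-2")
  ac <- astredChange(pair, src, tgt)
  expect_equal(ac$astred_change, c(FALSE, TRUE, FALSE))
  # oracle agrees on the cost of the relabeled instance
  labs <- mergeLabels(pair, src, tgt)
  expect_equal(attr(ac, "cost"),
               bruteTreeEditDistance(src, tgt, labs$src, labs$tgt)$cost)

  # extra unaligned modifier under the source root: exactly one TRUE
  src2 <- depTree(c("a", "mod", "b"), c(-1, 0, 0), c("root", "m", "l"))
  tgt2 <- depTree(c("x", "y"), c(-1, 0), c("root", "l"))
  pair2 <- sentencePair(c("a", "mod", "b"), c("x", "y"), "0-0 2-1")
  ac2 <- astredChange(pair2, src2, tgt2)
  expect_equal(ac2$astred_change, c(FALSE, TRUE, FALSE))
  expect_equal(ac2$operation[2], "delete")
  labs2 <- mergeLabels(pair2, src2, tgt2)
  expect_equal(attr(ac2, "cost"),
               bruteTreeEditDistance(src2, tgt2, labs2$src, labs2$tgt)$cost)
})

test_that("source-side operations are only match, rename or delete", {
  set.seed(41)
  for (rep in 1:15) {
    p <- randomPair(4, 4, 0.4)
    src <- randomTree(4); tgt <- randomTree(4)
    ac <- astredChange(p, src, tgt)
    expect_true(all(ac$operation %in% c("match", "rename", "delete")))
  }
})
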