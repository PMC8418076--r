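# small ensemble builder: same source, per-version targets + alignments
makeEnsemble <- function(source, targets, alignments) {
  vers <- list()
  for (v in seq_along(targets)) {
    vers[[sprintf("P%02d", v)]] <-
      sentencePair(source, targets[[v]], alignments[[v]])
  }
  translationEnsemble(source, vers)
}

test_that("entropyBits evaluates the Shannon formula on counts", {
  expect_equal(entropyBits(4), 0)
  expect_equal(entropyBits(c(1, 1)), 1)
  expect_equal(entropyBits(c(2, 1, 1)), 1.5)
  expect_equal(entropyBits(c(3, 1)), -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(entropyBits(numeric(0)), "empty")
  expect_error(entropyBits(c(1, 0)), "positive")
})

test_that("HTra measures lexical agreement across versions", {
  src <- c("the", "house")
  # full agreement on "huis" -> 0 bits
  ens0 <- makeEnsemble(src,
    replicate(4, c("het", "huis"), simplify = FALSE),
    replicate(4, "0-0 1-1", simplify = FALSE))
  expect_equal(hTra(ens0, 1), 0)
  # 2 x "big", 2 x "large" -> uniform binary, 1 bit
  ens1 <- makeEnsemble(c("big", "dog"),
    list(c("big", "x"), c("big", "x"), c("large", "x"), c("large", "x")),
    replicate(4, "0-0 1-1", simplify = FALSE))
  expect_equal(hTra(ens1, 0), 1)
  # counts (2, 1, 1) -> 1.5 bits
  ens2 <- makeEnsemble(c("w"),
    list("a", "a", "b", "c"), replicate(4, "0-0", simplify = FALSE))
  expect_equal(hTra(ens2, 0), 1.5)
})

test_that("HTra normalizes casing and joins multi-token alignments", {
  src <- c("w")
  ens <- makeEnsemble(src, list(c("Huis"), c("huis")),
                      list("0-0", "0-0"))
  expect_equal(hTra(ens, 0), 0)  # casing variants are the same event
  ens2 <- makeEnsemble(src, list(c("op", "maat"), c("op", "maat")),
                       list("0-0 0-1", "0-0 0-1"))
  expect_equal(hTra(ens2, 0), 0)  # joined in target order
})

test_that("versions with an unaligned token are dropped unless asked for", {
  src <- c("w", "v")
  ens <- makeEnsemble(src,
    list(c("a", "x"), c("a", "x"), c("y", "x")),
    list("0-0 1-1", "0-0 1-1", "1-1"))  # token 0 unaligned in version 3
  expect_equal(hTra(ens, 0), 0)
  # with dropUnaligned = FALSE the missing translation is its own event
  expect_equal(hTra(ens, 0, dropUnaligned = FALSE),
               entropyBits(c(2, 1)))
  # token unaligned in every version has no distribution
  ens2 <- makeEnsemble(src, list(c("a", "x"), c("b", "x")),
                       list("1-1", "1-1"))
  expect_true(is.na(hTra(ens2, 0)))
})

test_that("HCross measures reordering agreement across versions", {
  src <- paste0("s", 1:3)
  # all versions monotone -> Cross constant 1 -> 0 bits
  ensA <- makeEnsemble(src,
    replicate(4, paste0("t", 1:3), simplify = FALSE),
    replicate(4, "0-0 1-1 2-2", simplify = FALSE))
  expect_equal(hCross(ensA, 0), 0)
  expect_equal(hCross(ensA, 2), 0)
  # half Cross = 1, half Cross = 2 for the first token -> 1 bit
  ensB <- makeEnsemble(src,
    list(paste0("t", 1:3), paste0("t", 1:3),
         paste0("t", 1:3), paste0("t", 1:3)),
    list("0-0 1-1 2-2", "0-0 1-1 2-2", "0-1 1-0 2-2", "0-1 1-0 2-2"))
  expect_equal(hCross(ensB, 0), 1)
  # counts (3, 1) -> 0.8113 bits
  ensC <- makeEnsemble(src,
    replicate(4, paste0("t", 1:3), simplify = FALSE),
    list("0-0 1-1 2-2", "0-0 1-1 2-2", "0-0 1-1 2-2", "0-1 1-0 2-2"))
  expect_equal(hCross(ensC, 0), 0.811278124459, tolerance = 1e-9)
})

test_that("alignment components are the connected alignment groups", {
  # degenerate: monotone 1-1, one component per token, group Cross all 1
  comps <- alignmentComponents(monotonePair(3))
  expect_length(comps, 3)
  expect_equal(vapply(comps, `[[`, 0L, "groupCross"), c(1L, 1L, 1L))
  # worked MWG example: one component spans the 2 x 4 block
  comps2 <- alignmentComponents(mwgExamplePair())
  mwg <- comps2[[which(vapply(comps2, function(cp)
    3L %in% cp$srcIndices, TRUE))]]
  expect_equal(mwg$srcIndices, 3:4)
  expect_equal(mwg$tgtIndices, 2:5)
  # chained links union into a single component
  chain <- sentencePair(c("a", "b"), c("x", "y"), "0-0 1-0 1-1")
  comps3 <- alignmentComponents(chain)
  expect_length(comps3, 1)
  expect_equal(comps3[[1]]$srcIndices, 0:1)
  expect_equal(comps3[[1]]$tgtIndices, 0:1)
})

test_that("HSTC is the entropy of (source group, target group, Cross)", {
  src <- c("w")
  # identical triplets -> 0 bits
  ens0 <- makeEnsemble(src, list("a", "a"), list("0-0", "0-0"))
  expect_equal(hSTC(ens0, 0), 0)
  # two versions with distinct triplets -> 1 bit
  ens1 <- makeEnsemble(src, list("a", "b"), list("0-0", "0-0"))
  expect_equal(hSTC(ens1, 0), 1)
  # versions differing only in c collapse to the Cross marginal
  src2 <- c("w", "v")
  ens2 <- makeEnsemble(src2,
    list(c("a", "b"), c("a", "b"), c("b", "a"), c("b", "a")),
    list("0-0 1-1", "0-0 1-1", "0-1 1-0", "0-1 1-0"))
  expect_equal(hSTC(ens2, 0), 1)
  expect_equal(hSTC(ens2, 0), hCross(ens2, 0))
})

test_that("entropies are bounded by log2 of the version count and are
           invariant under version order and translator relabeling", {
  set.seed(5)
  for (rep in 1:10) {
    cfg <- simConfig(seed = rep, nSrc = 6, nVersions = 8,
                     reorderRate = 0.3, mwgProb = 0.2)
    ens <- genEnsemble(cfg)
    prof <- entropyProfile(ens)
    bound <- log2(length(versions(ens))) + 1e-12
    expect_true(all(prof$htra <= bound, na.rm = TRUE))
    expect_true(all(prof$hcross <= bound, na.rm = TRUE))
    expect_true(all(prof$hstc <= bound, na.rm = TRUE))
    expect_true(all(prof$htra >= 0, na.rm = TRUE))
    # permute versions and rename translators: identical entropies
    vs <- versions(ens)
    perm <- sample(length(vs))
    relabeled <- setNames(vs[perm], paste0("X", seq_along(vs)))
    ens2 <- translationEnsemble(sourceTokens(ens), relabeled)
    expect_equal(entropyProfile(ens2)[, c("htra", "hcross", "hstc")],
                 prof[, c("htra", "hcross", "hstc")])
  }
})

test_that("the joint triplet entropy dominates its coordinate marginals", {
  # rebuild the per-version (s, t, c) events from alignment components and
  # check H(joint) >= H(marginal) for each coordinate, on random ensembles
  tripletEvents <- function(ens, tok) {
    evs <- lapply(versions(ens), function(pair) {
      comps <- alignmentComponents(pair)
      for (cp in comps) {
        if (tok %in% cp$srcIndices) {
          return(c(s = paste(sourceTokens(pair)[cp$srcIndices + 1],
                             collapse = " "),
                   t = paste(targetTokens(pair)[cp$tgtIndices + 1],
                             collapse = " "),
                   c = as.character(cp$groupCross)))
        }
      }
      NULL
    })
    do.call(rbind, evs[!vapply(evs, is.null, TRUE)])
  }
  set.seed(17)
  for (rep in 1:8) {
    cfg <- simConfig(seed = 100 + rep, nSrc = 5, nVersions = 10,
                     reorderRate = 0.4, mwgProb = 0.3)
    ens <- genEnsemble(cfg)
    for (tok in 0:4) {
      ev <- tripletEvents(ens, tok)
      if (is.null(ev)) next
      joint <- entropyBits(as.vector(table(apply(ev, 1, paste,
                                                 collapse = "|"))))
      expect_equal(joint, hSTC(ens, tok))
      for (coord in colnames(ev)) {
        marg <- entropyBits(as.vector(table(ev[, coord])))
        expect_gte(joint, marg - 1e-9)
      }
    }
  }
})
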