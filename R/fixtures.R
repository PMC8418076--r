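#' Configuration for the synthetic translation-process generator
#'
#' Bundles every tunable of the synthetic generators with validated
#' defaults. The defaults emulate the structure of a from-scratch
#' translation study: around ten translations per source text, news-style
#' sentence lengths, modest reordering, occasional idiomatic multi-word
#' groups, and fixation/keystroke timing in the ranges typical of reading
#' during translation.
#'
#' @param seed integer master seed; every generator derives its own
#'   substream from it, so adding a generator never perturbs the others
#' @param nSrc number of source tokens per sentence
#' @param reorderRate target inversion density in \eqn{[0, 1]}: 0 produces a
#'   monotone pair, 1 fully reverses the group order
#' @param mwgProb probability that a group is generated as a full-bipartite
#'   multi-word group instead of a one-to-one token
#' @param mwgSrcWidth,mwgTgtWidth source/target widths of generated MWGs
#'   (scalar or range to sample from)
#' @param nVersions number of translations in a generated ensemble
#' @param translationDist per-token named probability vectors over candidate
#'   renderings (list of length \code{nSrc}); \code{NULL} gives every token
#'   the same three-way (0.6, 0.3, 0.1) lexical distribution
#' @param stratified force ensemble rendering counts to the rounded expected
#'   counts instead of sampling them
#' @param participants participant ids for event-log generation
#' @param fixMean,fixSd mean / sd of fixation durations (ms)
#' @param refixProb probability of an immediate refixation on a token
#' @param regressionProb probability of a one-fixation regression to the
#'   previous token after a token is read
#' @param saccadeGap inter-fixation gap (ms)
#' @param keyDelayMean,keyDelaySd typing latency after reading a token (ms)
#' @param keystrokes generate a keystroke log (disable for reading-only
#'   logs; all EKS become \code{NA})
#' @return a validated list of class \code{"simConfig"}
#' @export
simConfig <- function(seed = 1L, nSrc = 15L, reorderRate = 0.15,
                      mwgProb = 0.1, mwgSrcWidth = 2L, mwgTgtWidth = 2:4,
                      nVersions = 10L, translationDist = NULL,
                      stratified = FALSE, participants = "P01",
                      fixMean = 220, fixSd = 50, refixProb = 0.3,
                      regressionProb = 0.2, saccadeGap = 30,
                      keyDelayMean = 800, keyDelaySd = 300,
                      keystrokes = TRUE) {
  stopifnot(nSrc >= 1, reorderRate >= 0, reorderRate <= 1,
            mwgProb >= 0, mwgProb <= 1, nVersions >= 1,
            all(mwgSrcWidth >= 2), all(mwgTgtWidth >= 1),
            fixMean > 0, fixSd >= 0, refixProb >= 0, refixProb <= 1,
            regressionProb >= 0, regressionProb <= 1)
  if (is.null(translationDist))
    translationDist <- rep(list(c(alpha = 0.6, beta = 0.3, gamma = 0.1)),
                           nSrc)
  stopifnot(length(translationDist) == nSrc)
  for (d in translationDist) {
    stopifnot(!is.null(names(d)), all(d > 0),
              abs(sum(d) - 1) < 1e-8)
  }
  structure(list(seed = as.integer(seed), nSrc = as.integer(nSrc),
                 reorderRate = reorderRate, mwgProb = mwgProb,
                 mwgSrcWidth = as.integer(mwgSrcWidth),
                 mwgTgtWidth = as.integer(mwgTgtWidth),
                 nVersions = as.integer(nVersions),
                 translationDist = translationDist,
                 stratified = stratified, participants = participants,
                 fixMean = fixMean, fixSd = fixSd, refixProb = refixProb,
                 regressionProb = regressionProb, saccadeGap = saccadeGap,
                 keyDelayMean = keyDelayMean, keyDelaySd = keyDelaySd,
                 keystrokes = keystrokes),
            class = "simConfig")
}

# per-component substream: one master seed fans out deterministically
setSubstreamSeed <- function(cfg, offset) {
  set.seed((cfg$seed %% 65011L) * 32749L + offset)
}

# adjacent-swap shuffle with swap budget proportional to rate: rate 0 is
# the identity, rate 1 applies n(n-1)/2 swaps (expected full scramble;
# exactly the full reversal for n = 2)
shufflePositions <- function(n, rate) {
  ord <- seq_len(n)
  if (n < 2) return(ord)
  nSwaps <- round(rate * n * (n - 1) / 2)
  for (s in seq_len(nSwaps)) {
    i <- sample.int(n - 1L, 1L)
    ord[c(i, i + 1L)] <- ord[c(i + 1L, i)]
  }
  ord
}

#' Generate a word-aligned sentence pair with known group structure
#'
#' Builds the pair group-wise: walking the source left to right, each group
#' is either a one-to-one token or (with probability \code{mwgProb}) a
#' full-bipartite multi-word group; the groups' target order is then
#' shuffled with an adjacent-swap budget proportional to
#' \code{reorderRate}. The generating group structure is attached as gold
#' labels (attribute \code{"goldGroups"}) for group-construction tests.
#' Identical seeds give identical output.
#'
#' @param cfg a [simConfig()]
#' @return a \linkS4class{SentencePair}; attribute \code{"goldGroups"} holds
#'   a list of \code{(srcSpan, tgtSpan, kind)} gold groups
#' @export
genPair <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  setSubstreamSeed(cfg, 1L)
  groups <- list()
  i <- 0L
  while (i < cfg$nSrc) {
    m <- resample1(cfg$mwgSrcWidth)
    if (cfg$mwgProb > 0 && i + m <= cfg$nSrc &&
        stats::runif(1) < cfg$mwgProb) {
      groups[[length(groups) + 1L]] <-
        list(srcWidth = m, tgtWidth = resample1(cfg$mwgTgtWidth),
             kind = "mwg")
      i <- i + m
    } else {
      groups[[length(groups) + 1L]] <-
        list(srcWidth = 1L, tgtWidth = 1L, kind = "singleton")
      i <- i + 1L
    }
  }
  G <- length(groups)
  tgtOrder <- shufflePositions(G, cfg$reorderRate)
  # source layout
  srcStart <- cumsum(c(0L, vapply(groups, `[[`, 0L, "srcWidth")))[seq_len(G)]
  # target layout in shuffled group order
  widths <- vapply(groups, `[[`, 0L, "tgtWidth")
  tgtStart <- integer(G)
  pos <- 0L
  for (k in tgtOrder) {
    tgtStart[k] <- pos
    pos <- pos + widths[k]
  }
  links <- NULL
  gold <- list()
  for (k in seq_len(G)) {
    g <- groups[[k]]
    ss <- srcStart[k] + seq_len(g$srcWidth) - 1L
    ts <- tgtStart[k] + seq_len(g$tgtWidth) - 1L
    links <- rbind(links, as.matrix(expand.grid(src = ss, tgt = ts)))
    gold[[k]] <- list(srcSpan = ss, tgtSpan = ts, kind = g$kind)
  }
  nTgt <- sum(widths)
  pair <- sentencePair(paste0("src", seq_len(cfg$nSrc) - 1L),
                       paste0("tgt", seq_len(nTgt) - 1L),
                       canonicalLinks(links))
  attr(pair, "goldGroups") <- gold
  pair
}

resample1 <- function(x) if (length(x) == 1) x else sample(x, 1L)

#' Generate a multi-translator ensemble with known entropy
#'
#' Samples \code{nVersions} translations of the same source sentence:
#' per version, each source token's rendering is drawn from that token's
#' \code{translationDist} and the token order is shuffled per
#' \code{reorderRate}. The generating distribution's entropy per token is
#' attached as gold (attribute \code{"goldHTra"}) for recovery tests. With
#' \code{stratified = TRUE} rendering counts are forced to the rounded
#' expected counts, making small-sample entropies exact.
#'
#' @param cfg a [simConfig()]
#' @return a \linkS4class{TranslationEnsemble} with attribute
#'   \code{"goldHTra"} (bits per source token)
#' @export
genEnsemble <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  setSubstreamSeed(cfg, 2L)
  n <- cfg$nSrc
  source <- paste0("src", seq_len(n) - 1L)
  # per token, the rendering drawn for each version
  renderings <- matrix("", nrow = cfg$nVersions, ncol = n)
  for (i in seq_len(n)) {
    d <- cfg$translationDist[[i]]
    if (cfg$stratified) {
      counts <- largestRemainderCounts(d, cfg$nVersions)
      renderings[, i] <- sample(rep(names(d), counts))
    } else {
      renderings[, i] <- sample(names(d), cfg$nVersions, replace = TRUE,
                                prob = d)
    }
  }
  vers <- list()
  for (v in seq_len(cfg$nVersions)) {
    ord <- shufflePositions(n, cfg$reorderRate)  # ord[k] = source token at
    tgt <- character(n)                          # target position k
    links <- cbind(src = ord - 1L, tgt = seq_len(n) - 1L)
    tgt <- paste0(renderings[v, ord], "_", ord - 1L)
    vers[[sprintf("P%02d", v)]] <- sentencePair(source, tgt, links)
  }
  ens <- translationEnsemble(source, vers)
  attr(ens, "goldHTra") <- vapply(cfg$translationDist,
                                  function(d) -sum(d * log2(d)), 0)
  ens
}

largestRemainderCounts <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate fixation and keystroke logs with gold measures
#'
#' Simulates a left-to-right reading pass over the source tokens of a pair:
#' each token receives one fixation (plus an immediate refixation with
#' probability \code{refixProb}); after a token is read, a single-fixation
#' regression to the previous token occurs with probability
#' \code{regressionProb}; with keystrokes enabled, a contributing keystroke
#' follows each token after a typing latency. Gold values of every reading
#' measure are recorded during generation (attribute \code{"gold"}) so the
#' measure implementations can be tested against the construction itself.
#'
#' @param cfg a [simConfig()]
#' @param pair the \linkS4class{SentencePair} being read (only its source
#'   length is used)
#' @return list with \code{fixations} and \code{keystrokes} data.frames (the
#'   documented log schemas) and attribute \code{"gold"}: a data.frame of
#'   per-participant, per-token gold \code{ffdur}, \code{trts}, \code{eks},
#'   \code{fpd}, \code{rpd}
#' @export
genEventLog <- function(cfg, pair) {
  stopifnot(inherits(cfg, "simConfig"))
  setSubstreamSeed(cfg, 3L)
  n <- length(sourceTokens(pair))
  fixRows <- list(); keyRows <- list(); goldRows <- list()
  for (p in cfg$participants) {
    clock <- 0
    ffdur <- rep(NA_real_, n); trts <- rep(0, n); fpd <- rep(NA_real_, n)
    rpd <- rep(NA_real_, n); eks <- rep(NA_real_, n)
    firstOnset <- rep(NA_real_, n)
    sampleDur <- function() max(30, round(stats::rnorm(1, cfg$fixMean,
                                                       cfg$fixSd)))
    addFix <- function(tok, dur) {
      fixRows[[length(fixRows) + 1L]] <<- data.frame(
        participant = p, token_index = tok, onset = clock, duration = dur)
      clock <<- clock + dur + cfg$saccadeGap
    }
    for (i in seq_len(n) - 1L) {
      nFix <- 1L + stats::rbinom(1, 1, cfg$refixProb)
      block <- numeric(0)
      for (f in seq_len(nFix)) {
        dur <- sampleDur()
        if (f == 1) { ffdur[i + 1] <- dur; firstOnset[i + 1] <- clock }
        block <- c(block, dur)
        addFix(i, dur)
      }
      fpd[i + 1] <- sum(block)
      rpd[i + 1] <- sum(block)
      trts[i + 1] <- trts[i + 1] + sum(block)
      if (i > 0 && stats::runif(1) < cfg$regressionProb) {
        dur <- sampleDur()
        addFix(i - 1L, dur)
        trts[i] <- trts[i] + dur
        # regression precedes the first fixation right of token i
        rpd[i + 1] <- rpd[i + 1] + dur
      }
      if (cfg$keystrokes) {
        kt <- clock + max(50, round(stats::rnorm(1, cfg$keyDelayMean,
                                                 cfg$keyDelaySd)))
        keyRows[[length(keyRows) + 1L]] <- data.frame(
          participant = p, time = kt, contributes_to = i)
        eks[i + 1] <- kt - firstOnset[i + 1]
      }
    }
    goldRows[[length(goldRows) + 1L]] <- data.frame(
      participant = p, token_index = seq_len(n) - 1L,
      ffdur = ffdur, trts = trts, eks = eks, fpd = fpd, rpd = rpd)
  }
  fixations <- do.call(rbind, fixRows)
  keystrokes <- if (length(keyRows)) do.call(rbind, keyRows) else
    data.frame(participant = character(0), time = numeric(0),
               contributes_to = integer(0))
  out <- list(fixations = fixations, keystrokes = keystrokes)
  attr(out, "gold") <- do.call(rbind, goldRows)
  out
}

#' The worked multi-word-group example pair
#'
#' A hand-written English-Dutch pair in which "marine sentinels" is
#' translated idiomatically as "wachters van de zee" (a full-bipartite 2 x 4
#' multi-word group) and "called" as the clause-final "genoemd". The single
#' alignment link of "called" crosses all eight word alignments of the MWG,
#' giving it a word_cross of 8, while at group level the MWG collapses to
#' one link and seq_cross("called") is 1.
#'
#' @return a \linkS4class{SentencePair}
#' @examples
#' p <- mwgExamplePair()
#' wordCross(p)[4]  # 8
#' seqCross(p)[4]   # 1
#' @export
mwgExamplePair <- function() {
  sentencePair(
    source = c("they", "are", "called", "marine", "sentinels"),
    target = c("ze", "worden", "wachters", "van", "de", "zee", "genoemd"),
    alignment = paste("0-0 1-1 2-6",
                      "3-2 3-3 3-4 3-5",
                      "4-2 4-3 4-4 4-5"))
}
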