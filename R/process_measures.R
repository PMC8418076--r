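#' Eye-tracking and keystroke dependent variables
#'
#' These functions derive the reading and production measures used as
#' dependent variables in translation process research from token-attributed
#' event logs. A fixation log is a data.frame with columns
#' \code{participant}, \code{token_index} (0-based source token),
#' \code{onset} and \code{duration} (milliseconds); a keystroke log has
#' \code{participant}, \code{time} and \code{contributes_to} (the source
#' token whose translation the keystroke produces, or \code{NA}).
#'
#' \describe{
#'   \item{FFDur}{duration of the first fixation when a source word is
#'     first encountered (early measure).}
#'   \item{TrtS}{total reading time: the sum of all fixations on a source
#'     word, irrespective of when they occurred (late measure).}
#'   \item{EKS}{eye-key span: time between the first fixation on a source
#'     word and the first keystroke that contributes to its translation
#'     (late measure).}
#'   \item{FPD}{first-pass duration: sum of the first consecutive fixations
#'     on a word before moving to any other word.}
#'   \item{RPD}{regression-path duration: sum of all fixations on a word,
#'     including regressions to previous words, before a fixation to the
#'     right of the word is registered.}
#' }
#'
#' @param fixLog fixation log data.frame (see above), sorted by onset per
#'   participant
#' @param keyLog keystroke log data.frame (see above)
#' @param participant participant id
#' @param token 0-based source token index
#' @return milliseconds, or \code{NA} when the defining events are absent
#' @name processMeasures
NULL

participantFixations <- function(fixLog, participant) {
  fx <- fixLog[fixLog$participant == participant, , drop = FALSE]
  fx <- fx[order(fx$onset), , drop = FALSE]
  if (any(fx$duration <= 0))
    stop("fixation durations must be positive", call. = FALSE)
  fx
}

#' @rdname processMeasures
#' @export
firstFixationDuration <- function(fixLog, participant, token) {
  fx <- participantFixations(fixLog, participant)
  on <- fx[fx$token_index == token, , drop = FALSE]
  if (nrow(on) == 0) return(NA_real_)
  first <- which(on$onset == min(on$onset))
  if (length(first) > 1)
    stop("ambiguous log: two fixations on token ", token,
         " share the earliest onset", call. = FALSE)
  on$duration[first]
}

#' @rdname processMeasures
#' @export
totalReadingTime <- function(fixLog, participant, token) {
  fx <- participantFixations(fixLog, participant)
  on <- fx[fx$token_index == token, , drop = FALSE]
  if (nrow(on) == 0) return(NA_real_)
  sum(on$duration)
}

#' @rdname processMeasures
#' @export
eyeKeySpan <- function(fixLog, keyLog, participant, token) {
  fx <- participantFixations(fixLog, participant)
  on <- fx[fx$token_index == token, , drop = FALSE]
  ks <- keyLog[keyLog$participant == participant &
               !is.na(keyLog$contributes_to) &
               keyLog$contributes_to == token, , drop = FALSE]
  if (nrow(on) == 0 || nrow(ks) == 0) return(NA_real_)
  span <- min(ks$time) - min(on$onset)
  if (span < 0) {
    warning("keystroke for token ", token, " of participant ", participant,
            " precedes its first fixation; EKS set to NA", call. = FALSE)
    return(NA_real_)
  }
  span
}

#' @rdname processMeasures
#' @export
firstPassDuration <- function(fixLog, participant, token) {
  fx <- participantFixations(fixLog, participant)
  hit <- which(fx$token_index == token)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  total <- 0
  while (i <= nrow(fx) && fx$token_index[i] == token) {
    total <- total + fx$duration[i]
    i <- i + 1L
  }
  total
}

#' @rdname processMeasures
#' @export
regressionPathDuration <- function(fixLog, participant, token) {
  fx <- participantFixations(fixLog, participant)
  hit <- which(fx$token_index == token)
  if (length(hit) == 0) return(NA_real_)
  total <- 0
  for (i in hit[1]:nrow(fx)) {
    if (fx$token_index[i] > token) break
    total <- total + fx$duration[i]
  }
  total
}

#' Per-token process records for every participant
#'
#' Convenience wrapper computing all five measures for every
#' (participant, fixated token) combination in the logs.
#'
#' @inheritParams processMeasures
#' @return data.frame with columns \code{participant}, \code{token_index},
#'   \code{ffdur}, \code{trts}, \code{eks}, \code{fpd}, \code{rpd}
#' @export
tokenProcessRecords <- function(fixLog, keyLog = NULL) {
  if (is.null(keyLog))
    keyLog <- data.frame(participant = character(0), time = numeric(0),
                         contributes_to = integer(0))
  combos <- unique(fixLog[, c("participant", "token_index")])
  combos <- combos[order(combos$participant, combos$token_index), ,
                   drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    p <- combos$participant[r]; tok <- combos$token_index[r]
    data.frame(
      participant = p, token_index = tok,
      ffdur = firstFixationDuration(fixLog, p, tok),
      trts = totalReadingTime(fixLog, p, tok),
      eks = eyeKeySpan(fixLog, keyLog, p, tok),
      fpd = firstPassDuration(fixLog, p, tok),
      rpd = regressionPathDuration(fixLog, p, tok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-participant standard-deviation outlier exclusion
#'
#' Single-pass raw-data filter: within each group (participant), an
#' observation is dropped when it differs from the group mean by more than
#' \code{k} sample standard deviations. A group with zero variance keeps all
#' its points. \code{NA} observations are kept (they carry no evidence) and
#' excluded from the group statistics. The same operation applies to a
#' residual column to reproduce residual-outlier exclusion.
#'
#' @param values numeric vector of observations
#' @param group vector of group (participant) labels, same length
#' @param k exclusion threshold in standard deviations (default 2.5)
#' @return list with \code{keep} (logical mask), \code{lossRate} (overall
#'   proportion of non-missing observations dropped) and \code{groupLoss}
#'   (named per-group proportions)
#' @examples
#' x <- c(10, 10, 10, 10)
#' excludeOutliers(x, rep("p1", 4))$keep  # all TRUE
#' @export
excludeOutliers <- function(values, group, k = 2.5) {
  stopifnot(length(values) == length(group), k >= 0)
  keep <- rep(TRUE, length(values))
  groups <- unique(group)
  groupLoss <- setNames(numeric(length(groups)), as.character(groups))
  for (g in groups) {
    idx <- which(group == g & !is.na(values))
    if (length(idx) < 2) next
    m <- mean(values[idx]); s <- sd(values[idx])
    if (is.na(s) || s == 0) next
    drop <- abs(values[idx] - m) > k * s
    keep[idx[drop]] <- FALSE
    groupLoss[as.character(g)] <- mean(drop)
  }
  nObs <- sum(!is.na(values))
  list(keep = keep,
       lossRate = if (nObs == 0) 0 else sum(!keep) / nObs,
       groupLoss = groupLoss)
}

#' Log transform of positive dependent variables
#'
#' Natural logarithm; \code{NA} values propagate, non-positive values are a
#' domain error naming the offending rows. The base is recorded in the
#' \code{"base"} attribute of the result.
#'
#' @param values numeric vector (> 0 or \code{NA})
#' @return transformed vector with attribute \code{base = exp(1)}
#' @export
logTransform <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad) > 0)
    stop("log transform of non-positive value(s) at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- log(values)
  attr(out, "base") <- exp(1)
  out
}
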