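#' @include AllClasses.R
NULL

#' Causal moving-average smoothing
#'
#' Smooths a signal with a causal average filter: the output at position
#' \code{t} is the mean of the \code{n} samples strictly before \code{t}.
#' Positions with fewer than \code{n} preceding samples use the mean of all
#' available preceding samples, and the first position passes through
#' unchanged, so the output always has the same length as the input.
#'
#' @param signal numeric vector, length >= 1.
#' @param n positive integer filter window length (default 10, i.e. half a
#'   second at 20 Hz).
#' @return Numeric vector of the same length as \code{signal}.
#' @examples
#' smoothSignal(1:20, n = 10)[15]  # mean of samples 5..14 -> 9.5
#' @export
smoothSignal <- function(signal, n = 10L) {
  if (length(signal) == 0L) stop("empty input")
  n <- as.integer(n)
  stopifnot(n >= 1L)
  T <- length(signal)
  out <- numeric(T)
  out[1L] <- signal[1L]
  if (T == 1L) return(out)
  # zero-padded cumulative sums give every windowed mean in O(T)
  cs <- c(0, cumsum(signal))
  t <- 2:T
  lo <- pmax(t - n, 1L)            # first sample entering the average
  width <- (t - 1L) - lo + 1L
  out[t] <- (cs[t] - cs[lo]) / width
  out
}

#' Preprocessing configuration
#'
#' @param smoothing_n causal average-filter window, in samples (default 10).
#' @param window_length_l feature window length, in samples (default 60,
#'   i.e. 3 s at 20 Hz).
#' @param overlap_fraction fraction of consecutive windows that overlaps,
#'   in \code{[0, 1)} (default 0.33; with l = 60 this gives a step of 40
#'   samples).
#' @return A list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(smoothing_n = 10L, window_length_l = 60L,
                             overlap_fraction = 0.33) {
  smoothing_n <- as.integer(smoothing_n)
  window_length_l <- as.integer(window_length_l)
  stopifnot(smoothing_n >= 1L, window_length_l >= 2L,
            overlap_fraction >= 0, overlap_fraction < 1)
  step <- window_length_l - as.integer(round(overlap_fraction * window_length_l))
  if (step < 1L) stop("overlap too large: step must be >= 1")
  structure(list(smoothing_n = smoothing_n,
                 window_length_l = window_length_l,
                 overlap_fraction = overlap_fraction,
                 step = step),
            class = "PreprocessConfig")
}

#' Enumerate feature windows over a recording
#'
#' Window starts advance from sample 0 in steps of
#' \code{l - round(overlap_fraction * l)}; a trailing partial window is
#' discarded. Each window receives the activity label covering the majority
#' of its samples under \code{labeling} (ties go to the earlier interval);
#' samples outside every labeled interval count toward \code{"not_tagged"}.
#'
#' @param recording a \code{\link{TriaxialRecording}}.
#' @param labeling an \code{\link{ActivityLabeling}} for the same run, or
#'   \code{NULL} for an unlabeled recording.
#' @param config a \code{\link{preprocessConfig}}.
#' @return A data.frame with columns \code{start}, \code{end} (0-based,
#'   half-open sample indices), \code{time} (window start timestamp) and
#'   \code{label}. Zero rows if the recording is shorter than one window.
#' @export
makeWindows <- function(recording, labeling = NULL,
                        config = preprocessConfig()) {
  stopifnot(methods::is(recording, "TriaxialRecording"))
  l <- config$window_length_l
  step <- config$step
  T <- nSamples(recording)
  starts <- seq.int(0L, by = step, length.out = max(0L, (T - l) %/% step + 1L))
  if (T < l) starts <- integer(0)
  if (length(starts) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      time = numeric(), label = character()))
  # per-sample label, then majority vote per window
  sampleLab <- sampleLabels(recording@time, labeling)
  lab <- vapply(starts, function(s) {
    majorityLabel(sampleLab[(s + 1L):(s + l)], labeling)
  }, character(1))
  data.frame(start = starts, end = starts + l,
             time = recording@time[starts + 1L], label = lab,
             stringsAsFactors = FALSE)
}

## label of each sample: index of covering interval (0 = not tagged)
sampleLabels <- function(time, labeling) {
  idx <- integer(length(time))
  if (is.null(labeling)) return(idx)
  for (i in seq_along(labeling@start)) {
    idx[time >= labeling@start[i] & time < labeling@end[i]] <- i
  }
  idx
}

## majority by sample count; ties resolved toward the earlier interval
## (lower interval index); interval index 0 is "not_tagged" and for the tie
## rule counts as earliest only when it is strictly the majority winner --
## a tie between not_tagged and an interval goes to the interval with the
## earlier start, so we order candidates by interval index with 0 last.
majorityLabel <- function(intervalIdx, labeling) {
  counts <- table(intervalIdx)
  ids <- as.integer(names(counts))
  best <- max(counts)
  cand <- ids[counts == best]
  # earlier interval wins ties; not_tagged (0) is "no interval" and yields
  # only when tied with a real interval
  pick <- if (length(cand) > 1L && any(cand > 0L)) min(cand[cand > 0L]) else cand[1L]
  if (pick == 0L) "not_tagged" else labeling@activity[pick]
}

.featureOrder <- c("mean_x", "mean_y", "mean_z", "var_x", "var_y", "var_z",
                   "corr_xy", "corr_xz", "corr_yz", "mean_mag", "var_mag",
                   "avg_deriv_mag")

## population variance and total-covariance correlation; a zero-variance
## axis pair has correlation 0 by convention so clustering stays total
popVar <- function(v) mean((v - mean(v))^2)

safeCorr <- function(a, b) {
  va <- popVar(a); vb <- popVar(b)
  if (va == 0 || vb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
}

#' Extract the 12 window features
#'
#' For one window of x/y/z samples, computes, in this fixed order: the mean
#' and (population) variance of each axis, the correlation of each axis pair,
#' and the mean, variance and average absolute first difference of the
#' magnitude \eqn{m(t) = \sqrt{x^2 + y^2 + z^2}}. Correlation of a
#' zero-variance axis pair is defined as 0.
#'
#' @param x,y,z numeric vectors of equal length \code{l >= 2}.
#' @return Named numeric vector of length 12.
#' @examples
#' extractFeatures(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0))
#' @export
extractFeatures <- function(x, y, z) {
  l <- length(x)
  if (l < 2L || length(y) != l || length(z) != l) stop("window too short")
  m <- sqrt(x^2 + y^2 + z^2)
  stats::setNames(
    c(mean(x), mean(y), mean(z), popVar(x), popVar(y), popVar(z),
      safeCorr(x, y), safeCorr(x, z), safeCorr(y, z),
      mean(m), popVar(m), mean(abs(diff(m)))),
    .featureOrder)
}

#' Preprocess a labeled recording into windowed feature vectors
#'
#' Smooths each axis with the causal average filter, enumerates overlapping
#' windows, and computes the 12 features per window together with its
#' majority ground-truth label.
#'
#' @param recording a \code{\link{TriaxialRecording}}.
#' @param labeling an \code{\link{ActivityLabeling}} or \code{NULL}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return A list with elements \code{features} (numeric matrix, one row per
#'   window, 12 columns), \code{windows} (the \code{\link{makeWindows}}
#'   data.frame) and \code{runId}.
#' @export
featurizeRecording <- function(recording, labeling = NULL,
                               config = preprocessConfig()) {
  xs <- smoothSignal(recording@x, config$smoothing_n)
  ys <- smoothSignal(recording@y, config$smoothing_n)
  zs <- smoothSignal(recording@z, config$smoothing_n)
  win <- makeWindows(recording, labeling, config)
  feats <- matrix(NA_real_, nrow(win), length(.featureOrder),
                  dimnames = list(NULL, .featureOrder))
  for (i in seq_len(nrow(win))) {
    idx <- (win$start[i] + 1L):win$end[i]
    feats[i, ] <- extractFeatures(xs[idx], ys[idx], zs[idx])
  }
  list(features = feats, windows = win, runId = runId(recording))
}
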