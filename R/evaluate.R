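#' @include decode.R subclass.R config.R
NULL

#' Pooled confusion matrix from truth/prediction label vectors
#'
#' @param truth,predicted character vectors of equal length.
#' @param classes optional fixed class ordering; defaults to the sorted
#'   union of both vectors.
#' @return Integer matrix of counts, rows = truth, columns = prediction.
#' @export
confusionMatrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  as.matrix(table(factor(truth, levels = classes),
                  factor(predicted, levels = classes)))
}

#' Per-class sensitivity (true positive rate)
#'
#' Diagonal count over row sum of a confusion matrix; classes with an empty
#' truth row are reported as \code{NA}.
#'
#' @param confusion a square count matrix, rows = truth.
#' @return Named numeric vector in \code{[0, 1]} (or \code{NA}).
#' @export
sensitivity <- function(confusion) {
  rs <- rowSums(confusion)
  out <- diag(as.matrix(confusion)) / rs
  out[rs == 0] <- NA_real_
  out
}

## fit the training half of the pipeline (codebook -> sequences ->
## subclassing -> model) on featurized runs; returns everything needed to
## decode a new run
fitPipeline <- function(featurized, config) {
  feats <- do.call(rbind, lapply(featurized, `[[`, "features"))
  codebook <- fitCodebook(feats, M = config$M, seed = config$seed,
                          n_restarts = config$n_restarts)
  seqs <- lapply(featurized, function(f) quantizeRun(codebook, f))
  subclassMap <- NULL
  trainSeqs <- seqs
  if (config$subclass_method != "none") {
    subclassMap <- findSubclasses(seqs, method = config$subclass_method,
                                  maxK = config$subclass_maxK,
                                  seed = config$seed,
                                  fixed = config$subclass_fixed)
    trainSeqs <- applySubclasses(subclassMap, seqs)
  }
  model <- trainModel(trainSeqs, M = config$M, k = config$kmer_k,
                      alpha = config$alpha, transitions = config$transitions,
                      weights = config$weights)
  list(codebook = codebook, model = model, subclassMap = subclassMap)
}

## decode one featurized run and map subclasses back to original classes
predictRun <- function(fit, featurized, method) {
  ps <- quantizeRun(fit$codebook, featurized)
  res <- decodeMethod(fit$model, ps, method)
  pred <- res@path
  if (!is.null(fit$subclassMap)) pred <- mapBack(fit$subclassMap, pred)
  list(predicted = pred, truth = activityLabels(ps), result = res)
}

#' Leave-one-day-out evaluation of the full pipeline
#'
#' For each run (day) \code{i}, trains the complete pipeline -- codebook,
#' probability tables, minimum-run-length array, optional subclassing -- on
#' all other runs, decodes day \code{i}, maps subclass predictions back to
#' original classes and scores them. Accuracy is the fraction of window
#' positions whose predicted class equals the ground truth, with
#' \code{"not_tagged"} counted as an ordinary class.
#'
#' @param runs list of runs, each a list with elements \code{recording} (a
#'   \code{\link{TriaxialRecording}}) and \code{labeling} (an
#'   \code{\link{ActivityLabeling}}); at least 2.
#' @param config a \code{\link{pipelineConfig}}.
#' @param methods subset of \code{c("hmm", "hmm_c", "crf")}; each fold's
#'   fitted pipeline is shared across methods.
#' @return A list per method, each with \code{perDay} (named numeric
#'   accuracies), \code{accuracy} (pooled over all test positions),
#'   \code{confusion} (pooled count matrix) and \code{sensitivity}.
#' @export
leaveOneDayOut <- function(runs, config = pipelineConfig(),
                           methods = c("hmm", "hmm_c", "crf")) {
  if (length(runs) < 2L) stop("leave-one-day-out needs at least 2 runs")
  methods <- match.arg(methods, several.ok = TRUE)
  # process runs in runId order so results do not depend on input order
  runs <- runs[order(vapply(runs, function(r) runId(r$recording),
                            character(1)))]
  featurized <- lapply(runs, function(r)
    featurizeRecording(r$recording, r$labeling, config$preprocess))
  classes <- sort(unique(unlist(lapply(featurized,
                                       function(f) f$windows$label))))
  acc <- lapply(methods, function(m) numeric(0))
  names(acc) <- methods
  conf <- lapply(methods, function(m)
    matrix(0L, length(classes), length(classes),
           dimnames = list(classes, classes)))
  names(conf) <- methods
  for (i in seq_along(runs)) {
    fit <- fitPipeline(featurized[-i], config)
    for (m in methods) {
      p <- predictRun(fit, featurized[[i]], m)
      day <- featurized[[i]]$runId
      acc[[m]][day] <- mean(p$predicted == p$truth)
      conf[[m]] <- conf[[m]] + confusionMatrix(p$truth, p$predicted, classes)
    }
  }
  out <- lapply(methods, function(m) {
    list(perDay = acc[[m]],
         accuracy = sum(diag(conf[[m]])) / sum(conf[[m]]),
         confusion = conf[[m]],
         sensitivity = sensitivity(conf[[m]]))
  })
  names(out) <- methods
  out
}

## time-of-day bin index per window start time (seconds since midnight)
timeBins <- function(time, bin_s) as.integer(time %% 86400 %/% bin_s) + 1L

#' Clock-time-only baselines
#'
#' Evaluates how far time of day alone predicts the activity, under
#' leave-one-day-out. \code{mode = "argmax"} predicts, for each time bin,
#' the class most frequent in that bin in training. \code{mode = "hmm"}
#' treats the time bins as the observations of an HMM over activities and
#' decodes each test day with the standard Viterbi algorithm.
#'
#' @param runs as in \code{\link{leaveOneDayOut}}.
#' @param mode \code{"argmax"} or \code{"hmm"}.
#' @param config a \code{\link{pipelineConfig}} (uses the preprocessing
#'   windows, \code{time_bin_s} and \code{alpha}).
#' @return List with \code{perDay} accuracies and pooled \code{accuracy}.
#' @export
timeOfDayBaseline <- function(runs, mode = c("argmax", "hmm"),
                              config = pipelineConfig()) {
  mode <- match.arg(mode)
  if (length(runs) < 2L) stop("leave-one-day-out needs at least 2 runs")
  wins <- lapply(runs, function(r)
    makeWindows(r$recording, r$labeling, config$preprocess))
  nbins <- as.integer(ceiling(86400 / config$time_bin_s))
  binSeqs <- lapply(seq_along(runs), function(i)
    PrimitiveSequence(runs[[i]]$recording@runId,
                      timeBins(wins[[i]]$time, config$time_bin_s),
                      labels = wins[[i]]$label, time = wins[[i]]$time,
                      M = nbins))
  perDay <- numeric(0)
  total <- 0L; correct <- 0L
  for (i in seq_along(runs)) {
    train <- binSeqs[-i]; test <- binSeqs[[i]]
    if (mode == "argmax") {
      lab <- unlist(lapply(train, activityLabels))
      bin <- unlist(lapply(train, primitives))
      overall <- names(which.max(table(lab)))
      perBin <- vapply(seq_len(nbins), function(b) {
        x <- lab[bin == b]
        if (!length(x)) overall else names(which.max(table(x)))
      }, character(1))
      pred <- perBin[primitives(test)]
    } else {
      model <- trainModel(train, M = nbins, k = 1L, alpha = config$alpha)
      pred <- viterbiDecode(model, test, "hmm")@path
    }
    ok <- sum(pred == activityLabels(test))
    perDay[runId(test)] <- ok / nSamples(test)
    correct <- correct + ok; total <- total + nSamples(test)
  }
  list(perDay = perDay, accuracy = correct / total)
}
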