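#' @include AllClasses.R
NULL

## Multinomial naive Bayes on primitive-count vectors, with Laplace
## smoothing; the fast stand-in classifier used inside the subclass search
## (building the full sequence models maxK times per class would be far
## slower). Hand-rolled: ~20 lines, no multinomial NB among the package's
## dependencies.

#' Fit a multinomial naive Bayes classifier on count vectors
#'
#' @param counts numeric matrix, one instance per row (primitive counts or
#'   any non-negative weights).
#' @param classes character class label per row.
#' @param laplace additive smoothing pseudocount (default 1).
#' @return A list with log class priors and per-class log symbol
#'   probabilities, for \code{\link{predictNaiveBayes}}.
#' @export
fitNaiveBayes <- function(counts, classes, laplace = 1) {
  counts <- as.matrix(counts)
  cls <- sort(unique(classes))
  logPrior <- log(table(factor(classes, levels = cls)) / length(classes))
  logP <- t(vapply(cls, function(cl) {
    s <- colSums(counts[classes == cl, , drop = FALSE])
    log((s + laplace) / (sum(s) + laplace * ncol(counts)))
  }, numeric(ncol(counts))))
  list(classes = cls, logPrior = as.numeric(logPrior), logP = logP)
}

#' Predict classes with a fitted multinomial naive Bayes model
#'
#' @param fit result of \code{\link{fitNaiveBayes}}.
#' @param counts numeric matrix of instances (rows).
#' @return Character vector of predicted class labels (ties to the first
#'   class in sorted order).
#' @export
predictNaiveBayes <- function(fit, counts) {
  counts <- as.matrix(counts)
  scores <- counts %*% t(fit$logP)           # n x K
  scores <- sweep(scores, 2L, fit$logPrior, `+`)
  fit$classes[apply(scores, 1L, which.max)]
}

## Leave-one-instance-out naive Bayes accuracy; `truth` may differ from the
## training labels (used to score subclass candidates against the original
## classes after map-back).
looNaiveBayesAccuracy <- function(counts, trainLabels, truth = trainLabels,
                                  mapback = NULL) {
  n <- nrow(counts)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fitNaiveBayes(counts[-i, , drop = FALSE], trainLabels[-i])
    pred[i] <- predictNaiveBayes(fit, counts[i, , drop = FALSE])
  }
  if (!is.null(mapback)) pred <- mapback(pred)
  mean(pred == truth)
}
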