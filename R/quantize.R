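#' @include AllClasses.R
NULL

## k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
## each next center drawn with probability proportional to squared distance
## to the nearest chosen center.
kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)       # degenerate: all points coincide
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

## Lloyd k-means from given centers; empty clusters are re-seeded from the
## point farthest from its assigned center
lloydFit <- function(X, centers, iter.max = 300L) {
  repeat {
    fit <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = iter.max,
                    algorithm = "Lloyd"))
    if (all(fit$size > 0L)) return(fit)
    empty <- which(fit$size == 0L)
    d2 <- rowSums((X - fit$centers[fit$cluster, , drop = FALSE])^2)
    for (e in empty) {
      far <- which.max(d2)
      fit$centers[e, ] <- X[far, ]
      d2[far] <- 0
    }
    centers <- fit$centers
  }
}

#' Learn a primitive codebook by k-means vector quantization
#'
#' Clusters the training feature vectors into \code{M} groups with k-means
#' (k-means++ initialisation, Lloyd iterations, best of \code{n_restarts}
#' runs by within-cluster sum of squares). Each centroid becomes one motion
#' primitive; the clustering is performed on the training set only. Features
#' are used unscaled by default; set \code{standardize = TRUE} to z-score
#' them first (the scaling is then stored and re-applied at assignment).
#'
#' @param train_features numeric matrix of training feature vectors (rows) or
#'   a list of numeric vectors.
#' @param M alphabet size: the number of primitives (the reference
#'   configuration uses 300; smaller values suit smaller datasets).
#' @param seed integer seed; the fit is bit-reproducible given the seed.
#' @param n_restarts number of independent k-means runs (default 10).
#' @param iter.max Lloyd iteration cap per run (default 300).
#' @param standardize z-score features before clustering (default FALSE).
#' @return A \code{\link{Codebook}}.
#' @export
fitCodebook <- function(train_features, M = 300L, seed = 1L,
                        n_restarts = 10L, iter.max = 300L,
                        standardize = FALSE) {
  X <- asFeatureMatrix(train_features)
  M <- as.integer(M)
  if (nrow(X) < M) stop("M exceeds sample count")
  if (nrow(unique(X)) < M) stop("M exceeds distinct sample count")
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0] <- 1
    X <- scale(X, center = center, scale = scale)
  }
  best <- NULL
  withr_seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  for (r in seq_len(n_restarts)) {
    if (M == 1L) {
      fit <- list(centers = matrix(colMeans(X), 1L), tot.withinss =
                    sum(sweep(X, 2L, colMeans(X))^2))
    } else {
      fit <- lloydFit(X, kmeansppCenters(X, M), iter.max = iter.max)
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  centroids <- unname(best$centers)
  if (standardize)
    centroids <- sweep(sweep(centroids, 2L, scale, `*`), 2L, center, `+`)
  colnames(centroids) <- if (!is.null(colnames(X))) colnames(X) else .featureOrder[seq_len(ncol(X))]
  methods::new("Codebook", centroids = centroids, seed = withr_seed,
               featureOrder = colnames(centroids))
}

asFeatureMatrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Assign feature vectors to their nearest primitive
#'
#' Returns the ID of the Euclidean-nearest centroid for each feature vector;
#' ties go to the lowest ID.
#'
#' @param codebook a \code{\link{Codebook}}.
#' @param features a single feature vector or a matrix with one vector per
#'   row.
#' @return Integer vector of primitive IDs in \code{1..M}.
#' @export
assignPrimitive <- function(codebook, features) {
  stopifnot(methods::is(codebook, "Codebook"))
  C <- codebook@centroids
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != ncol(C)) stop("feature dimensionality mismatch")
  # squared distances via the expansion |x - c|^2 = |x|^2 - 2 x.c + |c|^2;
  # the |x|^2 term is constant per row and dropped
  D <- -2 * features %*% t(C)
  D <- sweep(D, 2L, rowSums(C^2), `+`)
  as.integer(apply(D, 1L, which.min))   # which.min takes the lowest ID on ties
}

#' Quantize a featurized run into a primitive sequence
#'
#' @param codebook a \code{\link{Codebook}}.
#' @param featurized result of \code{\link{featurizeRecording}} (features,
#'   windows, runId).
#' @return A \code{\link{PrimitiveSequence}} with per-window labels and
#'   window start times carried through.
#' @export
quantizeRun <- function(codebook, featurized) {
  if (is.null(featurized$features) || nrow(featurized$features) == 0L)
    stop("empty input: no windows to quantize")
  ids <- assignPrimitive(codebook, featurized$features)
  PrimitiveSequence(featurized$runId, ids,
                    labels = featurized$windows$label,
                    time = featurized$windows$time,
                    M = alphabetSize(codebook))
}
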