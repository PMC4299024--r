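#' @include AllClasses.R
NULL

## Cluster validity indices used to choose the number of subclasses. All
## three use Euclidean distance and are larger-is-better except silhouette's
## bounded range. Inputs: a numeric point matrix (rows = observations) and an
## integer/character cluster assignment.

checkClustering <- function(points, assignment) {
  points <- as.matrix(points)
  assignment <- as.vector(assignment)
  if (nrow(points) != length(assignment))
    stop("points and assignment lengths differ")
  cl <- unique(assignment)
  if (length(cl) < 2L) stop("need at least 2 clusters")
  list(points = points, assignment = assignment, clusters = cl)
}

#' Silhouette index
#'
#' Mean over points of \code{(b - a) / max(a, b)} where \code{a} is the mean
#' distance to co-members and \code{b} the smallest mean distance to another
#' cluster. Points in singleton clusters score 0 by convention. Range
#' \code{[-1, 1]}; larger is better.
#'
#' @param points numeric matrix, one observation per row (a vector is taken
#'   as 1-D points).
#' @param assignment cluster label per row; at least 2 non-empty clusters.
#' @return A single numeric value in \code{[-1, 1]}.
#' @examples
#' silhouetteIndex(c(0, 1, 10, 11), c(1, 1, 2, 2))  # ~0.8997
#' @export
silhouetteIndex <- function(points, assignment) {
  z <- checkClustering(points, assignment)
  D <- as.matrix(stats::dist(z$points))
  n <- nrow(D)
  s <- numeric(n)
  for (p in seq_len(n)) {
    own <- z$assignment == z$assignment[p]
    if (sum(own) == 1L) { s[p] <- 0; next }          # singleton convention
    a <- sum(D[p, own]) / (sum(own) - 1L)
    b <- min(vapply(z$clusters[z$clusters != z$assignment[p]],
                    function(cl) mean(D[p, z$assignment == cl]), numeric(1)))
    s[p] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' PBM index
#'
#' \code{((1/K) * (E1/EK) * DK)^2} where \code{E1} is the summed distance of
#' all points to the global centroid, \code{EK} the summed distance of
#' points to their cluster centroid, and \code{DK} the largest pairwise
#' centroid distance. Larger is better; a clustering whose clusters are all
#' collapsed to points (\code{EK = 0}) returns \code{Inf}.
#'
#' @inheritParams silhouetteIndex
#' @return A single positive numeric value (possibly \code{Inf}).
#' @examples
#' pbmIndex(c(0, 1, 10, 11), c(1, 1, 2, 2))  # 2500
#' @export
pbmIndex <- function(points, assignment) {
  z <- checkClustering(points, assignment)
  X <- z$points
  K <- length(z$clusters)
  g <- colMeans(X)
  E1 <- sum(sqrt(rowSums(sweep(X, 2L, g)^2)))
  cent <- vapply(z$clusters, function(cl)
    colMeans(X[z$assignment == cl, , drop = FALSE]), numeric(ncol(X)))
  centroids <- if (is.matrix(cent)) t(cent) else matrix(cent, ncol = 1L)
  EK <- sum(vapply(seq_len(K), function(k) {
    Xi <- X[z$assignment == z$clusters[k], , drop = FALSE]
    sum(sqrt(rowSums(sweep(Xi, 2L, centroids[k, ])^2)))
  }, numeric(1)))
  if (EK == 0) return(Inf)
  DK <- max(stats::dist(centroids))
  ((1 / K) * (E1 / EK) * DK)^2
}

#' Generalized Dunn index, variant (3,3)
#'
#' \code{min_(i != j) delta3(Ci, Cj) / max_i Delta3(Ci)} with between-cluster
#' distance \code{delta3} the mean pairwise distance between members of the
#' two clusters, and cluster diameter \code{Delta3} twice the mean distance
#' of members to their centroid. Larger is better; all-singleton diameters
#' (\code{Delta3 = 0} everywhere) return \code{Inf}.
#'
#' @inheritParams silhouetteIndex
#' @return A single positive numeric value (possibly \code{Inf}).
#' @examples
#' gdi33Index(c(0, 1, 10, 11), c(1, 1, 2, 2))  # 10
#' @export
gdi33Index <- function(points, assignment) {
  z <- checkClustering(points, assignment)
  X <- z$points
  D <- as.matrix(stats::dist(X))
  K <- length(z$clusters)
  diam <- vapply(z$clusters, function(cl) {
    Xi <- X[z$assignment == cl, , drop = FALSE]
    2 * mean(sqrt(rowSums(sweep(Xi, 2L, colMeans(Xi))^2)))
  }, numeric(1))
  if (max(diam) == 0) return(Inf)
  sep <- Inf
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    mi <- z$assignment == z$clusters[i]
    mj <- z$assignment == z$clusters[j]
    sep <- min(sep, mean(D[mi, mj]))
  }
  sep / max(diam)
}
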