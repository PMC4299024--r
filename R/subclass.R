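#' @include quantize.R indices.R naivebayes.R
NULL

#' Primitive histogram of an activity instance
#'
#' Relative frequency of each primitive ID over one activity instance
#' (normalising by length keeps instances of different durations
#' comparable).
#'
#' @param primitives integer primitive IDs in \code{1..M}, non-empty.
#' @param M alphabet size.
#' @return Numeric vector of length \code{M} summing to 1.
#' @examples
#' primitiveHistogram(c(1, 1, 2), M = 3)  # 2/3, 1/3, 0
#' @export
primitiveHistogram <- function(primitives, M) {
  primitives <- as.integer(primitives)
  if (length(primitives) == 0L) stop("empty primitive list")
  if (any(primitives < 1L) || any(primitives > M)) stop("primitive ID out of range")
  tabulate(primitives, nbins = M) / length(primitives)
}

#' Extract activity instances from labeled primitive sequences
#'
#' One instance per maximal run of a label within each run/day: its
#' primitive count vector, histogram, class and location (for later
#' relabeling).
#'
#' @param train list of labeled \code{\link{PrimitiveSequence}} objects.
#' @return A list with \code{counts} (instances x M), \code{hist}
#'   (row-normalized counts), \code{classes}, and \code{where} (data.frame
#'   \code{run}, \code{startPos}, \code{endPos}).
#' @export
activityInstances <- function(train) {
  if (!is.list(train)) train <- list(train)
  M <- alphabetSize(train[[1]])
  rows <- list(); classes <- character(); where <- list()
  for (r in seq_along(train)) {
    lab <- activityLabels(train[[r]])
    prim <- primitives(train[[r]])
    runs <- rle(lab)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in seq_along(runs$values)) {
      rows[[length(rows) + 1L]] <-
        tabulate(prim[starts[i]:ends[i]], nbins = M)
      classes <- c(classes, runs$values[i])
      where[[length(where) + 1L]] <-
        data.frame(run = r, startPos = starts[i], endPos = ends[i])
    }
  }
  counts <- do.call(rbind, rows)
  list(counts = counts, hist = counts / rowSums(counts),
       classes = classes, where = do.call(rbind, where), M = M)
}

## seeded k-means over instance histograms (k-means++ init, few restarts)
clusterHistograms <- function(X, k, seed, n_restarts = 5L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloydFit(X, kmeansppCenters(X, k))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

subclassName <- function(class, j) paste0(class, ".", j)

buildSubclassMap <- function(instances, fragments, assignment) {
  classes <- names(fragments)
  mapRows <- lapply(classes, function(cl) {
    if (fragments[cl] == 1L) data.frame(subclass = cl, original = cl)
    else data.frame(subclass = subclassName(cl, seq_len(fragments[cl])),
                    original = cl)
  })
  methods::new("SubclassMap",
               map = do.call(rbind, mapRows),
               fragments = fragments,
               assignments = cbind(instances$where,
                                   data.frame(original = instances$classes,
                                              subclass = assignment)))
}

#' Search for fragmented classes and subclass them
#'
#' Implements the index-driven subclassing procedure: (1) compute the
#' baseline leave-one-instance-out naive-Bayes accuracy on the original
#' classes; (2) for each class, cluster its instance histograms with k-means
#' for k = 2..maxK and score each k with the chosen cluster validity index;
#' (3) take the index-optimal k as the candidate split; (4) recompute the
#' cross-validated accuracy with the candidate subclasses (predictions
#' mapped back to original classes); (5) keep the split only if it strictly
#' improves the baseline. With \code{method = "fixed"} the per-class
#' fragment counts in \code{fixed} are applied directly, bypassing the index
#' search and the gate (the analogue of choosing counts by visual
#' inspection). The catch-all \code{"not_tagged"} class is eligible like any
#' other.
#'
#' @param train list of labeled \code{\link{PrimitiveSequence}} objects.
#' @param method \code{"silhouette"}, \code{"pbm"}, \code{"gdi33"},
#'   \code{"fixed"} or \code{"none"}.
#' @param maxK upper bound on the number of fragments per class (default 5);
#'   a class with n instances is only probed up to \code{min(maxK, n - 1)}.
#' @param seed integer seed for the clustering restarts.
#' @param fixed named list/vector \code{class -> k} for
#'   \code{method = "fixed"}.
#' @return A \code{\link{SubclassMap}}; attribute \code{"baseline"} carries
#'   the baseline CV accuracy and attribute \code{"accuracy"} the accuracy
#'   under the returned map.
#' @export
findSubclasses <- function(train,
                           method = c("silhouette", "pbm", "gdi33",
                                      "fixed", "none"),
                           maxK = 5L, seed = 1L, fixed = NULL) {
  method <- match.arg(method)
  inst <- activityInstances(train)
  classes <- sort(unique(inst$classes))
  fragments <- stats::setNames(rep(1L, length(classes)), classes)
  assignment <- inst$classes
  identityMap <- function() {
    m <- buildSubclassMap(inst, fragments, assignment)
    base <- looNaiveBayesAccuracy(inst$counts, inst$classes)
    attr(m, "baseline") <- base; attr(m, "accuracy") <- base
    m
  }
  if (method == "none" || maxK < 2L) return(identityMap())

  if (method == "fixed") {
    for (cl in names(fixed)) {
      k <- as.integer(fixed[[cl]])
      idx <- which(inst$classes == cl)
      if (k < 2L || length(idx) < k) next
      grp <- clusterHistograms(inst$hist[idx, , drop = FALSE], k, seed)
      fragments[cl] <- k
      assignment[idx] <- subclassName(cl, grp)
    }
    m <- buildSubclassMap(inst, fragments, assignment)
    attr(m, "baseline") <- looNaiveBayesAccuracy(inst$counts, inst$classes)
    attr(m, "accuracy") <- subclassCvAccuracy(inst, assignment, m)
    return(m)
  }

  indexFun <- switch(method, silhouette = silhouetteIndex,
                     pbm = pbmIndex, gdi33 = gdi33Index)
  baseline <- looNaiveBayesAccuracy(inst$counts, inst$classes)
  for (cl in classes) {
    idx <- which(inst$classes == cl)
    n_i <- length(idx)
    X <- inst$hist[idx, , drop = FALSE]
    kmax <- min(maxK, n_i - 1L, nrow(unique(X)))
    if (kmax < 2L) next
    scores <- rep(-Inf, kmax)
    groups <- vector("list", kmax)
    for (k in 2:kmax) {
      grp <- clusterHistograms(X, k, seed + k)
      groups[[k]] <- grp
      scores[k] <- indexFun(X, grp)
    }
    kBest <- which.max(scores)              # ties toward smaller k
    # each class's candidate is judged in isolation against the step-1
    # baseline, so one class's gain cannot smuggle another's split through
    candAssign <- inst$classes
    candAssign[idx] <- subclassName(cl, groups[[kBest]])
    candFrag <- stats::setNames(rep(1L, length(classes)), classes)
    candFrag[cl] <- as.integer(kBest)
    candMap <- buildSubclassMap(inst, candFrag, candAssign)
    acc <- subclassCvAccuracy(inst, candAssign, candMap)
    if (acc > baseline) {                   # the accuracy gate: strict improvement
      fragments[cl] <- as.integer(kBest)
      assignment[idx] <- subclassName(cl, groups[[kBest]])
    }
  }
  m <- buildSubclassMap(inst, fragments, assignment)
  attr(m, "baseline") <- baseline
  attr(m, "accuracy") <- subclassCvAccuracy(inst, assignment, m)
  m
}

## LOO NB accuracy training on (candidate) subclass labels, scored on the
## original classes after map-back
subclassCvAccuracy <- function(inst, assignment, map) {
  looNaiveBayesAccuracy(inst$counts, assignment, truth = inst$classes,
                        mapback = function(p) mapBack(map, p))
}

#' Relabel training sequences with their subclasses
#'
#' Replaces each activity instance's labels in the training runs with its
#' assigned subclass, so models can be trained on the subclasses as if they
#' were independent classes (minimum-run-length constraints are then
#' re-estimated per subclass).
#'
#' @param subclass_map a \code{\link{SubclassMap}} from
#'   \code{\link{findSubclasses}}.
#' @param train the same list of \code{\link{PrimitiveSequence}} objects the
#'   map was built from.
#' @return The list with labels rewritten.
#' @export
applySubclasses <- function(subclass_map, train) {
  if (!is.list(train)) train <- list(train)
  a <- subclass_map@assignments
  for (i in seq_len(nrow(a))) {
    s <- train[[a$run[i]]]
    s@labels[a$startPos[i]:a$endPos[i]] <- a$subclass[i]
    train[[a$run[i]]] <- s
  }
  train
}

#' Map predicted subclass labels back to original classes
#'
#' @param subclass_map a \code{\link{SubclassMap}}.
#' @param predictions character vector of predicted subclass labels; every
#'   label must appear in the map.
#' @return Character vector of original class labels.
#' @examples
#' \dontrun{mapBack(m, c("commuting.2", "working", "commuting.1"))}
#' @export
mapBack <- function(subclass_map, predictions) {
  idx <- match(predictions, subclass_map@map$subclass)
  if (anyNA(idx))
    stop("unknown subclass label: ",
         paste(unique(predictions[is.na(idx)]), collapse = ", "))
  subclass_map@map$original[idx]
}
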