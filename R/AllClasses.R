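#' @include AllGenerics.R
NULL

## Central containers. All are plain S4 value classes with validity checks;
## numeric slots use base vectors/matrices so objects serialize to CSV/JSON
## without loss.

#' TriaxialRecording: one continuous accelerometer run
#'
#' Timestamped x/y/z acceleration (in g) for a single recording session,
#' typically one day of wear.
#'
#' @slot runId length-one character identifier.
#' @slot time numeric, strictly increasing timestamps in seconds.
#' @slot x,y,z numeric acceleration per axis, in g, same length as
#'   \code{time}.
#' @export
setClass("TriaxialRecording",
  representation(runId = "character", time = "numeric",
                 x = "numeric", y = "numeric", z = "numeric"))

setValidity("TriaxialRecording", function(object) {
  n <- length(object@time)
  if (n < 1L) return("recording must contain at least one sample")
  if (length(object@runId) != 1L) return("runId must be length one")
  if (length(object@x) != n || length(object@y) != n || length(object@z) != n)
    return("time, x, y, z must have equal length")
  if (n > 1L && any(diff(object@time) <= 0))
    return("timestamps must be strictly increasing")
  if (!all(is.finite(c(object@x, object@y, object@z))))
    return("acceleration values must be finite")
  TRUE
})

#' ActivityLabeling: labeled time intervals over a recording
#'
#' Ordered, non-overlapping half-open intervals \code{[start, end)} on the
#' same clock as the recording's timestamps. Time not covered by any interval
#' is implicitly the catch-all class \code{"not_tagged"}.
#'
#' @slot runId length-one character identifier of the labeled run.
#' @slot start,end numeric interval bounds in seconds, \code{start < end},
#'   sorted and non-overlapping.
#' @slot activity character activity name per interval.
#' @export
setClass("ActivityLabeling",
  representation(runId = "character", start = "numeric", end = "numeric",
                 activity = "character"))

setValidity("ActivityLabeling", function(object) {
  k <- length(object@start)
  if (length(object@end) != k || length(object@activity) != k)
    return("start, end, activity must have equal length")
  if (k > 0L) {
    if (any(object@end <= object@start)) return("intervals must satisfy start < end")
    if (k > 1L && any(object@start[-1] < object@end[-k]))
      return("intervals must be sorted and non-overlapping")
  }
  TRUE
})

#' Codebook: the primitive alphabet learned by vector quantization
#'
#' M centroids in the 12-dimensional window-feature space; each centroid ID is
#' one motion primitive.
#'
#' @slot centroids numeric matrix, M rows by 12 columns.
#' @slot seed integer seed the k-means fit was run with.
#' @slot featureOrder character names of the 12 feature dimensions.
#' @export
setClass("Codebook",
  representation(centroids = "matrix", seed = "integer",
                 featureOrder = "character"))

setValidity("Codebook", function(object) {
  if (nrow(object@centroids) < 1L) return("codebook needs at least one centroid")
  if (ncol(object@centroids) != length(object@featureOrder))
    return("centroid columns must match featureOrder")
  if (anyDuplicated(object@centroids) > 0)
    return("centroids must be pairwise distinct")
  if (!all(is.finite(object@centroids))) return("centroids must be finite")
  TRUE
})

#' PrimitiveSequence: a run encoded as discrete motion primitives
#'
#' One symbol per feature window, with the window's majority ground-truth
#' label and start time carried along.
#'
#' @slot runId length-one character.
#' @slot primitives integer primitive IDs in \code{1..M}.
#' @slot labels character per-position activity labels.
#' @slot time numeric per-position window start times (seconds).
#' @slot M integer alphabet size the IDs refer to.
#' @export
setClass("PrimitiveSequence",
  representation(runId = "character", primitives = "integer",
                 labels = "character", time = "numeric", M = "integer"))

setValidity("PrimitiveSequence", function(object) {
  t <- length(object@primitives)
  if (t < 1L) return("sequence must be non-empty")
  if (length(object@labels) != t) return("labels and primitives must have equal length")
  if (length(object@time) != t) return("time and primitives must have equal length")
  if (any(object@primitives < 1L) || any(object@primitives > object@M))
    return("primitive IDs must lie in 1..M")
  TRUE
})

#' SequenceModel: all estimated tables shared by HMM and CRF decoding
#'
#' Holds the transition matrix A, emission matrix B, uniform initial
#' distribution pi, per-state k-mer log-probability tables, the per-state
#' minimum-run-length array, and the CRF feature weights.
#'
#' @slot states character state (activity or subclass) names, length N.
#' @slot M integer alphabet size.
#' @slot A numeric N x N transition matrix, rows summing to 1.
#' @slot B numeric N x M emission matrix, rows summing to 1.
#' @slot pi numeric length-N initial distribution (uniform).
#' @slot kmerK integer k of the k-mer feature (default 2).
#' @slot kmerLogp list, one entry per state: a named numeric vector of
#'   log-probabilities for observed k-mers plus a shared \code{default}
#'   log-probability for the unobserved remainder (sparse storage of the
#'   M^k table).
#' @slot kappa integer length-N minimum run lengths, all >= 1.
#' @slot weights numeric length-3 CRF feature weights (omega1, omega2,
#'   omega3), default c(1, 1, 1).
#' @slot alpha numeric additive-smoothing pseudocount used at estimation.
#' @export
setClass("SequenceModel",
  representation(states = "character", M = "integer", A = "matrix",
                 B = "matrix", pi = "numeric", kmerK = "integer",
                 kmerLogp = "list", kappa = "integer", weights = "numeric",
                 alpha = "numeric"))

setValidity("SequenceModel", function(object) {
  n <- length(object@states)
  if (n < 1L) return("model needs at least one state")
  if (anyDuplicated(object@states)) return("state names must be unique")
  if (!all(dim(object@A) == c(n, n))) return("A must be N x N")
  if (!all(dim(object@B) == c(n, object@M))) return("B must be N x M")
  if (length(object@pi) != n) return("pi must have length N")
  if (any(abs(rowSums(object@A) - 1) > 1e-9)) return("rows of A must sum to 1")
  if (any(abs(rowSums(object@B) - 1) > 1e-9)) return("rows of B must sum to 1")
  if (abs(sum(object@pi) - 1) > 1e-9) return("pi must sum to 1")
  if (length(object@kappa) != n || any(object@kappa < 1L))
    return("kappa must have length N with entries >= 1")
  if (length(object@kmerLogp) != n) return("kmerLogp needs one table per state")
  if (length(object@weights) != 3L) return("weights must be length 3")
  TRUE
})

#' SubclassMap: mapping between discovered subclasses and original classes
#'
#' @slot map data.frame with columns \code{subclass} and \code{original};
#'   each subclass maps to exactly one original class. An unsplit class
#'   appears as a single subclass equal to its own name.
#' @slot fragments named integer, chosen number of fragments per original
#'   class (1 means the class was not split).
#' @slot assignments data.frame with one row per training activity instance
#'   (columns \code{run}, \code{startPos}, \code{endPos}, \code{original},
#'   \code{subclass}), used to relabel the training sequences.
#' @export
setClass("SubclassMap",
  representation(map = "data.frame", fragments = "integer",
                 assignments = "data.frame"))

setValidity("SubclassMap", function(object) {
  if (!all(c("subclass", "original") %in% names(object@map)))
    return("map must have columns subclass, original")
  if (anyDuplicated(object@map$subclass)) return("subclass names must be unique")
  if (is.null(names(object@fragments))) return("fragments must be named by class")
  if (any(object@fragments < 1L)) return("fragment counts must be >= 1")
  tab <- table(object@map$original)
  bad <- names(object@fragments)[object@fragments !=
                                   as.integer(tab[names(object@fragments)])]
  if (length(bad)) return(paste("fragment counts disagree with map for:",
                                paste(bad, collapse = ", ")))
  TRUE
})

#' DecodeResult: the best state path for one observation sequence
#'
#' @slot path character decoded state per position.
#' @slot stateIndex integer decoded state index per position.
#' @slot score numeric log-domain score of the path (unnormalized for the
#'   CRF scoring).
#' @export
setClass("DecodeResult",
  representation(path = "character", stateIndex = "integer",
                 score = "numeric"))

## ---- accessors ----

#' @describeIn TriaxialRecording run identifier
#' @param x a \code{TriaxialRecording}
#' @export
setMethod("runId", "TriaxialRecording", function(x) x@runId)

#' @describeIn PrimitiveSequence run identifier
#' @param x a \code{PrimitiveSequence}
#' @export
setMethod("runId", "PrimitiveSequence", function(x) x@runId)

#' @describeIn TriaxialRecording number of samples
#' @export
setMethod("nSamples", "TriaxialRecording", function(x) length(x@time))

#' @describeIn PrimitiveSequence number of positions
#' @export
setMethod("nSamples", "PrimitiveSequence", function(x) length(x@primitives))

#' @describeIn SequenceModel state names
#' @param x a \code{SequenceModel}
#' @export
setMethod("states", "SequenceModel", function(x) x@states)

#' @describeIn SequenceModel number of states
#' @export
setMethod("nStates", "SequenceModel", function(x) length(x@states))

#' @describeIn SequenceModel alphabet size
#' @export
setMethod("alphabetSize", "SequenceModel", function(x) x@M)

#' @describeIn Codebook alphabet size (number of centroids)
#' @param x a \code{Codebook}
#' @export
setMethod("alphabetSize", "Codebook", function(x) nrow(x@centroids))

#' @describeIn PrimitiveSequence alphabet size
#' @export
setMethod("alphabetSize", "PrimitiveSequence", function(x) x@M)

#' @describeIn PrimitiveSequence primitive IDs
#' @export
setMethod("primitives", "PrimitiveSequence", function(x) x@primitives)

#' @describeIn PrimitiveSequence per-position labels
#' @export
setMethod("activityLabels", "PrimitiveSequence", function(x) x@labels)

#' @describeIn SequenceModel minimum run lengths (kappa array)
#' @export
setMethod("minRunLengths", "SequenceModel",
          function(x) stats::setNames(x@kappa, x@states))

## ---- show methods ----

setMethod("show", "TriaxialRecording", function(object) {
  cat("TriaxialRecording '", object@runId, "': ", length(object@time),
      " samples, ", sprintf("%.1f", diff(range(object@time))), " s span\n",
      sep = "")
})

setMethod("show", "ActivityLabeling", function(object) {
  cat("ActivityLabeling '", object@runId, "': ", length(object@start),
      " intervals, ", length(unique(object@activity)), " activities\n",
      sep = "")
})

setMethod("show", "Codebook", function(object) {
  cat("Codebook: M =", nrow(object@centroids), "primitives in",
      ncol(object@centroids), "feature dimensions\n")
})

setMethod("show", "PrimitiveSequence", function(object) {
  cat("PrimitiveSequence '", object@runId, "': T = ",
      length(object@primitives), ", M = ", object@M, ", labels: ",
      paste(utils::head(unique(object@labels), 6), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "SequenceModel", function(object) {
  cat("SequenceModel: N =", length(object@states), "states, M =", object@M,
      "primitives, k =", object@kmerK, "\n")
  cat("  states:", paste(object@states, collapse = ", "), "\n")
  cat("  kappa: ", paste(object@kappa, collapse = ", "),
      "  weights: ", paste(object@weights, collapse = ", "), "\n", sep = "")
})

setMethod("show", "SubclassMap", function(object) {
  split <- names(object@fragments)[object@fragments > 1L]
  cat("SubclassMap:", nrow(object@map), "subclasses over",
      length(object@fragments), "classes;",
      if (length(split)) paste("split:", paste(split, collapse = ", "))
      else "no class split", "\n")
})

setMethod("show", "DecodeResult", function(object) {
  runs <- rle(object@path)
  cat("DecodeResult: T =", length(object@path), ", score =",
      format(object@score), "\n  segments:",
      paste(sprintf("%s(%d)", runs$values, runs$lengths), collapse = " "),
      "\n")
})

## ---- constructors ----

#' Create a TriaxialRecording
#'
#' @param runId identifier for the run (e.g., the day).
#' @param time numeric timestamps in seconds, strictly increasing.
#' @param x,y,z numeric per-axis acceleration in g.
#' @return A validated \code{TriaxialRecording}.
#' @examples
#' rec <- TriaxialRecording("day1", time = (0:99) / 20,
#'                          x = rnorm(100), y = rnorm(100), z = rnorm(100))
#' nSamples(rec)
#' @export
TriaxialRecording <- function(runId, time, x, y, z) {
  if (length(time) == 0L) stop("empty input")
  methods::new("TriaxialRecording", runId = as.character(runId),
               time = as.numeric(time), x = as.numeric(x),
               y = as.numeric(y), z = as.numeric(z))
}

#' Create an ActivityLabeling
#'
#' @param runId identifier of the labeled run.
#' @param start,end numeric half-open interval bounds in seconds.
#' @param activity character activity name per interval.
#' @return A validated \code{ActivityLabeling}.
#' @export
ActivityLabeling <- function(runId, start = numeric(), end = numeric(),
                             activity = character()) {
  o <- order(start)
  methods::new("ActivityLabeling", runId = as.character(runId),
               start = as.numeric(start)[o], end = as.numeric(end)[o],
               activity = as.character(activity)[o])
}

#' Create a PrimitiveSequence
#'
#' @param runId identifier of the run.
#' @param primitives integer primitive IDs in \code{1..M}.
#' @param labels character per-position labels (defaults to
#'   \code{"not_tagged"}).
#' @param time numeric per-position window start times (defaults to
#'   position index).
#' @param M alphabet size (defaults to \code{max(primitives)}).
#' @return A validated \code{PrimitiveSequence}.
#' @export
PrimitiveSequence <- function(runId, primitives,
                              labels = rep("not_tagged", length(primitives)),
                              time = seq_along(primitives) - 1,
                              M = max(primitives)) {
  methods::new("PrimitiveSequence", runId = as.character(runId),
               primitives = as.integer(primitives),
               labels = as.character(labels), time = as.numeric(time),
               M = as.integer(M))
}
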