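#' Run identifier of an object
#'
#' Accessor for the run (recording session, typically one day) an object
#' belongs to.
#'
#' @param x an object with a run identifier.
#' @return A length-one character vector.
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' Number of samples / positions in an object
#'
#' @param x an object with a natural length (samples for a recording,
#'   positions for a primitive sequence).
#' @return A single integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Activity state names of a model
#'
#' @param x a fitted sequence model.
#' @return Character vector of state names, in model order.
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Number of activity states
#'
#' @param x a fitted sequence model.
#' @return A single integer.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' Codebook / alphabet size
#'
#' Number of motion primitives (distinct observation symbols) an object is
#' defined over.
#'
#' @param x a codebook, primitive sequence, or sequence model.
#' @return A single integer.
#' @export
setGeneric("alphabetSize", function(x) standardGeneric("alphabetSize"))

#' Per-position primitive IDs
#'
#' @param x a \code{PrimitiveSequence}.
#' @return Integer vector of primitive IDs in \code{1..M}.
#' @export
setGeneric("primitives", function(x) standardGeneric("primitives"))

#' Per-position activity labels
#'
#' @param x a \code{PrimitiveSequence}.
#' @return Character vector, same length as \code{primitives(x)}.
#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))

#' Minimum-run-length constraints of a model
#'
#' Per-state minimum number of consecutive positions a decoded activity run
#' must span (the k-minimum-consecutive-states constraint, estimated from the
#' shortest training episode of each activity divided by two).
#'
#' @param x a fitted sequence model.
#' @return Named integer vector, one entry per state, all \eqn{\ge 1}.
#' @export
setGeneric("minRunLengths", function(x) standardGeneric("minRunLengths"))
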