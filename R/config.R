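#' @include preprocess.R
NULL

#' Full pipeline configuration
#'
#' Collects every tunable of the segmentation pipeline in one validated
#' object. Defaults follow the reference configuration (M = 300 primitives,
#' k = 2 for k-mers, smoothing window 10 samples, 60-sample windows with 33
#' percent overlap at 20 Hz); smaller datasets typically want a smaller
#' \code{M}.
#'
#' @param preprocess a \code{\link{preprocessConfig}}.
#' @param M codebook size (number of primitives).
#' @param kmer_k k-mer length for the CRF sequence-pattern feature.
#' @param alpha additive-smoothing pseudocount for all probability tables.
#' @param weights numeric length-3 CRF feature weights.
#' @param transitions \code{"learned"} or \code{"uniform"}.
#' @param subclass_method \code{"none"}, \code{"fixed"}, \code{"silhouette"},
#'   \code{"pbm"} or \code{"gdi33"}.
#' @param subclass_maxK upper bound on fragments per class.
#' @param subclass_fixed named list \code{class -> k} for the fixed mode.
#' @param seed root seed; stage seeds are derived from it.
#' @param n_restarts k-means restarts for the codebook fit.
#' @param time_bin_s width of the time-of-day bins for the clock baselines,
#'   in seconds (default 900, i.e. 15 min).
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(preprocess = preprocessConfig(),
                           M = 300L, kmer_k = 2L, alpha = 1,
                           weights = c(1, 1, 1),
                           transitions = c("learned", "uniform"),
                           subclass_method = c("none", "fixed", "silhouette",
                                               "pbm", "gdi33"),
                           subclass_maxK = 5L, subclass_fixed = NULL,
                           seed = 1L, n_restarts = 10L, time_bin_s = 900) {
  transitions <- match.arg(transitions)
  subclass_method <- match.arg(subclass_method)
  stopifnot(M >= 1L, kmer_k >= 1L, alpha >= 0, length(weights) == 3L,
            subclass_maxK >= 1L, time_bin_s > 0)
  structure(list(preprocess = preprocess, M = as.integer(M),
                 kmer_k = as.integer(kmer_k), alpha = alpha,
                 weights = as.numeric(weights), transitions = transitions,
                 subclass_method = subclass_method,
                 subclass_maxK = as.integer(subclass_maxK),
                 subclass_fixed = subclass_fixed,
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 time_bin_s = time_bin_s),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys raise an error naming the key; all values are validated by
#' \code{\link{pipelineConfig}}.
#'
#' @param path YAML file path.
#' @return A \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pre <- y$preprocess
  y$preprocess <- NULL
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  preArgs <- if (is.null(pre)) list() else pre
  badPre <- setdiff(names(preArgs), names(formals(preprocessConfig)))
  if (length(badPre))
    stop("unknown preprocess key(s): ", paste(badPre, collapse = ", "))
  y$preprocess <- do.call(preprocessConfig, preArgs)
  do.call(pipelineConfig, y)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a \code{"PipelineConfig"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  out <- unclass(config)
  out$preprocess <- out$preprocess[c("smoothing_n", "window_length_l",
                                     "overlap_fraction")]
  yaml::write_yaml(out, path)
  invisible(path)
}
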