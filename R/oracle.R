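#' @include decode.R
NULL

#' Brute-force decoding by exhaustive path enumeration
#'
#' Scores every one of the \code{N^T} state paths with
#' \code{\link{hmmScore}} or \code{\link{crfScore}} and returns the argmax,
#' optionally restricted to paths satisfying the minimum-run-length
#' constraint. Intended as an independent test oracle for the dynamic
#' programming decoders; only usable at toy sizes.
#'
#' @param model a \code{\link{SequenceModel}}.
#' @param observations integer primitive IDs.
#' @param scoring \code{"hmm"} or \code{"crf"}.
#' @param constrained if \code{TRUE}, paths violating the model's kappa
#'   array are excluded.
#' @return A \code{\link{DecodeResult}}, or an error if no feasible path
#'   exists under the constraint.
#' @export
enumerateDecode <- function(model, observations,
                            scoring = c("hmm", "crf"),
                            constrained = FALSE) {
  scoring <- match.arg(scoring)
  obs <- as.integer(observations)
  T <- length(obs)
  N <- nStates(model)
  if (N^T > 2e6) stop("instance too large for exhaustive enumeration")
  scorer <- if (scoring == "hmm") hmmScore else crfScore
  grid <- as.matrix(expand.grid(rep(list(seq_len(N)), T))[, T:1, drop = FALSE])
  best <- NULL; bestScore <- -Inf
  for (p in seq_len(nrow(grid))) {
    path <- grid[p, ]
    if (constrained && !pathSatisfiesKappa(path, model@kappa)) next
    s <- scorer(model, obs, path)
    if (s > bestScore) { bestScore <- s; best <- path }
  }
  if (is.null(best)) stop("infeasible constraint for T")
  methods::new("DecodeResult", path = states(model)[best],
               stateIndex = as.integer(best), score = bestScore)
}
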