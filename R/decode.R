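#' @include models.R
NULL

## ---- score tables -------------------------------------------------------
## Both decoders maximise a sum of per-position "emission-like" terms E[i,t]
## plus transition terms LA[i,j] and an initial term lpi[i]. For HMM scoring
## these are the log probability tables; for CRF scoring they are the
## weighted feature functions: f1 (emission log-prob, weight w1), f2
## (transition / initial log-prob, weight w2) and f3 (k-mer log-prob, weight
## w3). f3 depends only on the observations and the state at t, so it folds
## into E; at the last k-1 positions the k-mer would extend past T and f3
## contributes 0.

scoreTables <- function(model, obs, scoring = c("hmm", "crf")) {
  scoring <- match.arg(scoring)
  obs <- as.integer(obs)
  if (any(obs < 1L) || any(obs > model@M)) stop("unknown primitive ID")
  N <- nStates(model)
  logBfull <- log(model@B)                      # N x M
  logB <- logBfull[, obs, drop = FALSE]         # N x T
  if (scoring == "hmm") {
    return(list(E = logB, LA = log(model@A), lpi = log(model@pi)))
  }
  w <- model@weights
  T <- length(obs)
  # a zero weight switches its feature off entirely (never 0 * -Inf = NaN)
  E <- matrix(0, N, T)
  if (w[1] != 0) E <- E + w[1] * logB
  if (w[3] != 0) {
    k <- model@kmerK
    f3 <- matrix(0, N, T)
    keys <- kmerKeys(obs, k)
    ok <- which(!is.na(keys))
    # log of the independence product over each position's k-mer symbols,
    # used by the emission back-off for k-mers unseen in training
    prodLogB <- matrix(0, N, length(ok))
    for (j in seq_len(k)) prodLogB <- prodLogB + logBfull[, obs[ok + j - 1L],
                                                          drop = FALSE]
    for (i in seq_len(N)) {
      tab <- model@kmerLogp[[i]]
      v <- unname(tab$logp[keys[ok]])
      v[is.na(v)] <- tab$default
      if (!is.null(tab$lambda)) {
        # Witten-Bell interpolation with the emission product (see
        # addKmerInterpolation): sparse states lean on the product term
        v <- log(tab$lambda * exp(v) +
                   (1 - tab$lambda) * exp(prodLogB[i, ]))
      }
      f3[i, ok] <- v
    }
    E <- E + w[3] * f3
  }
  list(E = E,
       LA = if (w[2] != 0) w[2] * log(model@A) else matrix(0, N, N),
       lpi = if (w[2] != 0) w[2] * log(model@pi) else rep(0, N))
}

pathToIndex <- function(model, path) {
  if (is.character(path)) {
    idx <- match(path, states(model))
    if (anyNA(idx)) stop("unknown state: ",
                         paste(unique(path[is.na(idx)]), collapse = ", "))
  } else {
    idx <- as.integer(path)
    if (any(idx < 1L) || any(idx > nStates(model))) stop("unknown state index")
  }
  idx
}

#' Joint HMM log-probability of a path
#'
#' \code{log pi(q1) + sum_t log B[q_t, o_t] + sum_(t>=2) log A[q_(t-1), q_t]}.
#'
#' @param model a \code{\link{SequenceModel}}.
#' @param observations integer primitive IDs.
#' @param path state names (or indices), same length as \code{observations}.
#' @return A single numeric log-probability (\code{-Inf} if any factor is 0).
#' @export
hmmScore <- function(model, observations, path) {
  idx <- pathToIndex(model, path)
  obs <- as.integer(observations)
  if (length(idx) != length(obs)) stop("path and observations lengths differ")
  if (any(obs < 1L) || any(obs > model@M)) stop("unknown primitive ID")
  T <- length(obs)
  s <- log(model@pi[idx[1]]) + sum(log(model@B[cbind(idx, obs)]))
  if (T > 1L) s <- s + sum(log(model@A[cbind(idx[-T], idx[-1L])]))
  s
}

#' Unnormalized CRF score of a path
#'
#' Sum over positions of the three weighted feature functions: w1 times the
#' emission log-probability, w2 times the transition log-probability (the
#' initial log-probability at t = 1), and w3 times the log-probability of
#' the k-mer starting at t given the state at t (0 at the last k-1
#' positions, where the k-mer would extend past the sequence). With weights
#' \code{c(1, 1, 0)} this equals \code{\link{hmmScore}} exactly.
#'
#' @inheritParams hmmScore
#' @return A single numeric score (log-domain, unnormalized: the partition
#'   function Z is never computed since only the argmax is needed).
#' @export
crfScore <- function(model, observations, path) {
  idx <- pathToIndex(model, path)
  obs <- as.integer(observations)
  if (length(idx) != length(obs)) stop("path and observations lengths differ")
  tabs <- scoreTables(model, obs, "crf")
  T <- length(obs)
  s <- tabs$lpi[idx[1]] + sum(tabs$E[cbind(idx, seq_len(T))])
  if (T > 1L) s <- s + sum(tabs$LA[cbind(idx[-T], idx[-1L])])
  s
}

#' Viterbi decoding (unconstrained)
#'
#' Finds the state path maximising the HMM joint log-probability or the CRF
#' score by standard dynamic programming. Ties are broken toward the lowest
#' state index.
#'
#' @param model a \code{\link{SequenceModel}}.
#' @param observations integer primitive IDs (or a
#'   \code{\link{PrimitiveSequence}}).
#' @param scoring \code{"hmm"} or \code{"crf"}.
#' @return A \code{\link{DecodeResult}}.
#' @export
viterbiDecode <- function(model, observations, scoring = c("hmm", "crf")) {
  scoring <- match.arg(scoring)
  if (methods::is(observations, "PrimitiveSequence"))
    observations <- primitives(observations)
  obs <- as.integer(observations)
  T <- length(obs)
  if (T < 1L) stop("empty observation sequence")
  tabs <- scoreTables(model, obs, scoring)
  N <- nStates(model)
  delta <- tabs$lpi + tabs$E[, 1L]
  psi <- matrix(0L, N, T)
  if (T > 1L) for (t in 2:T) {
    cand <- tabs$LA + delta                 # [from, to] + delta[from]
    best <- apply(cand, 2L, which.max)      # lowest index wins ties
    delta <- cand[cbind(best, seq_len(N))] + tabs$E[, t]
    psi[, t] <- best
  }
  path <- integer(T)
  path[T] <- which.max(delta)
  if (T > 1L) for (t in T:2) path[t - 1L] <- psi[path[t], t]
  methods::new("DecodeResult", path = states(model)[path],
               stateIndex = path, score = max(delta))
}

#' Duration-constrained Viterbi decoding
#'
#' Finds the best state path among those whose every maximal run of state
#' \code{i} -- including the first and last runs -- lasts at least
#' \code{kappa(i)} positions (the k-minimum-consecutive-states constraint
#' encoding each activity's minimum lifespan). Implemented exactly by
#' dynamic programming over (state, run length capped at kappa) pairs:
#' a transition into a different state is allowed only once the current run
#' has reached its state's kappa.
#'
#' @inheritParams viterbiDecode
#' @return A \code{\link{DecodeResult}} whose path satisfies the run-length
#'   constraint (verified before returning).
#' @export
constrainedViterbi <- function(model, observations,
                               scoring = c("hmm", "crf")) {
  scoring <- match.arg(scoring)
  if (methods::is(observations, "PrimitiveSequence"))
    observations <- primitives(observations)
  obs <- as.integer(observations)
  T <- length(obs)
  if (T < 1L) stop("empty observation sequence")
  kap <- model@kappa
  if (T < min(kap)) stop("infeasible constraint for T")
  tabs <- scoreTables(model, obs, scoring)
  N <- nStates(model)
  d <- lapply(seq_len(N), function(i) {
    v <- rep(-Inf, kap[i]); v[1L] <- tabs$lpi[i] + tabs$E[i, 1L]; v
  })
  capChoice <- matrix(1L, N, T)   # 1: run arrived at kappa; 2: already capped
  entFrom <- matrix(0L, N, T)     # predecessor state for run length 1
  LA <- tabs$LA
  if (T > 1L) for (t in 2:T) {
    exit <- vapply(seq_len(N), function(j) d[[j]][kap[j]], numeric(1))
    nd <- vector("list", N)
    for (i in seq_len(N)) {
      c_i <- kap[i]
      v <- rep(-Inf, c_i)
      aii <- LA[i, i]
      if (c_i > 1L) {
        if (c_i > 2L) v[2:(c_i - 1L)] <- d[[i]][1:(c_i - 2L)] + aii
        top <- c(d[[i]][c_i - 1L], d[[i]][c_i])
        ch <- if (top[1L] >= top[2L]) 1L else 2L
        v[c_i] <- top[ch] + aii
        capChoice[i, t] <- ch
        # entering i restarts its run at length 1
        inc <- exit + LA[, i]
        inc[i] <- -Inf
        j <- which.max(inc)
        v[1L] <- inc[j]
        entFrom[i, t] <- j
      } else {
        # kappa = 1: staying and entering both land on the single level
        inc <- exit + LA[, i]   # j = i is the self-transition (stay)
        j <- which.max(inc)
        v[1L] <- inc[j]
        entFrom[i, t] <- j
      }
      nd[[i]] <- v + tabs$E[i, t]
    }
    d <- nd
  }
  final <- vapply(seq_len(N), function(i) d[[i]][kap[i]], numeric(1))
  if (!any(is.finite(final))) stop("infeasible constraint for T")
  i <- which.max(final)
  score <- final[i]
  # backtrack through (state, capped run length)
  path <- integer(T)
  r <- kap[i]
  for (t in T:1) {
    path[t] <- i
    if (t == 1L) break
    if (r == 1L) {
      j <- entFrom[i, t]
      r <- kap[j]
      i <- j
    } else if (r == kap[i] && capChoice[i, t] == 2L) {
      # stay at the cap: run had already reached kappa before t
    } else {
      r <- r - 1L
    }
  }
  stopifnot(pathSatisfiesKappa(path, kap))   # invariant, checked every decode
  methods::new("DecodeResult", path = states(model)[path],
               stateIndex = path, score = score)
}

#' Check a path against the minimum-run-length constraint
#'
#' @param path integer state indices or character state names.
#' @param kappa integer per-state minimum run lengths (named by state if
#'   \code{path} is character).
#' @return \code{TRUE} if every maximal run of state \code{i} (including the
#'   first and last) has length \code{>= kappa[i]}.
#' @export
pathSatisfiesKappa <- function(path, kappa) {
  r <- rle(as.vector(path))
  need <- if (is.character(r$values)) kappa[r$values] else kappa[r$values]
  all(r$lengths >= need)
}

#' Decode with a named method
#'
#' Convenience dispatcher over the three segmentation methods compared in
#' the evaluation grid: \code{"hmm"} (unconstrained Viterbi, HMM scoring),
#' \code{"hmm_c"} (constrained Viterbi, HMM scoring) and \code{"crf"}
#' (constrained Viterbi, CRF scoring with the k-mer feature).
#'
#' @param model a \code{\link{SequenceModel}}.
#' @param observations integer primitive IDs or a
#'   \code{\link{PrimitiveSequence}}.
#' @param method one of \code{"hmm"}, \code{"hmm_c"}, \code{"crf"}.
#' @return A \code{\link{DecodeResult}}.
#' @export
decodeMethod <- function(model, observations,
                         method = c("hmm", "hmm_c", "crf")) {
  method <- match.arg(method)
  switch(method,
         hmm = viterbiDecode(model, observations, "hmm"),
         hmm_c = constrainedViterbi(model, observations, "hmm"),
         crf = constrainedViterbi(model, observations, "crf"))
}
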