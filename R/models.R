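#' @include AllClasses.R
NULL

## Training data come in as a list of PrimitiveSequence objects (one per
## run/day). All estimators share additive (Laplace) smoothing with
## pseudocount alpha; alpha = 1 by default because with M = 300 primitives
## and k = 2 the 90,000-cell k-mer table is mostly unobserved and the
## feature functions take logs.

checkStates <- function(train, states) {
  seen <- unique(unlist(lapply(train, activityLabels)))
  missing <- setdiff(states, seen)
  if (length(missing))
    stop("state(s) absent from training labels: ",
         paste(missing, collapse = ", "))
}

#' Estimate the emission matrix B
#'
#' \code{B[q, k]} is the smoothed relative frequency of primitive \code{k}
#' among all training positions labeled \code{q}:
#' \code{(count + alpha) / (total + alpha * M)}.
#'
#' @param train list of labeled \code{\link{PrimitiveSequence}} objects.
#' @param states character state names (every one must occur in training).
#' @param M alphabet size.
#' @param alpha additive-smoothing pseudocount (default 1).
#' @return Numeric \code{N x M} matrix with rows summing to 1.
#' @export
estimateEmissions <- function(train, states, M, alpha = 1) {
  checkStates(train, states)
  M <- as.integer(M)
  lab <- unlist(lapply(train, activityLabels))
  obs <- unlist(lapply(train, primitives))
  B <- matrix(0, length(states), M, dimnames = list(states, NULL))
  for (q in states) {
    cnt <- tabulate(obs[lab == q], nbins = M)
    B[q, ] <- (cnt + alpha) / (sum(cnt) + alpha * M)
  }
  B
}

#' Estimate the transition matrix A and initial distribution pi
#'
#' In \code{"learned"} mode, \code{A[i, j]} is the smoothed frequency of
#' adjacent label pairs \code{i -> j} within each training run (self
#' transitions dominate, since long-term activities span many windows). In
#' \code{"uniform"} mode every entry is \code{1/N}, representing a lack of
#' information about activity ordering. The initial distribution is always
#' uniform.
#'
#' @param train list of labeled \code{\link{PrimitiveSequence}} objects.
#' @param states character state names.
#' @param alpha additive-smoothing pseudocount (default 1).
#' @param mode \code{"learned"} or \code{"uniform"}.
#' @return List with elements \code{A} (\code{N x N}, rows sum to 1) and
#'   \code{pi} (uniform, length N).
#' @export
estimateTransitions <- function(train, states, alpha = 1,
                                mode = c("learned", "uniform")) {
  mode <- match.arg(mode)
  N <- length(states)
  pi <- rep(1 / N, N)
  if (mode == "uniform")
    return(list(A = matrix(1 / N, N, N, dimnames = list(states, states)),
                pi = pi))
  cnt <- matrix(0, N, N, dimnames = list(states, states))
  for (s in train) {
    lab <- activityLabels(s)
    T <- length(lab)
    if (T < 2L) next
    from <- factor(lab[-T], levels = states)
    to <- factor(lab[-1L], levels = states)
    cnt <- cnt + unclass(table(from, to))
  }
  A <- (cnt + alpha) / (rowSums(cnt) + alpha * N)
  # a state never seen as a "from" with alpha = 0 would be 0/0; fall back to
  # uniform for such rows so A stays stochastic
  bad <- !is.finite(rowSums(A)) | abs(rowSums(A) - 1) > 1e-9
  A[bad, ] <- 1 / N
  list(A = matrix(as.numeric(A), N, N, dimnames = list(states, states)),
       pi = pi)
}

#' Count (possibly overlapping) k-mer occurrences
#'
#' Number of times \code{pattern} appears as a substring of \code{text},
#' counting overlaps.
#'
#' @param text a character scalar, or a vector of symbols (each element one
#'   symbol, e.g. integer primitive IDs).
#' @param pattern same form as \code{text}; must not be empty or longer than
#'   \code{text}.
#' @return Non-negative integer.
#' @examples
#' countKmers("ACACTACTGCATACTACTACCT", "CTAC")  # 3
#' @export
countKmers <- function(text, pattern) {
  text <- asSymbols(text)
  pattern <- asSymbols(pattern)
  k <- length(pattern)
  if (k == 0L) stop("empty pattern")
  T <- length(text)
  if (k > T) stop("pattern longer than text")
  hits <- rep(TRUE, T - k + 1L)
  for (j in seq_len(k))
    hits <- hits & (text[(j):(T - k + j)] == pattern[j])
  sum(hits)
}

asSymbols <- function(x) {
  if (is.character(x) && length(x) == 1L)
    strsplit(x, "", fixed = TRUE)[[1]] else x
}

## key for a k-mer starting at each position of an ID vector; positions
## whose k-mer would extend past the end are NA
kmerKeys <- function(ids, k) {
  T <- length(ids)
  if (T < k) return(rep(NA_character_, T))
  E <- stats::embed(ids, k)[, k:1, drop = FALSE]  # row t = ids[t..t+k-1]
  keys <- do.call(paste, c(split(E, col(E)), sep = "."))
  c(keys, rep(NA_character_, k - 1L))
}

#' Estimate per-state k-mer log-probability tables
#'
#' For each state, the primitive subsequences of all its training positions
#' are concatenated (per run, in order) into one string \code{PrimSeq_i};
#' the probability of each of the \code{M^k} possible k-mers is then its
#' smoothed overlapping-occurrence frequency,
#' \code{(count + alpha) / (|PrimSeq_i| - k + 1 + alpha * M^k)}. Tables are
#' stored sparsely: only observed k-mers are kept, with one shared default
#' log-probability for the unobserved remainder.
#'
#' @param train list of labeled \code{\link{PrimitiveSequence}} objects.
#' @param states character state names.
#' @param k k-mer length (default 2).
#' @param M alphabet size.
#' @param alpha additive-smoothing pseudocount (default 1).
#' @return A list with one element per state: \code{list(logp = <named
#'   numeric>, default = <numeric>, n_obs = <int>)}.
#' @export
estimateKmerTable <- function(train, states, k = 2L, M, alpha = 1) {
  checkStates(train, states)
  k <- as.integer(k); M <- as.integer(M)
  out <- vector("list", length(states))
  names(out) <- states
  for (q in states) {
    seqs <- lapply(train, function(s) primitives(s)[activityLabels(s) == q])
    prim <- unlist(seqs[lengths(seqs) > 0L])
    if (length(prim) < k)
      stop("concatenated primitive sequence shorter than k for state ", q)
    keys <- kmerKeys(prim, k)
    keys <- keys[!is.na(keys)]
    cnt <- table(keys)
    denom <- length(keys) + alpha * M^k
    logp <- log((as.numeric(cnt) + alpha) / denom)
    names(logp) <- names(cnt)
    out[[q]] <- list(logp = logp, default = log(alpha / denom),
                     n_obs = length(cnt), n_positions = length(keys))
  }
  out
}

#' Estimate the minimum-run-length (kappa) array
#'
#' For each state, finds the shortest maximal run of that state across the
#' training label sequences and divides it by two (to allow some deviance),
#' flooring and clamping at 1.
#'
#' @param train list of labeled \code{\link{PrimitiveSequence}} objects.
#' @param states character state names.
#' @return Named integer vector of per-state minimum run lengths, all >= 1.
#' @export
estimateKappa <- function(train, states) {
  checkStates(train, states)
  minRun <- stats::setNames(rep(Inf, length(states)), states)
  for (s in train) {
    r <- rle(activityLabels(s))
    for (i in seq_along(r$values)) {
      v <- r$values[i]
      if (v %in% states && r$lengths[i] < minRun[v]) minRun[v] <- r$lengths[i]
    }
  }
  stats::setNames(pmax(1L, as.integer(floor(minRun / 2))), states)
}

#' Train a full sequence model from labeled primitive sequences
#'
#' Estimates every table the HMM and CRF decoders share: transition matrix A
#' (learned or uniform), emission matrix B, uniform initial distribution,
#' per-state k-mer tables, and the minimum-run-length array kappa.
#'
#' @param train list of labeled \code{\link{PrimitiveSequence}} objects.
#' @param states character state names; defaults to the sorted set of labels
#'   present in training.
#' @param M alphabet size; defaults to the alphabet of the first sequence.
#' @param k k-mer length for the sequence-pattern feature (default 2).
#' @param alpha additive-smoothing pseudocount (default 1).
#' @param kmer_alpha pseudocount for the k-mer table; defaults to
#'   \code{alpha / M^(k-1)} so the total smoothing mass added to the
#'   \code{M^k}-cell table equals \code{alpha * M}, the same strength as the
#'   emission matrix (a flat per-cell \code{alpha} would swamp the observed
#'   pair counts and bias CRF scores toward data-rich states).
#' @param transitions \code{"learned"} (default) or \code{"uniform"}.
#' @param weights numeric length-3 CRF feature weights (default
#'   \code{c(1, 1, 1)}).
#' @return A \code{\link{SequenceModel}}.
#' @export
trainModel <- function(train, states = NULL, M = NULL, k = 2L, alpha = 1,
                       kmer_alpha = NULL,
                       transitions = c("learned", "uniform"),
                       weights = c(1, 1, 1)) {
  transitions <- match.arg(transitions)
  if (!is.list(train)) train <- list(train)
  if (is.null(states))
    states <- sort(unique(unlist(lapply(train, activityLabels))))
  if (is.null(M)) M <- alphabetSize(train[[1]])
  if (is.null(kmer_alpha)) kmer_alpha <- alpha / as.numeric(M)^(k - 1)
  tr <- estimateTransitions(train, states, alpha = alpha, mode = transitions)
  B <- estimateEmissions(train, states, M, alpha)
  kmerLogp <- estimateKmerTable(train, states, k, M, kmer_alpha)
  kmerLogp <- addKmerInterpolation(kmerLogp, B, k)
  methods::new("SequenceModel",
               states = states, M = as.integer(M),
               A = tr$A, B = B,
               pi = tr$pi, kmerK = as.integer(k),
               kmerLogp = kmerLogp,
               kappa = unname(estimateKappa(train, states)),
               weights = as.numeric(weights), alpha = as.numeric(alpha))
}

#' Attach emission-interpolation weights to a k-mer table
#'
#' The k-mer distribution used by the CRF's sequence-pattern feature is the
#' Witten-Bell interpolation of the state's smoothed pair table with the
#' independence product of its emission probabilities:
#' \deqn{P(w | q) = \lambda_q \hat p_\alpha(w | q) +
#'   (1 - \lambda_q) \prod_j B[q, w_j],}
#' with \eqn{\lambda_q = n_q / (n_q + d_q)}, where \eqn{n_q} is the number
#' of k-mer positions observed for the state and \eqn{d_q} the number of
#' distinct k-mers among them. A data-rich state trusts its pair counts; a
#' sparse state degrades gracefully to emission-product scores instead of
#' noisy or flat defaults (which would systematically favour data-rich
#' states). Both mixture components sum to 1 over the \eqn{M^k} k-mers, so
#' each per-state table still sums to exactly 1; at \eqn{k = 1} (alpha held
#' equal) the mixture reduces exactly to \code{B}.
#'
#' @param kmerLogp result of \code{\link{estimateKmerTable}}.
#' @param B emission matrix whose rows drive the interpolation.
#' @param k k-mer length.
#' @return The table list with a per-state \code{lambda} added.
#' @export
addKmerInterpolation <- function(kmerLogp, B, k) {
  for (q in rownames(B)) {
    tab <- kmerLogp[[q]]
    kmerLogp[[q]]$lambda <-
      tab$n_positions / (tab$n_positions + max(1L, tab$n_obs))
  }
  kmerLogp
}
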