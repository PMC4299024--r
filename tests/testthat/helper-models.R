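# Builders for small hand-specified models and random toy instances used
# across the decoder and model tests.

makeToyModel <- function(A, B, states = paste0("s", seq_len(nrow(A))),
                         kappa = rep(1L, nrow(A)),
                         weights = c(1, 1, 1), k = 2L, alpha = 1,
                         kmerLogp = NULL) {
  N <- nrow(A); M <- ncol(B)
  if (is.null(kmerLogp)) {
    # product-of-emissions k-mer table (independent symbols), fully dense
    kmerLogp <- lapply(seq_len(N), function(i) {
      keys <- expand.grid(rep(list(seq_len(M)), k))
      lp <- vapply(seq_len(nrow(keys)), function(r)
        sum(log(B[i, as.numeric(keys[r, ])])), numeric(1))
      names(lp) <- apply(keys, 1L, paste, collapse = ".")
      list(logp = lp, default = -Inf, n_obs = length(lp))
    })
    names(kmerLogp) <- states
  }
  new("SequenceModel", states = states, M = as.integer(M), A = A, B = B,
      pi = rep(1 / N, N), kmerK = as.integer(k), kmerLogp = kmerLogp,
      kappa = as.integer(kappa), weights = as.numeric(weights),
      alpha = as.numeric(alpha))
}

# random stochastic matrix with strictly positive entries
randomStochastic <- function(n, m) {
  x <- matrix(stats::rexp(n * m) + 0.05, n, m)
  x / rowSums(x)
}

randomToyModel <- function(N, M, T, kappaMax = 1L, k = 2L,
                           weights = c(1, 1, 1)) {
  A <- randomStochastic(N, N)
  B <- randomStochastic(N, M)
  kappa <- sample.int(kappaMax, N, replace = TRUE)
  # a random (normalized) k-mer table, independent of B
  kmerLogp <- lapply(seq_len(N), function(i) {
    p <- stats::rexp(M^k) + 0.05
    p <- p / sum(p)
    keys <- apply(expand.grid(rep(list(seq_len(M)), k)), 1L, paste,
                  collapse = ".")
    list(logp = stats::setNames(log(p), keys), default = -Inf,
         n_obs = M^k)
  })
  states <- paste0("s", seq_len(N))
  names(kmerLogp) <- states
  model <- makeToyModel(A, B, states = states, kappa = kappa, k = k,
                        weights = weights, kmerLogp = kmerLogp)
  list(model = model, obs = sample.int(M, T, replace = TRUE))
}

# two labeled primitive sequences for table-estimation tests
makeLabeledSequences <- function() {
  list(PrimitiveSequence("r1", c(1L, 1L, 2L, 3L, 3L, 3L),
                         labels = c("a", "a", "a", "b", "b", "b"), M = 3L),
       PrimitiveSequence("r2", c(2L, 2L, 1L, 3L, 1L, 2L),
                         labels = c("a", "a", "b", "b", "a", "a"), M = 3L))
}
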