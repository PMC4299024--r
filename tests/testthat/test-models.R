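test_that("emission estimates match direct counting, with and without smoothing", {
  s <- PrimitiveSequence("r", c(1L, 1L, 2L), labels = rep("q", 3), M = 2L)
  B0 <- estimateEmissions(list(s), "q", M = 2, alpha = 0)
  expect_equal(unname(B0["q", ]), c(2 / 3, 1 / 3))
  B1 <- estimateEmissions(list(s), "q", M = 2, alpha = 1)
  expect_equal(unname(B1["q", ]), c(0.6, 0.4))   # (2+1)/(3+2)
  # uniform counts give a uniform row
  s2 <- PrimitiveSequence("r", rep(1:4, 5), labels = rep("q", 20), M = 4L)
  expect_equal(unname(estimateEmissions(list(s2), "q", 4, 0)["q", ]),
               rep(0.25, 4))
  expect_error(estimateEmissions(list(s), c("q", "ghost"), 2, 1), "ghost")
})

test_that("transition estimates count adjacent label pairs", {
  s <- PrimitiveSequence("r", rep(1L, 4), labels = c("1", "1", "2", "2"),
                         M = 1L)
  tr <- estimateTransitions(list(s), c("1", "2"), alpha = 0)
  expect_equal(unname(tr$A), rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(tr$pi, c(0.5, 0.5))               # pi always uniform
  # single state
  s1 <- PrimitiveSequence("r", rep(1L, 3), labels = rep("a", 3), M = 1L)
  expect_equal(unname(estimateTransitions(list(s1), "a", 0)$A),
               matrix(1))
  # uniform mode ignores the data
  tru <- estimateTransitions(list(s), as.character(1:4), mode = "uniform")
  expect_equal(unname(tru$A), matrix(0.25, 4, 4))
})

test_that("k-mer counting includes overlapping occurrences", {
  expect_equal(countKmers("ACACTACTGCATACTACTACCT", "CTAC"), 3L)
  expect_equal(countKmers("AAAA", "AA"), 3L)
  expect_equal(countKmers(c(1, 2, 1, 2, 1), c(1, 2, 1)), 2L)
  expect_error(countKmers("ABC", ""), "empty pattern")
  # counts over all 2-mers of a random string sum to T - 1
  set.seed(10)
  txt <- sample(c("a", "b", "c"), 30, replace = TRUE)
  allPairs <- expand.grid(c("a", "b", "c"), c("a", "b", "c"),
                          stringsAsFactors = FALSE)
  tot <- sum(apply(allPairs, 1, function(p)
    countKmers(txt, c(p[[1]], p[[2]]))))
  expect_equal(tot, 29L)
})

test_that("k-mer tables follow the smoothed overlapping-count formula", {
  s <- PrimitiveSequence("r", c(1L, 1L, 2L, 1L), labels = rep("q", 4), M = 2L)
  tab <- estimateKmerTable(list(s), "q", k = 2, M = 2, alpha = 0)
  lp <- tab$q$logp
  # "1121" has 2-mers 11, 12, 21 once each over 3 positions
  expect_equal(unname(exp(lp[c("1.1", "1.2", "2.1")])), rep(1 / 3, 3))
  expect_true(is.na(lp["2.2"]) || !("2.2" %in% names(lp)))
  expect_equal(tab$q$default, -Inf)
  # constant sequence: its single 2-mer has probability 1
  sc <- PrimitiveSequence("r", rep(2L, 6), labels = rep("q", 6), M = 2L)
  tc <- estimateKmerTable(list(sc), "q", 2, 2, alpha = 0)
  expect_equal(unname(exp(tc$q$logp["2.2"])), 1)
  expect_error(estimateKmerTable(list(PrimitiveSequence("r", 1L,
                                                        labels = "q", M = 2L)),
                                 "q", 2, 2, 1), "shorter than k")
})

test_that("per-state tables normalize to 1 for alpha in {0, 1}", {
  set.seed(11)
  for (alpha in c(0, 1)) {
    seqs <- lapply(1:3, function(i)
      PrimitiveSequence(paste0("r", i), sample.int(4, 50, replace = TRUE),
                        labels = sample(c("a", "b"), 50, replace = TRUE),
                        M = 4L))
    B <- estimateEmissions(seqs, c("a", "b"), 4, alpha)
    expect_equal(unname(rowSums(B)), c(1, 1), tolerance = 1e-9)
    tr <- estimateTransitions(seqs, c("a", "b"), alpha)
    expect_equal(unname(rowSums(tr$A)), c(1, 1), tolerance = 1e-9)
    expect_equal(sum(tr$pi), 1, tolerance = 1e-9)
    tab <- estimateKmerTable(seqs, c("a", "b"), 2, 4, alpha)
    for (q in c("a", "b")) {
      tot <- sum(exp(tab[[q]]$logp)) +
        (4^2 - tab[[q]]$n_obs) * exp(tab[[q]]$default)
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }
})

test_that("kmer table with k = 1 reduces to the emission matrix", {
  seqs <- makeLabeledSequences()
  B <- estimateEmissions(seqs, c("a", "b"), 3, alpha = 1)
  tab <- estimateKmerTable(seqs, c("a", "b"), k = 1, M = 3, alpha = 1)
  for (q in c("a", "b")) {
    got <- exp(tab[[q]]$logp[as.character(1:3)])
    got[is.na(got)] <- exp(tab[[q]]$default)
    expect_equal(unname(got), unname(B[q, ]), tolerance = 1e-12)
  }
})

test_that("estimated emissions converge to the generating distribution", {
  set.seed(12)
  p <- c(0.5, 0.3, 0.15, 0.05)
  s <- PrimitiveSequence("r", sample.int(4, 1e4, replace = TRUE, prob = p),
                         labels = rep("q", 1e4), M = 4L)
  B <- estimateEmissions(list(s), "q", 4, alpha = 0)
  expect_lt(sum(abs(B["q", ] - p)) / 2, 0.05)    # total variation
})

test_that("kappa halves the shortest training run, floored and clamped", {
  lab <- function(x) PrimitiveSequence("r", rep(1L, length(x)), labels = x,
                                       M = 1L)
  s <- lab(c(rep("i", 10), rep("j", 1), rep("i", 12)))
  k <- estimateKappa(list(s), c("i", "j"))
  expect_equal(unname(k["i"]), 5L)               # min run 10 -> 5
  expect_equal(unname(k["j"]), 1L)               # min run 1 -> clamp
  s2 <- lab(c("a", "a", "a", "b", "a", "a"))
  expect_equal(unname(estimateKappa(list(s2), c("a", "b"))["a"]), 1L)
  s3 <- lab(rep("a", 7))                         # min run 7 -> floor(3.5)
  expect_equal(unname(estimateKappa(list(s3), "a")["a"]), 3L)
})

test_that("trainModel assembles a valid model", {
  seqs <- makeLabeledSequences()
  m <- trainModel(seqs, k = 2, alpha = 1)
  expect_s4_class(m, "SequenceModel")
  expect_equal(states(m), c("a", "b"))
  expect_equal(alphabetSize(m), 3L)
  expect_true(all(minRunLengths(m) >= 1L))
  expect_true(validObject(m))
})
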