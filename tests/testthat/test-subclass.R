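# Helpers: labeled sequences whose "commute" class mixes two disjoint
# primitive modes (episodes drawn from one mode each), next to homogeneous
# classes -- the intra-class fragmentation setting.

makeFragmentedTraining <- function(seed = 1, daysN = 6, M = 12L) {
  # "commute" mixes two disjoint primitive modes, one drawn per episode;
  # its second mode shares symbols 5..8 with the skewed "sport" class, so
  # the blended commute profile loses those episodes to sport at baseline
  # -- exactly what a kept split must fix
  set.seed(seed)
  modeA <- 1:4; modeB <- 5:8; workP <- 9:10; idleP <- 11:12
  lapply(seq_len(daysN), function(d) {
    prim <- c(); lab <- c()
    addEp <- function(pool, class, len, prob = NULL) {
      prim <<- c(prim, sample(pool, len, replace = TRUE, prob = prob))
      lab <<- c(lab, rep(class, len))
    }
    addEp(workP, "work", 40)
    addEp(if (d %% 2 == 0) modeA else modeB, "commute", 25)
    addEp(idleP, "idle", 40)
    addEp(modeB, "sport", 30, prob = c(0.4, 0.3, 0.2, 0.1))
    addEp(if (runif(1) < 0.5) modeA else modeB, "commute", 25)
    addEp(workP, "work", 40)
    PrimitiveSequence(paste0("d", d), prim, labels = lab, M = M)
  })
}

test_that("histograms are relative frequencies", {
  expect_equal(primitiveHistogram(c(1, 1, 2), 3), c(2 / 3, 1 / 3, 0))
  expect_equal(primitiveHistogram(rep(4, 9), 5), c(0, 0, 0, 1, 0))
  set.seed(40)
  x <- sample.int(6, 50, replace = TRUE)
  h <- primitiveHistogram(x, 6)
  expect_equal(sum(h), 1)
  expect_equal(h, as.numeric(table(factor(x, levels = 1:6))) / 50)
  expect_error(primitiveHistogram(integer(), 3), "empty")
})

test_that("activity instances are the maximal label runs", {
  s <- PrimitiveSequence("r", c(1L, 1L, 2L, 2L, 1L),
                         labels = c("a", "a", "b", "b", "a"), M = 2L)
  inst <- activityInstances(list(s))
  expect_equal(inst$classes, c("a", "b", "a"))
  expect_equal(inst$where$startPos, c(1L, 3L, 5L))
  expect_equal(rowSums(inst$counts), c(2, 2, 1))
  expect_equal(rowSums(inst$hist), rep(1, 3))
})

test_that("the index search splits the fragmented class and only it", {
  train <- makeFragmentedTraining(seed = 2)
  for (method in c("silhouette", "pbm", "gdi33")) {
    m <- findSubclasses(train, method = method, maxK = 4, seed = 5)
    expect_equal(unname(m@fragments["commute"]), 2L)
    expect_equal(unname(m@fragments["work"]), 1L)
    expect_equal(unname(m@fragments["idle"]), 1L)
    expect_equal(unname(m@fragments["sport"]), 1L)
    # the gate never lets accuracy drop
    expect_gte(attr(m, "accuracy"), attr(m, "baseline"))
  }
})

test_that("subclass assignment recovers the generating modes", {
  train <- makeFragmentedTraining(seed = 3)
  m <- findSubclasses(train, method = "silhouette", maxK = 4, seed = 5)
  a <- m@assignments[m@assignments$original == "commute", ]
  # recompute each episode's true mode from its primitives
  inst <- activityInstances(train)
  commuteRows <- which(inst$classes == "commute")
  trueMode <- ifelse(rowSums(inst$counts[commuteRows, 1:4]) > 0, "A", "B")
  tab <- table(trueMode, a$subclass)
  # agreement up to label permutation
  expect_equal(sum(apply(tab, 1, max)), length(trueMode))
})

test_that("a homogeneous class is never split", {
  set.seed(41)
  train <- lapply(1:4, function(d) {
    prim <- c(sample(1:3, 30, TRUE), sample(4:6, 30, TRUE))
    PrimitiveSequence(paste0("d", d), prim,
                      labels = rep(c("a", "b"), each = 30), M = 6L)
  })
  for (method in c("silhouette", "pbm")) {
    m <- findSubclasses(train, method = method, maxK = 3, seed = 1)
    expect_true(all(m@fragments == 1L))
  }
})

test_that("maxK = 1 and method none give the identity map", {
  train <- makeFragmentedTraining(seed = 4, daysN = 3)
  m <- findSubclasses(train, method = "silhouette", maxK = 1, seed = 1)
  expect_true(all(m@fragments == 1L))
  expect_equal(m@map$subclass, m@map$original)
  m2 <- findSubclasses(train, method = "none")
  expect_equal(m2@map$subclass, m2@map$original)
})

test_that("fixed subclassing applies the requested counts, bypassing the gate", {
  train <- makeFragmentedTraining(seed = 5)
  m <- findSubclasses(train, method = "fixed", fixed = list(commute = 2),
                      seed = 3)
  expect_equal(unname(m@fragments["commute"]), 2L)
  expect_true(all(m@fragments[c("work", "idle")] == 1L))
})

test_that("mapBack inverts the relabeling and rejects unknown labels", {
  train <- makeFragmentedTraining(seed = 6, daysN = 4)
  m <- findSubclasses(train, method = "silhouette", maxK = 4, seed = 5)
  relabeled <- applySubclasses(m, train)
  for (i in seq_along(train)) {
    expect_equal(mapBack(m, activityLabels(relabeled[[i]])),
                 activityLabels(train[[i]]))
  }
  expect_error(mapBack(m, "never.seen"), "unknown subclass")
  # explicit toy map
  toy <- new("SubclassMap",
             map = data.frame(subclass = c("A1", "A2", "B1"),
                              original = c("A", "A", "B")),
             fragments = c(A = 2L, B = 1L),
             assignments = data.frame(run = integer(), startPos = integer(),
                                      endPos = integer(),
                                      original = character(),
                                      subclass = character()))
  expect_equal(mapBack(toy, c("A2", "B1", "A1")), c("A", "B", "A"))
})

test_that("naive Bayes separates multinomial profiles", {
  set.seed(42)
  p1 <- c(0.7, 0.2, 0.1); p2 <- c(0.1, 0.2, 0.7)
  counts <- rbind(t(rmultinom(15, 40, p1)), t(rmultinom(15, 40, p2)))
  cls <- rep(c("x", "y"), each = 15)
  fit <- fitNaiveBayes(counts, cls)
  expect_equal(predictNaiveBayes(fit, counts), cls)
  expect_equal(predictNaiveBayes(fit, matrix(c(40, 0, 0), 1)), "x")
})
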