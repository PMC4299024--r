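test_that("causal average filter matches its defining sum and edge rule", {
  # interior: mean of the n samples strictly before t
  s <- 1:20
  out <- smoothSignal(s, n = 10)
  expect_equal(out[15], mean(s[5:14]))  # 0-based index 14
  expect_equal(length(out), length(s))
  for (t in 2:10) expect_equal(out[t], mean(s[1:(t - 1)]))  # partial prefix
  expect_equal(out[1], s[1])
  # constants are fixed points
  expect_equal(smoothSignal(rep(4.2, 50), 10), rep(4.2, 50))
  # single sample passes through
  expect_equal(smoothSignal(5, 10), 5)
  expect_error(smoothSignal(numeric(0), 10), "empty")
})

test_that("window enumeration advances by step and drops partial windows", {
  rec <- function(n) TriaxialRecording("r", (seq_len(n) - 1) / 20,
                                       rnorm(n), rnorm(n), rnorm(n))
  cfg <- preprocessConfig()      # l = 60, overlap 0.33 -> step 40
  expect_equal(cfg$step, 40L)
  w <- makeWindows(rec(60), NULL, cfg)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(0L, 60L))
  w <- makeWindows(rec(100), NULL, cfg)
  expect_equal(w$start, c(0L, 40L))
  expect_equal(nrow(makeWindows(rec(59), NULL, cfg)), 0L)
  # starts form an arithmetic progression; adjacent windows share l - step
  w <- makeWindows(rec(400), NULL, cfg)
  expect_equal(unique(diff(w$start)), 40L)
  expect_true(all(w$end <= 400))
})

test_that("window labels are the per-sample majority, ties to earlier interval", {
  n <- 60L
  rec <- TriaxialRecording("r", (seq_len(n) - 1), rnorm(n), rnorm(n), rnorm(n))
  cfg <- preprocessConfig(window_length_l = n)
  # 40 samples of a vs 20 of b
  lab <- ActivityLabeling("r", start = c(0, 40), end = c(40, 60),
                          activity = c("a", "b"))
  expect_equal(makeWindows(rec, lab, cfg)$label, "a")
  # exact tie 30/30: earlier interval wins
  lab <- ActivityLabeling("r", start = c(0, 30), end = c(30, 60),
                          activity = c("b", "a"))
  expect_equal(makeWindows(rec, lab, cfg)$label, "b")
  # wholly outside any interval
  expect_equal(makeWindows(rec, ActivityLabeling("r"), cfg)$label,
               "not_tagged")
  # majority untagged but some coverage: untagged wins by count
  lab <- ActivityLabeling("r", start = 50, end = 60, activity = "a")
  expect_equal(makeWindows(rec, lab, cfg)$label, "not_tagged")
})

test_that("the feature vector has the documented 12 entries with hand-checked values", {
  f <- extractFeatures(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0))
  expect_length(f, 12L)
  expect_equal(unname(f["mean_x"]), 2)
  expect_equal(unname(f["var_x"]), 2 / 3)      # population variance
  expect_equal(unname(f["corr_xy"]), 1)
  expect_equal(unname(f["corr_xz"]), 0)        # zero-variance convention
  m <- sqrt(c(1, 2, 3)^2 + c(1, 2, 3)^2)
  expect_equal(unname(f["mean_mag"]), mean(m))
  expect_equal(unname(f["avg_deriv_mag"]), mean(abs(diff(m))))
  # constant window: all variation features zero, magnitude scales by sqrt(3)
  g <- extractFeatures(rep(2, 5), rep(2, 5), rep(2, 5))
  expect_equal(unname(g), c(2, 2, 2, 0, 0, 0, 0, 0, 0, 2 * sqrt(3), 0, 0))
  expect_error(extractFeatures(1, 1, 1), "too short")
})

test_that("features are finite and permutation-covariant in the axes", {
  set.seed(42)
  for (rep in 1:20) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    f <- extractFeatures(x, y, z)
    expect_true(all(is.finite(f)))
    g <- extractFeatures(y, x, z)      # swap x and y
    expect_equal(unname(g[c("mean_y", "mean_x", "var_y", "var_x")]),
                 unname(f[c("mean_x", "mean_y", "var_x", "var_y")]))
    expect_equal(unname(g["corr_xy"]), unname(f["corr_xy"]))
    expect_equal(unname(g["corr_xz"]), unname(f["corr_yz"]))
    expect_equal(unname(g[c("mean_mag", "var_mag", "avg_deriv_mag")]),
                 unname(f[c("mean_mag", "var_mag", "avg_deriv_mag")]))
  }
})

test_that("featurizeRecording glues smoothing, windows and features together", {
  set.seed(7)
  n <- 220L
  rec <- TriaxialRecording("d", (seq_len(n) - 1) / 20,
                           rnorm(n, 0.1), rnorm(n, -0.3), rnorm(n, 0.9))
  lab <- ActivityLabeling("d", start = 0, end = 5, activity = "work")
  fz <- featurizeRecording(rec, lab)
  expect_equal(nrow(fz$features), nrow(fz$windows))
  expect_equal(ncol(fz$features), 12L)
  expect_true(all(is.finite(fz$features)))
  # first window fully inside the labeled interval
  expect_equal(fz$windows$label[1], "work")
  # features recomputed by hand from the smoothed signal
  xs <- smoothSignal(rec@x, 10); ys <- smoothSignal(rec@y, 10)
  zs <- smoothSignal(rec@z, 10)
  expect_equal(fz$features[2, ],
               extractFeatures(xs[41:100], ys[41:100], zs[41:100]))
})
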