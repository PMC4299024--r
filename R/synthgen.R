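#' @include AllClasses.R
NULL

#' Define a synthetic activity class
#'
#' An activity is a concatenation of short motion regimes, each a Gaussian
#' noise process around per-axis mean accelerations with an optional
#' sinusoidal component (the simplest family that makes the 12 window
#' features -- means, variances, correlations, magnitude statistics --
#' discriminative). A non-fragmented multi-regime class alternates regimes
#' in short bouts within each episode; a \emph{fragmented} class fixes one
#' regime per episode, so the same label covers kinematically different
#' episodes (e.g., commuting sometimes by bus, sometimes on foot).
#'
#' @param name class name.
#' @param min_duration,max_duration episode duration bounds, seconds.
#' @param regimes list of regimes; each a list with \code{name},
#'   \code{weight}, \code{mean} (length-3, g), \code{sd} (length-3, g),
#'   optional \code{freq} (Hz), \code{amp} (length-3, g) and \code{bout_s}
#'   (mean bout duration for within-episode alternation).
#' @param fragmented logical; draw one regime per episode instead of
#'   alternating.
#' @return A list of class \code{"ActivitySpec"}.
#' @export
activitySpec <- function(name, min_duration, max_duration, regimes,
                         fragmented = FALSE) {
  stopifnot(min_duration <= max_duration, length(regimes) >= 1L)
  regimes <- lapply(regimes, function(r) {
    r$freq <- if (is.null(r$freq)) 0 else r$freq
    r$amp <- if (is.null(r$amp)) c(0, 0, 0) else rep_len(as.numeric(r$amp), 3L)
    r$bout_s <- if (is.null(r$bout_s)) 10 else r$bout_s
    r$mean <- rep_len(as.numeric(r$mean), 3L)
    r$sd <- rep_len(as.numeric(r$sd), 3L)
    r
  })
  w <- vapply(regimes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-6) stop("regime weights must sum to 1")
  structure(list(name = name, min_duration = min_duration,
                 max_duration = max_duration, regimes = regimes,
                 fragmented = isTRUE(fragmented)),
            class = "ActivitySpec")
}

## samples for one episode of a spec: regime index per sample, then signal.
## For a fragmented class one *mode* (regime group) is drawn per episode;
## regimes within the chosen group still alternate in bouts, so a mode can
## itself be textured (e.g., walking with brief pauses).
episodeSamples <- function(spec, n, rate) {
  regimeIdx <- integer(n)
  w <- vapply(spec$regimes, `[[`, numeric(1), "weight")
  active <- seq_along(spec$regimes)
  if (spec$fragmented) {
    modes <- vapply(seq_along(spec$regimes), function(i) {
      m <- spec$regimes[[i]]$mode
      if (is.null(m)) spec$regimes[[i]]$name else m
    }, character(1))
    pick <- sample(unique(modes), 1L,
                   prob = vapply(unique(modes),
                                 function(m) sum(w[modes == m]), numeric(1)))
    active <- which(modes == pick)
  }
  if (length(active) == 1L) {
    regimeIdx[] <- active
  } else {
    wa <- w[active] / sum(w[active])
    pos <- 1L
    while (pos <= n) {
      r <- active[sample.int(length(active), 1L, prob = wa)]
      len <- max(1L, round(stats::rexp(1, 1 / spec$regimes[[r]]$bout_s) * rate))
      regimeIdx[pos:min(n, pos + len - 1L)] <- r
      pos <- pos + len
    }
  }
  sig <- matrix(0, n, 3L)
  for (r in unique(regimeIdx)) {
    rs <- spec$regimes[[r]]
    at <- which(regimeIdx == r)
    tt <- (at - 1L) / rate
    phase <- stats::runif(3L, 0, 2 * pi)
    for (ax in 1:3) {
      osc <- if (rs$freq > 0) rs$amp[ax] * sin(2 * pi * rs$freq * tt + phase[ax]) else 0
      sig[at, ax] <- rs$mean[ax] + osc + stats::rnorm(length(at), 0, rs$sd[ax])
    }
  }
  list(signal = sig, regime = regimeIdx)
}

#' Generate one synthetic day
#'
#' Emits a triaxial recording, the user-visible labeling (tagged episodes
#' only) and the full ground-truth trace, deterministically for a given
#' seed. Episodes whose \code{tagged} flag is \code{FALSE} -- plus a random
#' \code{untagged_fraction} of the remaining episodes -- have their labels
#' withheld from the labeling but kept in the trace.
#'
#' @param specs named list of \code{\link{activitySpec}} objects.
#' @param plan list with \code{run_id}, \code{sampling_rate} (Hz, default
#'   20), \code{start_time} (clock seconds, default 9 h), \code{schedule}
#'   (data.frame with columns \code{activity}, \code{duration} seconds,
#'   \code{tagged}) and optional \code{untagged_fraction} (default 0).
#' @param seed integer seed.
#' @return List with \code{recording} (\code{\link{TriaxialRecording}}),
#'   \code{labeling} (\code{\link{ActivityLabeling}}) and \code{trace}
#'   (data.frame per sample: \code{activity}, \code{regime},
#'   \code{tagged}).
#' @export
generateDay <- function(specs, plan, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rate <- if (is.null(plan$sampling_rate)) 20 else plan$sampling_rate
  start_time <- if (is.null(plan$start_time)) 9 * 3600 else plan$start_time
  uf <- if (is.null(plan$untagged_fraction)) 0 else plan$untagged_fraction
  sched <- plan$schedule
  stopifnot(nrow(sched) >= 1L, all(sched$activity %in% names(specs)))
  for (i in seq_len(nrow(sched))) {
    sp <- specs[[sched$activity[i]]]
    if (sched$duration[i] < sp$min_duration - 1e-9 ||
        sched$duration[i] > sp$max_duration + 1e-9)
      stop("impossible schedule: episode duration outside spec bounds for ",
           sp$name)
  }
  tagged <- sched$tagged
  if (uf > 0) {
    cand <- which(tagged)
    hide <- sample(cand, size = round(uf * length(cand)))
    tagged[hide] <- FALSE
  }
  sigs <- list(); act <- character(); reg <- character(); tagv <- logical()
  starts <- numeric(nrow(sched)); ends <- numeric(nrow(sched))
  t0 <- start_time
  for (i in seq_len(nrow(sched))) {
    sp <- specs[[sched$activity[i]]]
    n <- max(1L, round(sched$duration[i] * rate))
    ep <- episodeSamples(sp, n, rate)
    sigs[[i]] <- ep$signal
    act <- c(act, rep(sp$name, n))
    reg <- c(reg, vapply(sp$regimes, `[[`, character(1), "name")[ep$regime])
    tagv <- c(tagv, rep(tagged[i], n))
    starts[i] <- t0
    ends[i] <- t0 + n / rate
    t0 <- ends[i]
  }
  sig <- do.call(rbind, sigs)
  nTot <- nrow(sig)
  time <- start_time + (seq_len(nTot) - 1L) / rate
  keep <- tagged
  labeling <- ActivityLabeling(plan$run_id,
                               start = starts[keep], end = ends[keep],
                               activity = sched$activity[keep])
  list(recording = TriaxialRecording(plan$run_id, time,
                                     sig[, 1], sig[, 2], sig[, 3]),
       labeling = labeling,
       trace = data.frame(activity = act, regime = reg, tagged = tagv))
}

loadScenarioSpecs <- function(path = system.file("extdata",
                                                 "default_scenario.json",
                                                 package = "actseg")) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  specs <- lapply(js$classes, function(cl)
    activitySpec(cl$name, cl$min_duration, cl$max_duration,
                 regimes = cl$regimes, fragmented = isTRUE(cl$fragmented)))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  list(specs = specs, sampling_rate = js$sampling_rate)
}

#' Generate the default multi-day scenario
#'
#' A five-activity daily-living scenario plus an untagged idle class filling
#' roughly 45 percent of each day, shaped after a desk worker's routine: a
#' dominant working class, short hygiene and commuting episodes, a meal, and
#' exercise on alternate days. The commuting class is deliberately
#' fragmented (one bus-like and one walking regime, fixed per episode), and
#' its walking regime coincides with the exercise class's walking regime, so
#' the unsplit commuting profile is genuinely confusable. Class definitions
#' are read from the packaged \code{default_scenario.json} fixture.
#'
#' @param n_days number of days (>= 2).
#' @param seed integer root seed; day \code{d} uses seed
#'   \code{seed * 1000 + d}.
#' @return List of days, each as returned by \code{\link{generateDay}}.
#' @export
defaultScenario <- function(n_days, seed = 1L) {
  stopifnot(n_days >= 2L)
  sc <- loadScenarioSpecs()
  specs <- sc$specs
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  lapply(seq_len(n_days), function(d) {
    set.seed(as.integer(seed) * 1000L + d)
    acts <- c("idle", "hygiene", "idle", "commuting", "working", "idle",
              "dinner", "idle", "working", "idle", "commuting", "idle")
    if (d %% 2L == 1L) acts <- c(acts, "exercise", "idle")
    dur <- vapply(acts, function(a)
      stats::runif(1, specs[[a]]$min_duration, specs[[a]]$max_duration),
      numeric(1))
    sched <- data.frame(activity = acts, duration = dur,
                        tagged = acts != "idle")
    plan <- list(run_id = sprintf("day%02d", d),
                 sampling_rate = sc$sampling_rate,
                 start_time = 9 * 3600 + stats::runif(1, 0, 600),
                 schedule = sched, untagged_fraction = 0)
    generateDay(specs, plan, seed = as.integer(seed) * 1000L + 500L + d)
  })
}
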