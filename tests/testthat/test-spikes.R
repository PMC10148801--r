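# Single-unit module: z-scores, rank-sum + Simes detection, tuning curves,
# burst detection, pre-stimulus test.

unit_from_spikes <- function(spikes, stimulus = NULL, condition = NULL,
                             region = "AM") {
  n <- length(spikes)
  structure(
    list(spikes = spikes,
         trial_stimulus = stimulus %||% rep("s1", n),
         trial_condition = condition %||% rep(c("primed", "control"),
                                              length.out = n),
         region = region, unit_class = "SU", window = c(-1000, 2000),
         baseline_rate = NA_real_,
         ground_truth = list(mechanism = "none")),
    class = "unit_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("z-scores follow their definition exactly", {
  # baseline rates alternate 2 and 4 Hz; activation rate = baseline mean + 1 SD
  spikes <- lapply(1:20, function(i) {
    nb <- if (i %% 2 == 0) 1 else 2              # spikes in [-500, 0)
    c(seq(-499, -1, length.out = nb), numeric(0))
  })
  u <- unit_from_spikes(spikes)
  z <- zscore_rates(u)
  base <- ifelse(seq_len(20) %% 2 == 0, 2, 4)
  expect_equal(z$baseline_mean, mean(base))
  expect_equal(z$baseline_sd, sd(base))
  # plant activation spikes so that rate = mean + 1 SD on every trial
  target_rate <- z$baseline_mean + z$baseline_sd  # Hz over [100, 1000) = 0.9 s
  k <- round(target_rate * 0.9)
  spikes2 <- lapply(spikes, function(t) sort(c(t, seq(150, 950, length.out = k))))
  z2 <- zscore_rates(unit_from_spikes(spikes2))
  expect_equal(z2$z, rep((k / 0.9 - z$baseline_mean) / z$baseline_sd, 20))
})

test_that("a silent unit is flagged instead of z-scored", {
  u <- unit_from_spikes(rep(list(numeric(0)), 10))
  expect_warning(z <- zscore_rates(u), "silent")
  expect_false(z$valid)
  expect_null(z$z)
})

test_that("a null homogeneous unit has mean z near zero", {
  tt <- repeat_trials("s1", 500)
  u <- simulate_unit(tt, mechanism_spec("none", baseline_rate = 5,
                                        tuning_gains = 1), seed = 8)
  z <- zscore_rates(u)
  expect_lt(abs(mean(z$z)), 0.1)
})

test_that("the internal rank-sum p matches wilcox.test on random data", {
  set.seed(10)
  for (i in 1:200) {
    x <- rpois(10, 3) * 10
    y <- rpois(sample(c(50, 1000), 1), 3) * 2
    expect_equal(mtladapt:::ranksum_p(x, y),
                 suppressWarnings(
                   wilcox.test(x, y, exact = FALSE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("the precomputed-reference rank-sum equals the direct one", {
  set.seed(20)
  for (i in 1:200) {
    x <- rpois(10, runif(1, 0.1, 6)) * 10
    y <- rpois(sample(c(200, 5000), 1), runif(1, 0.1, 4)) * 10
    ref <- mtladapt:::make_ranksum_ref(y)
    expect_equal(mtladapt:::ranksum_p_ref(x, ref),
                 suppressWarnings(
                   wilcox.test(x, y, exact = FALSE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("Simes decision equals the direct inequality on random p-vectors", {
  set.seed(11)
  for (i in 1:2000) {
    p <- runif(19)^sample(1:4, 1)
    alpha <- sample(c(0.001, 0.01, 0.05), 1)
    oracle <- any(sort(p) <= seq_len(19) * alpha / 19)
    expect_identical(simes_test(p, alpha), oracle)
  }
})

test_that("the 19 overlapping response bins tile [0, 1000) as specified", {
  bins <- mtladapt:::response_bins()
  expect_equal(nrow(bins), 19)
  expect_equal(bins[1:10, "start"], seq(0, 900, 100), ignore_attr = TRUE)
  expect_equal(bins[11:19, "start"], seq(50, 850, 100), ignore_attr = TRUE)
  expect_true(all(bins[, "end"] - bins[, "start"] == 100))
  # bin_rates agrees with direct counting on a hand-made train
  spikes <- list(c(0, 49.9, 50, 99.9, 100, 550, 949.9, 950, 999.9))
  br <- mtladapt:::bin_rates(spikes)
  expect_equal(br[1, 1], 4 * 10)    # [0,100): 0,49.9,50,99.9
  expect_equal(br[1, 11], 3 * 10)   # [50,150): 50,99.9,100
  expect_equal(br[1, 10], 3 * 10)   # [900,1000): 949.9,950,999.9
  expect_equal(br[1, 19], 1 * 10)   # [850,950): only 949.9
})

test_that("a unit firing nothing is not responsive (criterion c)", {
  spikes <- rep(list(numeric(0)), 1000)
  spikes[[1]] <- c(-400, -100)  # avoid a zero baseline SD
  u <- unit_from_spikes(spikes,
                        stimulus = rep(sprintf("x%03d", 1:100), each = 10))
  d <- binwise_response_criterion(u, "x001")
  expect_false(d$responsive)
  expect_false(d$spike_presence)
})

test_that("fewer than 10 presentations is an explicit error", {
  u <- unit_from_spikes(rep(list(c(10, 20)), 8))
  expect_error(binwise_response_criterion(u, "s1"), "needs 10")
})

test_that("a strong planted response is detected; criterion parts line up", {
  set.seed(12)
  tt <- repeat_trials(sprintf("x%02d", 1:50), 10 / 2)
  u <- simulate_unit(tt, mechanism_spec("none", baseline_rate = 3,
                                        tuning_gains = c(5),
                                        onset_latency = 200,
                                        response_duration = 600),
                     tuned_stimuli = "x07", seed = 12)
  d <- response_decisions(u, c("x07", "x20"))
  expect_true(d$responsive[d$stimulus == "x07"])
  expect_false(d$responsive[d$stimulus == "x20"])
  expect_true(d$simes_pass[1] && d$rate_above_baseline[1] &&
                d$spike_presence[1])
})

test_that("multi-responsive selection is monotone in min_stimuli", {
  decisions <- data.frame(
    unit = rep(1:5, each = 6),
    stimulus = rep(sprintf("s%d", 1:6), 5),
    responsive = c(rep(TRUE, 5), FALSE,
                   rep(TRUE, 4), rep(FALSE, 2),
                   rep(TRUE, 3), rep(FALSE, 3),
                   rep(TRUE, 2), rep(FALSE, 4),
                   rep(FALSE, 6)))
  s2 <- select_multiresponsive_units(decisions, 2)
  s3 <- select_multiresponsive_units(decisions, 3)
  s4 <- select_multiresponsive_units(decisions, 4)
  expect_identical(s4, c("1", "2"))
  expect_true(all(s4 %in% s3) && all(s3 %in% s2))
  expect_identical(s2, c("1", "2", "3", "4"))
})

test_that("tuning curves normalize to the control rank-1 rate and order stably", {
  # deterministic spikes: rates per (stimulus, condition) fully controlled
  mk_trials <- function(rate_hz) {
    lapply(rate_hz, function(r) {
      if (r == 0) numeric(0) else seq(0, 999.9, length.out = r)
    })
  }
  stim <- rep(c("b", "a", "c"), each = 10)
  cond <- rep(rep(c("primed", "control"), each = 5), 3)
  rates <- c(rep(c(14, 20), each = 5),   # b: primed 14, control 20
             rep(c(14, 20), each = 5),   # a: tie with b on pooled rate
             rep(c(7, 10), each = 5))    # c: half
  u <- unit_from_spikes(mk_trials(rates), stimulus = stim, condition = cond)
  curve <- build_tuning_curve(u, c("b", "a", "c"))
  expect_equal(curve$stimulus, c("a", "b", "c"))  # tie broken by id
  expect_equal(curve$control_norm[1], 1)
  expect_equal(curve$primed_norm, c(0.7, 0.7, 0.35))
  expect_equal(attr(curve, "fr_max"), 20)
})

test_that("FRmax of zero excludes the unit with a warning", {
  u <- unit_from_spikes(rep(list(numeric(0)), 10))
  u$spikes[[1]] <- c(10, 20)  # primed trial only
  expect_warning(curve <- build_tuning_curve(u, "s1"), "FRmax")
  expect_null(curve)
})

test_that("rank contrasts recover generator signatures and classify them", {
  sess <- cached_session()
  mk_cohort <- function(mech, n_units, seed) {
    lapply(seq_len(n_units), function(i) {
      u <- simulate_unit(sess$trials, mech, stim_set = sess$stim_set,
                         seed = seed * 1000 + i)
      build_tuning_curve(u, u$ground_truth$tuned_stimuli[
        mech$tuning_gains > 1])
    })
  }
  shp <- contrast_tuning(mk_cohort(mechanism_spec("sharpening"), 40, 21))
  expect_gt(shp$per_rank$p[1], 0.05)
  expect_lt(shp$per_rank$p[2], 0.05)
  expect_lt(shp$per_rank$mean_primed[2], shp$per_rank$mean_control[2])
  expect_identical(classify_population_profile(shp), "sharpening")
  fat <- contrast_tuning(mk_cohort(mechanism_spec("fatiguing"), 40, 22))
  expect_lt(fat$per_rank$p[1], 0.05)
  expect_lt(fat$per_rank$p[2], 0.05)
  expect_identical(classify_population_profile(fat), "fatiguing")
})

test_that("identical primed/control curves yield null contrasts", {
  curve <- data.frame(rank = 1:4, stimulus = letters[1:4],
                      pooled = c(4, 3, 2, 1), primed = c(4, 3, 2, 1),
                      control = c(4, 3, 2, 1),
                      primed_norm = c(1, .75, .5, .25),
                      control_norm = c(1, .75, .5, .25))
  curves <- replicate(10, structure(curve,
                                    class = c("tuning_curve", "data.frame")),
                      simplify = FALSE)
  ctr <- contrast_tuning(curves)
  expect_true(all(ctr$per_rank$p == 1))
  expect_identical(classify_population_profile(ctr), "indeterminate")
})

test_that("poisson-surprise burst detection localizes a constructed burst", {
  # baseline 5 Hz, dense 10x burst between 250 and 600 ms
  set.seed(14)
  spikes <- lapply(1:30, function(i) {
    bg <- sort(runif(15, -1000, 2000))            # 5 Hz over 3 s
    burst <- sort(runif(18, 250, 600))            # ~50 Hz
    sort(c(bg, burst))
  })
  u <- unit_from_spikes(spikes)
  br <- detect_burst(u)
  expect_true(all(br$method == "poisson_burst"))
  expect_equal(median(br$onset, na.rm = TRUE), 250, tolerance = 60)
  expect_equal(median(br$offset, na.rm = TRUE), 600, tolerance = 60)
  expect_true(all(br$offset >= br$onset, na.rm = TRUE))
})

test_that("false bursts on homogeneous trains are threshold-controlled", {
  tt <- repeat_trials("s1", 250)
  u <- simulate_unit(tt, mechanism_spec("none", baseline_rate = 5,
                                        tuning_gains = 1), seed = 15)
  # scanning all candidate runs inflates the nominal per-run level, but the
  # acceptance fraction falls steeply with the threshold
  frac <- vapply(c(2, 4, 6), function(th) {
    mean(!is.na(detect_burst(u, surprise_threshold = th)$duration))
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
  expect_lt(frac[3], 0.05)
})

test_that("low-baseline units fall back to first-spike latency", {
  spikes <- lapply(1:10, function(i) c(-400, 150 + i, 1500))
  u <- unit_from_spikes(spikes)  # baseline 2 Hz, not > 2
  br <- detect_burst(u)
  expect_true(all(br$method == "first_spike"))
  expect_equal(br$onset, 151:160)
  expect_true(all(is.na(br$duration)))
  # no spikes in the fallback window -> missing values
  u2 <- unit_from_spikes(list(c(-300), c(-200)))
  br2 <- detect_burst(u2)
  expect_true(all(is.na(br2$onset)))
})

test_that("facilitation shortens detected burst durations on primed trials", {
  tt <- repeat_trials("s1", 150)
  units <- lapply(1:8, function(i) {
    simulate_unit(tt, mechanism_spec("facilitation", baseline_rate = 4,
                                     tuning_gains = 10, attenuation = 0.3),
                  tuned_stimuli = "s1", seed = 30 + i)
  })
  res <- contrast_burst_duration(units)
  expect_lt(res$mean_diff, 0)
  expect_lt(res$p_t, 0.05)
})

test_that("pre-stimulus test is null without a pre-stimulus effect", {
  sess <- cached_session()
  units <- lapply(1:12, function(i) {
    simulate_unit(sess$trials, mechanism_spec("fatiguing"),
                  stim_set = sess$stim_set, seed = 50 + i)
  })
  resp <- lapply(units, function(u) u$ground_truth$tuned_stimuli[1:4])
  res <- prestimulus_test(units, resp)
  expect_lt(abs(res$mean_primed - res$mean_control), 0.25)
  expect_s3_class(data.frame(res$per_unit), "data.frame")
  expect_error(prestimulus_test(units[1], resp[1]), ">= 2 units")
})

test_that("a planted pre-stimulus elevation is detected", {
  set.seed(16)
  units <- list()
  resp <- list()
  for (i in 1:40) {
    stim <- rep(c("s1", "s2"), each = 10)
    cond <- rep(rep(c("primed", "control"), each = 5), 2)
    spikes <- lapply(seq_along(stim), function(j) {
      extra <- if (cond[j] == "primed") 3 else 0   # +6 Hz pre-stimulus
      sort(c(runif(rpois(1, 5 + extra), -500, 0),
             runif(rpois(1, 10), 0, 1000)))
    })
    units[[i]] <- unit_from_spikes(spikes, stimulus = stim, condition = cond)
    resp[[i]] <- "s1"
  }
  res <- prestimulus_test(units, resp)
  expect_gt(res$mean_primed, res$mean_control)
  expect_lt(res$p, 0.01)
})
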