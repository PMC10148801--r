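# Generator contracts: RT model, inhomogeneous-Poisson units under each
# mechanism (Monte-Carlo vs closed form), cohort simulation, iEEG segments.

test_that("behavior simulator produces the configured priming effect", {
  tt <- repeat_trials("s1", 20000)
  tb <- simulate_behavior(tt, rt_params(outlier_rate = 0), seed = 21)
  md_p <- median(tb$rt[tb$condition == "primed"])
  md_c <- median(tb$rt[tb$condition == "control"])
  expect_lt(md_p, md_c)
  expect_equal(md_c - md_p, rt_params()$effect, tolerance = 0.05)
  expect_equal(md_c, rt_params()$shift + exp(rt_params()$meanlog),
               tolerance = 0.02)
})

test_that("a zero effect leaves the two conditions identical in law", {
  tt <- repeat_trials("s1", 2000)
  tb <- simulate_behavior(tt, rt_params(effect = 0, outlier_rate = 0),
                          seed = 5)
  ks <- suppressWarnings(
    ks.test(tb$rt[tb$condition == "primed"],
            tb$rt[tb$condition == "control"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted RT outliers appear at the configured rate and are flagged", {
  tt <- repeat_trials("s1", 5000)
  tb <- simulate_behavior(tt, rt_params(outlier_rate = 0.02), seed = 6)
  expect_equal(mean(tb$planted_outlier), 0.02, tolerance = 0.25)
  # plants are extreme relative to the generating law
  expect_true(all(tb$rt[tb$planted_outlier] >= 2000 |
                    tb$rt[tb$planted_outlier] <= 80))
})

test_that("rt parameter validation catches non-positive scales", {
  expect_error(rt_params(sdlog = 0), "positive")
  expect_error(rt_params(effect = 600), "smaller")
  expect_error(rt_params(outlier_rate = 1.2), "outlier_rate")
})

test_that("a homogeneous unit fires at its baseline rate", {
  tt <- repeat_trials("s1", 500)
  u <- simulate_unit(tt, mechanism_spec("none", baseline_rate = 5,
                                        tuning_gains = 1), seed = 3)
  for (w in list(c(-1000, 0), c(0, 1000), c(1000, 2000))) {
    expect_equal(mean(rate_in_window_test(u, w)), 5, tolerance = 0.05)
  }
})

test_that("mechanism modulation matches its closed form", {
  tun <- c("s1", "s2")
  tt <- repeat_trials(tun, 400)
  resp <- c(300, 900)  # the response window of the generator defaults
  ratio <- function(u, s) {
    i <- u$trial_stimulus == s
    mean(rate_in_window_test_sub(u, i & u$trial_condition == "primed", resp)) /
      mean(rate_in_window_test_sub(u, i & u$trial_condition == "control", resp))
  }
  fat <- simulate_unit(tt, mechanism_spec("fatiguing", baseline_rate = 20,
                                          tuning_gains = c(8, 5),
                                          attenuation = 0.3),
                       tuned_stimuli = tun, seed = 4)
  expect_equal(ratio(fat, "s1"), 0.7, tolerance = 0.05)
  expect_equal(ratio(fat, "s2"), 0.7, tolerance = 0.05)
  shp <- simulate_unit(tt, mechanism_spec("sharpening", baseline_rate = 20,
                                          tuning_gains = c(8, 5),
                                          attenuation = 0.3),
                       tuned_stimuli = tun, seed = 5)
  expect_equal(ratio(shp, "s1"), 1.0, tolerance = 0.05)
  expect_equal(ratio(shp, "s2"), 0.7, tolerance = 0.05)
  # facilitation: rate unchanged inside the shortened window, spike count
  # over the full response period scales with duration
  fac <- simulate_unit(tt, mechanism_spec("facilitation", baseline_rate = 20,
                                          tuning_gains = c(8, 5),
                                          attenuation = 0.3,
                                          onset_latency = 300,
                                          response_duration = 600),
                       tuned_stimuli = tun, seed = 6)
  i <- fac$trial_stimulus == "s1"
  count_p <- mean(counts_in(fac, i & fac$trial_condition == "primed",
                            c(300, 900)))
  count_c <- mean(counts_in(fac, i & fac$trial_condition == "control",
                            c(300, 900)))
  # expected: control 8*20*0.6 = 96 extra-ish; primed window only 420 ms of
  # elevated firing: (0.42 * 160 + 0.18 * 20) vs 0.6 * 160 above baseline
  expect_equal(count_p / count_c, (0.42 * 160 + 0.18 * 20) / (0.6 * 160),
               tolerance = 0.05)
})

test_that("unit simulation is reproducible and rejects bad mechanisms", {
  tt <- repeat_trials("s1", 10)
  m <- mechanism_spec("none")
  expect_identical(simulate_unit(tt, m, seed = 9)$spikes,
                   simulate_unit(tt, m, seed = 9)$spikes)
  expect_error(mechanism_spec("warmup"), "unknown mechanism|arg")
  expect_error(mechanism_spec(tuning_gains = c(1, 5)), "non-increasing")
  expect_error(mechanism_spec(attenuation = 1.5), "attenuation")
  expect_error(mechanism_spec(baseline_rate = -1), ">= 0")
})

test_that("population simulation attaches regions and ground truth", {
  sess <- cached_session()
  pop <- simulate_population(
    sess$trials,
    list(list(region = "AM", n_units = 3,
              mech = mechanism_spec("sharpening")),
         list(region = "HC", n_units = 2,
              mech = mechanism_spec("fatiguing"))),
    stim_set = sess$stim_set, seed = 11)
  expect_length(pop, 5)
  expect_equal(vapply(pop, `[[`, character(1), "region"),
               c("AM", "AM", "AM", "HC", "HC"))
  expect_equal(vapply(pop, function(u) u$ground_truth$mechanism,
                      character(1)),
               c(rep("sharpening", 3), rep("fatiguing", 2)))
  # tuned stimuli drawn within one category by default
  for (u in pop) {
    cats <- unique(sess$stim_set$category_of[u$ground_truth$tuned_stimuli])
    expect_length(cats, 1)
  }
  expect_error(
    simulate_population(sess$trials,
                        list(list(region = "AM", n_units = 0,
                                  mech = mechanism_spec()))),
    "n_units")
})

test_that("iEEG simulator produces labelled segments with ground truth", {
  sess <- cached_session()
  spec <- erp_template_spec(artifact_rate = 0)
  seg <- simulate_ieeg(sess$trials, spec, seed = 2)
  expect_equal(dim(seg$data), c(1000, 768))
  expect_false(any(seg$artifact_truth))
  expect_setequal(unique(seg$condition), c("primed", "control"))
  # artifact rate honoured and flagged
  spec2 <- erp_template_spec(artifact_rate = 0.1)
  seg2 <- simulate_ieeg(sess$trials, spec2, seed = 2)
  expect_equal(mean(seg2$artifact_truth), 0.1, tolerance = 0.3)
  expect_identical(simulate_ieeg(sess$trials, spec2, seed = 2)$data,
                   seg2$data)
  # condition template difference survives averaging
  pm <- colMeans(seg$data[seg$condition == "primed", ])
  cm <- colMeans(seg$data[seg$condition == "control", ])
  expect_gt(max(abs(pm - cm)), 1)
})

test_that("segment windows that cannot host the analyses are rejected", {
  expect_error(erp_template_spec(window = c(-200, 1500)), "cover")
})
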