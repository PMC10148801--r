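# iEEG module: filtering, segmentation, baseline, the two median-ratio
# artifact filters, ERPs, and peak latencies.

test_that("constant input becomes all-zero after baseline correction", {
  fs <- 1024
  trace <- rep(3.3, fs * 20)
  onsets <- c(5000, 9000, 13000)
  seg <- suppressWarnings(
    preprocess_ieeg(trace, fs, onsets, rep("control", 3)))
  expect_equal(dim(seg$data), c(3, 768))
  expect_lt(max(abs(seg$data)), 1e-6)
  expect_true(seg$baseline_corrected)
})

test_that("the designed filters attenuate a 100 Hz tone by >= 20 dB", {
  filt <- design_bandpass(256, c(0.1, 80))
  h <- signal::freqz(filt$lp, n = 512, Fs = 256)
  # single-pass response at 100 Hz; filtfilt squares the magnitude
  mag <- abs(h$h[which.min(abs(h$f - 100))])
  atten_db <- -20 * log10(mag^2)
  expect_gte(atten_db, 20)
  # passband is essentially flat
  mag10 <- abs(h$h[which.min(abs(h$f - 10))])
  expect_equal(mag10^2, 1, tolerance = 0.01)
})

test_that("a noise-free template survives the pipeline up to filter transients", {
  fs <- 1024
  spec <- erp_template_spec(fs = fs)
  template <- erp_template(spec, "control")
  n <- length(template)
  trace <- rep(0, fs * 30)
  onset_ms <- 10000
  i0 <- round((onset_ms - 1000) / 1000 * fs) + 1
  trace[i0:(i0 + n - 1)] <- template
  seg <- preprocess_ieeg(trace, fs, onset_ms, "control")
  target <- erp_template(erp_template_spec(fs = 256), "control")
  # compare away from segment edges (zero-phase filtering leaves the
  # interior intact); peaks line up to within one sample
  mid <- 200:700
  expect_gt(cor(seg$data[1, mid], target[mid]), 0.99)
  expect_equal(which.min(seg$data[1, ]), which.min(target), tolerance = 1)
})

test_that("baseline window mean is zero for every emitted segment", {
  sess <- cached_session()
  seg <- baseline_correct(simulate_ieeg(sess$trials, seed = 1))
  idx <- mtladapt:::window_to_samples(c(-200, 0), seg$fs, seg$window[1])
  bl <- rowMeans(seg$data[, idx[1]:(idx[2] - 1)])
  expect_lt(max(abs(bl)), 1e-9)
})

test_that("homogeneous segments are never flagged", {
  data <- matrix(rep(sin(seq_len(768) / 20), each = 100), nrow = 100)
  expect_identical(reject_artifacts(data), rep(FALSE, 100))
})

test_that("a 10x segment is flagged by both ratio rules", {
  base <- sin(seq_len(768) / 20)
  data <- matrix(rep(base, each = 100), nrow = 100, byrow = FALSE)
  data[17, ] <- 10 * base
  maxima <- apply(abs(data), 1, max)
  meds <- apply(abs(data), 1, median)
  expect_gt(maxima[17] / median(maxima), 2.5)
  expect_gt(meds[17] / median(meds), 2.5)
  expect_identical(which(reject_artifacts(data)), 17L)
})

test_that("the 2.5 ratio boundary is strict: 2.4 retained, 2.6 removed", {
  base <- cos(seq_len(768) / 15)
  data <- matrix(rep(base, each = 50), nrow = 50)
  data[5, ] <- 2.4 * base
  expect_false(any(reject_artifacts(data)))
  data[5, ] <- 2.6 * base
  expect_identical(which(reject_artifacts(data)), 5L)
  # exactly 2.5 does not exceed the threshold
  data[5, ] <- 2.5 * base
  expect_false(any(reject_artifacts(data)))
})

test_that("artifact rejection is permutation-equivariant and guards degenerate input", {
  set.seed(1)
  data <- matrix(rnorm(40 * 768), 40)
  data[c(3, 30), ] <- data[c(3, 30), ] * 8
  mask <- reject_artifacts(data)
  perm <- sample(40)
  expect_identical(reject_artifacts(data[perm, ]), mask[perm])
  expect_error(reject_artifacts(matrix(0, 10, 768)), "zero")
  expect_error(reject_artifacts(data[1:2, ]), ">= 3 segments")
})

test_that("ERP is the per-condition mean and degenerates correctly", {
  tmpl <- erp_template(erp_template_spec())
  data <- rbind(tmpl, tmpl + 1, 2 * tmpl)
  seg <- segments_from_matrix(data,
                              condition = c("primed", "primed", "control"))
  erp <- compute_erp(seg)
  expect_equal(erp$traces$primed, tmpl + 0.5, ignore_attr = TRUE)
  expect_equal(erp$traces$control, 2 * tmpl, ignore_attr = TRUE)
  expect_equal(unname(erp$n), c(2L, 1L))
  # empty condition after masking errors by name
  expect_error(compute_erp(seg, mask = c(FALSE, FALSE, TRUE)),
               "control")
})

test_that("ERP noise variance shrinks as 1/n", {
  set.seed(7)
  n <- 400
  seg <- segments_from_matrix(matrix(rnorm(n * 100), n, 100),
                              condition = rep(c("primed", "control"),
                                              each = n / 2))
  erp <- compute_erp(seg)
  expect_equal(var(erp$traces$primed), 1 / (n / 2), tolerance = 0.3)
})

test_that("peak latency finds the signed extremum inside the window", {
  fs <- 256
  t <- mtladapt:::sample_times(768, fs, -1000)
  trace <- -exp(-((t - 270) / 30)^2)  # negative peak at 270 ms
  erp <- structure(list(traces = list(primed = trace, control = trace),
                        fs = fs, window = c(-1000, 2000)), class = "erp")
  lat <- mtladapt:::peak_latency(trace, fs, -1000, c(200, 400), "negative")
  expect_equal(lat, 270, tolerance = 1000 / fs)
  # window clipping: a larger out-of-window peak is ignored
  trace2 <- trace - 3 * exp(-((t - 450) / 30)^2)
  lat2 <- mtladapt:::peak_latency(trace2, fs, -1000, c(200, 400), "negative")
  expect_equal(lat2, 270, tolerance = 1000 / fs)
  # flat trace: first sample with warning
  expect_warning(
    lat3 <- mtladapt:::peak_latency(rep(0, 768), fs, -1000, c(200, 400),
                                    "negative"),
    "flat")
  expect_equal(lat3, mtladapt:::sample_times(768, fs, -1000)[
    mtladapt:::window_to_samples(c(200, 400), fs, -1000)[1]])
})

test_that("peak latency is invariant to uniform amplitude scaling", {
  set.seed(2)
  trace <- cumsum(rnorm(768))
  l1 <- mtladapt:::peak_latency(trace, 256, -1000, c(200, 750), "positive")
  l2 <- mtladapt:::peak_latency(5 * trace, 256, -1000, c(200, 750),
                                "positive")
  expect_identical(l1, l2)
})

test_that("a constructed -16 ms shift is recovered by the latency contrast", {
  fs <- 256
  t <- mtladapt:::sample_times(768, fs, -1000)
  mk_erp <- function(shift, noise_seed) {
    set.seed(noise_seed)
    ctrl <- -10 * exp(-((t - 283) / 45)^2) + rnorm(768, 0, 0.1)
    prim <- -10 * exp(-((t - 283 - shift) / 45)^2) + rnorm(768, 0, 0.1)
    structure(list(traces = list(primed = prim, control = ctrl), fs = fs,
                   window = c(-1000, 2000)), class = "erp")
  }
  erps <- lapply(1:30, function(s) mk_erp(16, s))
  res <- peak_latency_contrast(erps, c(200, 400), "negative")
  expect_equal(res$median_diff, -16, tolerance = 1000 / fs)
  expect_lt(res$p_value, 0.001)
  expect_true(all(res$latencies >= 200 & res$latencies < 400))
})
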