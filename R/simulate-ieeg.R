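#' ERP template specification for the iEEG simulator
#'
#' Defines the noise-free per-trial template as a sum of Gaussian-shaped
#' deflections, plus condition effects and an artifact model. The default
#' template has a negative deflection at 283 ms and a positive one at
#' 520 ms, so that the early (200-400 ms, negative) and late (400-750 ms,
#' positive) peak-latency search windows are meaningful; the default primed
#' condition is scaled down in amplitude and shifted earlier by 16 ms.
#'
#' @param fs Sampling rate in Hz.
#' @param window Segment window in ms, must cover `c(-1000, 2000)`.
#' @param peaks Data frame with columns `polarity` (+1/-1), `latency_ms`,
#'   `amplitude` (uV), `width_ms` (Gaussian SD).
#' @param amp_scale Named numeric, per-condition amplitude scaling.
#' @param latency_shift Named numeric, per-condition latency shift in ms
#'   (negative = earlier).
#' @param noise_sd SD of the additive 1/f noise (uV).
#' @param artifact_rate Probability that a trial carries an injected
#'   amplitude-burst artifact.
#' @param artifact_factor Multiplicative amplitude of the burst.
#' @param artifact_duration Burst length in ms.
#' @return A list of class `erp_template_spec`.
#' @export
erp_template_spec <- function(fs = 256, window = c(-1000, 2000),
                              peaks = data.frame(
                                polarity = c(-1, 1),
                                latency_ms = c(283, 520),
                                amplitude = c(12, 16),
                                width_ms = c(45, 90)),
                              amp_scale = c(primed = 0.75, control = 1),
                              latency_shift = c(primed = -16, control = 0),
                              noise_sd = 6, artifact_rate = 0.05,
                              artifact_factor = 10,
                              artifact_duration = 300) {
  check_window(window)
  if (window[1] > -1000 || window[2] < 2000) {
    stop("`window` must cover [-1000, 2000] ms so baseline and analysis ",
         "windows exist", call. = FALSE)
  }
  stopifnot(fs > 0, is.data.frame(peaks),
            all(c("polarity", "latency_ms", "amplitude", "width_ms") %in%
                  names(peaks)))
  if (!all(c("primed", "control") %in% names(amp_scale)) ||
      !all(c("primed", "control") %in% names(latency_shift))) {
    stop("`amp_scale` and `latency_shift` need 'primed' and 'control' ",
         "entries", call. = FALSE)
  }
  if (noise_sd < 0 || artifact_rate < 0 || artifact_rate > 1) {
    stop("`noise_sd` >= 0 and `artifact_rate` in [0, 1] required",
         call. = FALSE)
  }
  structure(list(fs = fs, window = window, peaks = peaks,
                 amp_scale = amp_scale, latency_shift = latency_shift,
                 noise_sd = noise_sd, artifact_rate = artifact_rate,
                 artifact_factor = artifact_factor,
                 artifact_duration = artifact_duration),
            class = "erp_template_spec")
}

#' Evaluate the noise-free ERP template
#'
#' @param spec An [erp_template_spec()].
#' @param condition `"primed"` or `"control"` (applies that condition's
#'   amplitude scale and latency shift); `NULL` for the raw template.
#' @return Numeric vector, one value per sample of the segment window.
#' @export
erp_template <- function(spec, condition = NULL) {
  n <- round((spec$window[2] - spec$window[1]) * spec$fs / 1000)
  t <- sample_times(n, spec$fs, spec$window[1])
  scale <- 1
  shift <- 0
  if (!is.null(condition)) {
    scale <- spec$amp_scale[[condition]]
    shift <- spec$latency_shift[[condition]]
  }
  y <- numeric(n)
  for (i in seq_len(nrow(spec$peaks))) {
    p <- spec$peaks[i, ]
    y <- y + p$polarity * p$amplitude *
      exp(-0.5 * ((t - (p$latency_ms + shift)) / p$width_ms)^2)
  }
  y * scale
}

#' Simulate per-trial iEEG segments for a session
#'
#' Each target trial's trace is its condition's template plus 1/f noise;
#' artifacts are injected as multiplicative amplitude bursts at the
#' configured rate, with ground-truth flags retained so artifact-rejection
#' recall can be measured. Traces are raw (not baseline-corrected); apply
#' [baseline_correct()] before analysis.
#'
#' @param tt Trial table; one segment per row with
#'   `condition != "discarded_first"`.
#' @param spec An [erp_template_spec()].
#' @param seed Optional integer seed.
#' @param region Anatomical label attached to the segments.
#' @return An `ieeg_segments` object: list with `data` (trials x samples
#'   matrix), `fs`, `window`, `condition` (character per trial), `region`,
#'   `artifact_truth` (logical per trial), `baseline_corrected` flag.
#' @export
simulate_ieeg <- function(tt, spec = erp_template_spec(), seed = NULL,
                          region = "AM") {
  if (!inherits(spec, "erp_template_spec")) {
    stop("`spec` must be an erp_template_spec() object", call. = FALSE)
  }
  tg <- tt[tt$condition != "discarded_first", , drop = FALSE]
  n_trials <- nrow(tg)
  n <- round((spec$window[2] - spec$window[1]) * spec$fs / 1000)
  with_seed(seed, {
    templates <- list(primed = erp_template(spec, "primed"),
                      control = erp_template(spec, "control"))
    cond <- as.character(tg$condition)
    data <- matrix(0, n_trials, n)
    for (i in seq_len(n_trials)) {
      data[i, ] <- templates[[cond[i]]] + spec$noise_sd * pink_noise(n)
    }
    artifact <- stats::runif(n_trials) < spec$artifact_rate
    if (any(artifact)) {
      dur_samp <- max(1L, round(spec$artifact_duration * spec$fs / 1000))
      for (i in which(artifact)) {
        start <- sample.int(max(1L, n - dur_samp), 1L)
        idx <- start:(start + dur_samp - 1L)
        data[i, idx] <- data[i, idx] * spec$artifact_factor
      }
    }
    new_ieeg_segments(data, spec$fs, spec$window, cond, region,
                      artifact_truth = artifact)
  })
}

#' @noRd
new_ieeg_segments <- function(data, fs, window, condition, region = NA,
                              artifact_truth = NULL,
                              baseline_corrected = FALSE) {
  structure(list(data = data, fs = fs, window = window,
                 condition = condition, region = region,
                 artifact_truth = artifact_truth,
                 baseline_corrected = baseline_corrected),
            class = "ieeg_segments")
}

#' @export
print.ieeg_segments <- function(x, ...) {
  cat(sprintf(
    "<ieeg_segments> %d trials x %d samples @ %g Hz, window [%g, %g) ms%s\n",
    nrow(x$data), ncol(x$data), x$fs, x$window[1], x$window[2],
    if (isTRUE(x$baseline_corrected)) ", baseline-corrected" else ""))
  invisible(x)
}
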