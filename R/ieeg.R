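# iEEG preprocessing, median-ratio artifact rejection, ERPs, peak latency.
# All windows half-open [start, end) ms; segments cover [-1000, 2000) ms at
# 256 Hz after preprocessing.

#' Design the preprocessing band-pass filters
#'
#' Zero-phase (forward-backward) IIR filtering is used so that filtering
#' cannot displace ERP peak latencies. The band is realized as a cascade of
#' a low-order Butterworth high-pass (stable at a 0.1 Hz edge) and a
#' higher-order Butterworth low-pass; each is applied with
#' [signal::filtfilt()], doubling its attenuation.
#'
#' @param fs Sampling rate in Hz.
#' @param band Pass band in Hz, default `c(0.1, 80)`.
#' @param hp_order,lp_order Butterworth orders (single pass).
#' @return List with `hp` and `lp` filter objects and the design metadata.
#' @export
design_bandpass <- function(fs = 256, band = c(0.1, 80), hp_order = 2,
                            lp_order = 6) {
  stopifnot(band[1] > 0, band[2] < fs / 2, band[1] < band[2])
  list(hp = signal::butter(hp_order, band[1] / (fs / 2), type = "high"),
       lp = signal::butter(lp_order, band[2] / (fs / 2), type = "low"),
       fs = fs, band = band, hp_order = hp_order, lp_order = lp_order)
}

#' @noRd
apply_bandpass <- function(x, filt) {
  x <- signal::filtfilt(filt$hp, x)
  signal::filtfilt(filt$lp, x)
}

#' Subtract the pre-stimulus baseline from each segment
#'
#' Subtracts the mean of the `[-200, 0)` ms window from every sample of the
#' corresponding segment.
#'
#' @param segments An `ieeg_segments` object.
#' @param baseline Baseline window in ms, default `c(-200, 0)`.
#' @return The segments with zero-mean baselines and
#'   `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(segments, baseline = c(-200, 0)) {
  stopifnot(inherits(segments, "ieeg_segments"))
  check_window(baseline, "baseline")
  idx <- window_to_samples(baseline, segments$fs, segments$window[1])
  cols <- idx[1]:(idx[2] - 1L)
  bl <- rowMeans(segments$data[, cols, drop = FALSE])
  segments$data <- segments$data - bl
  segments$baseline_corrected <- TRUE
  segments
}

#' Preprocess a continuous iEEG trace into analysis segments
#'
#' Anti-aliased resampling to `target_fs` (default 256 Hz), zero-phase
#' band-pass filtering (default 0.1-80 Hz), segmentation to
#' `[-1000, 2000)` ms around each event onset, and baseline correction by
#' the `[-200, 0)` ms mean. Events too close to the recording edges are
#' dropped with a warning.
#'
#' @param trace Numeric vector, one referenced continuous channel.
#' @param native_fs Native sampling rate in Hz (must be >= 512 so the
#'   downsampling is a true decimation).
#' @param onsets_ms Event onset times in ms from the start of the trace.
#' @param condition Character vector of condition labels, one per onset.
#' @param target_fs Output rate, default 256 Hz.
#' @param band Pass band in Hz.
#' @param window Segment window in ms relative to onset.
#' @param baseline Baseline window in ms.
#' @param region Optional anatomical label.
#' @return An `ieeg_segments` object (baseline-corrected).
#' @export
preprocess_ieeg <- function(trace, native_fs, onsets_ms, condition,
                            target_fs = 256, band = c(0.1, 80),
                            window = c(-1000, 2000), baseline = c(-200, 0),
                            region = NA) {
  stopifnot(is.numeric(trace), length(onsets_ms) == length(condition))
  if (native_fs < 2 * target_fs) {
    stop("`native_fs` must be >= ", 2 * target_fs,
         " Hz for downsampling to ", target_fs, " Hz", call. = FALSE)
  }
  check_window(window)
  # remove the DC offset first: a large offset would ripple at the
  # resampler's edges and ring through the slow (0.1 Hz) high-pass
  # transient across the whole recording
  trace <- trace - mean(trace)
  x <- if (native_fs != target_fs) {
    resample_trace(trace, native_fs, target_fs)
  } else trace
  filt <- design_bandpass(target_fs, band)
  x <- apply_bandpass(x, filt)
  n_seg <- round((window[2] - window[1]) * target_fs / 1000)
  step <- 1000 / target_fs
  # sample index of each segment's first sample (time of sample k is
  # (k - 1) * step ms from trace start)
  first <- ceiling((onsets_ms + window[1]) / step - 1e-9) + 1L
  keep <- first >= 1L & (first + n_seg - 1L) <= length(x)
  if (any(!keep)) {
    warning(sum(!keep), " event(s) too close to the recording edges; ",
            "segment(s) dropped", call. = FALSE)
  }
  data <- t(vapply(first[keep], function(i) x[i:(i + n_seg - 1L)],
                   numeric(n_seg)))
  seg <- new_ieeg_segments(data, target_fs, window,
                           as.character(condition)[keep], region)
  baseline_correct(seg, baseline)
}

# Rational-factor polyphase resampling with anti-alias filtering.
#' @noRd
resample_trace <- function(x, from_fs, to_fs) {
  g <- gcd_int(round(to_fs), round(from_fs))
  signal::resample(x, round(to_fs) / g, round(from_fs) / g)
}

#' @noRd
gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Median-ratio artifact rejection
#'
#' Two segment-level criteria, both computed on the same input set (no
#' iterative re-computation after removal):
#' * max-ratio: the maximum of the absolute signal in a segment divided by
#'   the median of these absolute maxima across segments;
#' * median-ratio (noise floor): the median of the absolute values of all
#'   samples in a segment divided by the median of these medians.
#'
#' A segment is flagged iff either ratio strictly exceeds `threshold`.
#'
#' @param segments An `ieeg_segments` object or a trials x samples matrix.
#' @param threshold Ratio threshold, default 2.5.
#' @return Logical vector, `TRUE` for flagged (artifactual) segments.
#' @export
reject_artifacts <- function(segments, threshold = 2.5) {
  data <- if (inherits(segments, "ieeg_segments")) segments$data else segments
  stopifnot(is.matrix(data))
  if (nrow(data) < 3L) {
    stop("need >= 3 segments to compute median ratios", call. = FALSE)
  }
  a <- abs(data)
  maxima <- apply(a, 1L, max)
  med_max <- stats::median(maxima)
  if (med_max == 0) {
    stop("median of absolute maxima is zero (all-zero data?); ",
         "ratios undefined", call. = FALSE)
  }
  medians <- apply(a, 1L, stats::median)
  med_med <- stats::median(medians)
  ratio_max <- maxima / med_max
  ratio_med <- if (med_med > 0) medians / med_med else rep(0, nrow(data))
  unname(ratio_max > threshold | ratio_med > threshold)
}

#' Condition-wise event-related potentials
#'
#' Arithmetic mean of artifact-free segments per condition, with per-sample
#' SEM and contributing-segment counts.
#'
#' @param segments A baseline-corrected `ieeg_segments` object.
#' @param mask Optional logical vector of segments to exclude (e.g. from
#'   [reject_artifacts()]).
#' @param conditions Conditions to average, default `c("primed","control")`.
#' @return An `erp` object: list with `traces` (named list of mean traces),
#'   `sem`, `n` (segments per condition), `fs`, `window`, `region`.
#' @export
compute_erp <- function(segments, mask = NULL,
                        conditions = c("primed", "control")) {
  stopifnot(inherits(segments, "ieeg_segments"))
  keep <- rep(TRUE, nrow(segments$data))
  if (!is.null(mask)) keep <- keep & !mask
  traces <- list()
  sem <- list()
  n <- integer(0)
  for (cond in conditions) {
    i <- keep & segments$condition == cond
    if (!any(i)) {
      stop("no clean segments left in condition '", cond, "'", call. = FALSE)
    }
    m <- segments$data[i, , drop = FALSE]
    traces[[cond]] <- colMeans(m)
    sem[[cond]] <- apply(m, 2L, stats::sd) / sqrt(nrow(m))
    n[cond] <- nrow(m)
  }
  structure(list(traces = traces, sem = sem, n = n, fs = segments$fs,
                 window = segments$window, region = segments$region),
            class = "erp")
}

#' Grand-average ERP across sessions
#'
#' Averages session ERPs (equal weight per session, the convention for
#' grand averages across recording sites).
#'
#' @param erps List of `erp` objects with identical windows and rates.
#' @return An `erp` object whose `n` counts contributing sessions.
#' @export
grand_average_erp <- function(erps) {
  stopifnot(length(erps) >= 1L, all(vapply(erps, inherits, logical(1), "erp")))
  conds <- names(erps[[1]]$traces)
  traces <- list()
  sem <- list()
  n <- integer(0)
  for (cond in conds) {
    m <- do.call(rbind, lapply(erps, function(e) e$traces[[cond]]))
    traces[[cond]] <- colMeans(m)
    sem[[cond]] <- apply(m, 2L, stats::sd) / sqrt(nrow(m))
    n[cond] <- nrow(m)
  }
  structure(list(traces = traces, sem = sem, n = n, fs = erps[[1]]$fs,
                 window = erps[[1]]$window, region = erps[[1]]$region),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp> %s, %g Hz, window [%g, %g) ms; n = %s\n",
              if (is.na(x$region)) "unlabelled region" else x$region,
              x$fs, x$window[1], x$window[2],
              paste(sprintf("%s: %d", names(x$n), x$n), collapse = ", ")))
  invisible(x)
}

#' @export
plot.erp <- function(x, conditions = names(x$traces),
                     col = c("firebrick", "navy"), ...) {
  t <- sample_times(length(x$traces[[1]]), x$fs, x$window[1])
  ylim <- range(unlist(x$traces[conditions]))
  graphics::plot(t, x$traces[[conditions[1]]], type = "l", col = col[1],
                 xlab = "time (ms)", ylab = "amplitude (uV)", ylim = ylim, ...)
  for (i in seq_along(conditions)[-1]) {
    graphics::lines(t, x$traces[[conditions[i]]],
                    col = col[(i - 1) %% length(col) + 1])
  }
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = conditions, col = col, lty = 1,
                   bty = "n")
  invisible(x)
}

# Latency (ms) of the signed extremum inside a half-open window; earliest
# sample wins ties (flat traces warn).
#' @noRd
peak_latency <- function(trace, fs, t0, window, polarity) {
  idx <- window_to_samples(window, fs, t0)
  seg <- trace[idx[1]:(idx[2] - 1L)]
  if (length(unique(seg)) == 1L) {
    warning("flat trace in the search window; returning its first sample",
            call. = FALSE)
  }
  k <- if (polarity == "negative") which.min(seg) else which.max(seg)
  t0 + (idx[1] + k - 2L) * 1000 / fs
}

#' Peak-latency contrast between conditions across sessions
#'
#' For each session ERP, finds the latency of the signed extremum (minimum
#' for `polarity = "negative"`, maximum for `"positive"`) within the
#' half-open search window, per condition, and contrasts the paired
#' latencies with a two-tailed Wilcoxon signed-rank test. The study's search
#' windows are 200-400 ms (negative, early) and 400-750 ms (positive, late).
#'
#' @param erps List of session `erp` objects.
#' @param window Search window in ms, e.g. `c(200, 400)`.
#' @param polarity `"negative"` or `"positive"`.
#' @return A `peak_latency_result`: per-session latencies, group Md/IQR per
#'   condition, signed-rank statistic and p-value.
#' @export
peak_latency_contrast <- function(erps, window = c(200, 400),
                                  polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  check_window(window)
  stopifnot(length(erps) >= 2L,
            all(vapply(erps, inherits, logical(1), "erp")))
  if (window[1] < erps[[1]]$window[1] || window[2] > erps[[1]]$window[2]) {
    stop("search window must lie inside the segment window", call. = FALSE)
  }
  lat <- t(vapply(erps, function(e) {
    c(primed = peak_latency(e$traces$primed, e$fs, e$window[1], window,
                            polarity),
      control = peak_latency(e$traces$control, e$fs, e$window[1], window,
                             polarity))
  }, numeric(2)))
  d <- lat[, "primed"] - lat[, "control"]
  if (all(d == 0)) {
    stat <- 0; p <- 1
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(lat[, "primed"], lat[, "control"], paired = TRUE,
                         exact = FALSE))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(
    list(latencies = as.data.frame(lat), window = window,
         polarity = polarity,
         md_primed = stats::median(lat[, "primed"]),
         iqr_primed = stats::IQR(lat[, "primed"]),
         md_control = stats::median(lat[, "control"]),
         iqr_control = stats::IQR(lat[, "control"]),
         median_diff = stats::median(d),
         statistic = stat, p_value = p, n = nrow(lat)),
    class = "peak_latency_result")
}

#' @export
print.peak_latency_result <- function(x, ...) {
  cat(sprintf(
    "<peak_latency_result> %s peak in [%g, %g) ms, %d sessions\n",
    x$polarity, x$window[1], x$window[2], x$n))
  cat(sprintf("  primed : Md %.1f ms [IQR %.1f]\n", x$md_primed, x$iqr_primed))
  cat(sprintf("  control: Md %.1f ms [IQR %.1f]\n", x$md_control,
              x$iqr_control))
  cat(sprintf("  median paired difference %.1f ms; signed-rank V = %g, p = %.3g\n",
              x$median_diff, x$statistic, x$p_value))
  invisible(x)
}
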