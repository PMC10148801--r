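# Single-unit analyses: firing-rate normalization, binwise rank-sum
# response detection with Simes correction, semantic tuning-curve rank
# contrasts, Poisson-surprise burst detection, and the pre-stimulus
# spreading-activation test. Windows are half-open [start, end) ms; rates
# are Hz = count / window length. Two distinct response-related windows are
# used on purpose: the z-score activation window [100, 1000) and the
# response window [0, 1000) of the detection criterion and tuning curves.

# --- normalization ---------------------------------------------------------

#' Z-score a unit's activation firing rates against its baseline
#'
#' Per trial, `z = (rate_activation - mean_baseline) / sd_baseline`, where
#' the baseline mean and SD are taken over the baseline-window rates of all
#' trials pooled across conditions.
#'
#' @param unit A `unit_recording`.
#' @param baseline_window Baseline window in ms, default `c(-500, 0)`.
#' @param activation_window Activation window in ms, default `c(100, 1000)`.
#' @return List with `z` (per-trial z-scores), `baseline_mean`,
#'   `baseline_sd` (Hz), and `valid`. A silent unit (zero baseline SD) gets
#'   `valid = FALSE`, `z = NULL`, and a warning: it cannot enter z-based
#'   analyses.
#' @export
zscore_rates <- function(unit, baseline_window = c(-500, 0),
                         activation_window = c(100, 1000)) {
  stopifnot(inherits(unit, "unit_recording"))
  if (length(unit$spikes) < 2L) {
    stop("need >= 2 trials to estimate the baseline distribution",
         call. = FALSE)
  }
  base <- rate_in_window(unit$spikes, baseline_window)
  bm <- mean(base)
  bs <- stats::sd(base)
  if (bs == 0) {
    warning("zero baseline SD (silent unit); excluded from z-based analyses",
            call. = FALSE)
    return(list(z = NULL, baseline_mean = bm, baseline_sd = 0,
                valid = FALSE))
  }
  act <- rate_in_window(unit$spikes, activation_window)
  list(z = (act - bm) / bs, baseline_mean = bm, baseline_sd = bs,
       valid = TRUE)
}

# --- rank-sum and Simes machinery ------------------------------------------

# Two-sided Wilcoxon rank-sum p-value by normal approximation with tie and
# continuity correction; agrees with stats::wilcox.test(exact = FALSE).
# Kept internal and fast: the binwise criterion runs it tens of thousands
# of times (10 bin rates vs thousands of baseline rates; exact enumeration
# would be pointless).
#' @noRd
ranksum_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  nties <- table(r)
  n <- nx + ny
  sigma2 <- (nx * ny / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

# Precomputed reference sample for repeated rank-sum tests against the
# same large y (the pooled baseline-bin rates): sorted values, tie table,
# and the tie-correction sum over y alone.
#' @noRd
make_ranksum_ref <- function(y) {
  ys <- sort(y)
  r <- rle(ys)
  list(sorted = ys, n = length(ys), vals = r$values, counts = r$lengths,
       tie_sum = sum(r$lengths^3 - r$lengths))
}

# ranksum_p(x, y) with y replaced by a make_ranksum_ref() object; exact
# same normal approximation with tie and continuity correction. Assumes
# the values of x and y are separated by more than 1 when unequal (true
# for rates that are multiples of 10 Hz).
#' @noRd
ranksum_p_ref <- function(x, ref) {
  nx <- length(x)
  ny <- ref$n
  le <- findInterval(x, ref$sorted)            # y <= x_i
  lt <- findInterval(x - 0.5, ref$sorted)      # y <  x_i
  ey <- le - lt
  lx <- vapply(x, function(v) sum(x < v), numeric(1))
  ex <- vapply(x, function(v) sum(x == v), numeric(1))
  ranks <- lt + lx + (ey + ex + 1) / 2
  w <- sum(ranks) - nx * (nx + 1) / 2
  n <- nx + ny
  tie_sum <- ref$tie_sum
  for (v in unique(x)) {
    tx <- sum(x == v)
    i <- match(v, ref$vals)
    ty <- if (is.na(i)) 0 else ref$counts[i]
    t_all <- tx + ty
    tie_sum <- tie_sum + (t_all^3 - t_all) - (ty^3 - ty)
  }
  sigma2 <- (nx * ny / 12) * ((n + 1) - tie_sum / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - nx * ny / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Simes global test
#'
#' Rejects the global null over `m` p-values iff
#' `min_i p_(i) * m / i <= alpha` for the sorted p-values `p_(i)`
#' (equivalently: any `p_(i) <= i * alpha / m`).
#'
#' @param p Numeric vector of p-values.
#' @param alpha Level, default 0.001.
#' @return Logical: global null rejected?
#' @export
simes_test <- function(p, alpha = 0.001) {
  stopifnot(length(p) >= 1L, all(p >= 0 & p <= 1), alpha > 0, alpha <= 1)
  m <- length(p)
  min(sort(p) * m / seq_len(m)) <= alpha
}

# The 19 overlapping 100 ms response bins: [0,100),...,[900,1000) and
# [50,150),...,[850,950).
#' @noRd
response_bins <- function() {
  starts <- c(seq(0, 900, by = 100), seq(50, 850, by = 100))
  cbind(start = starts, end = starts + 100)
}

# Baseline-bin rates: the spike rate (Hz) in each of the five 100 ms bins
# tiling [-500, 0) ms, for every trial, pooled into one vector. This is
# the baseline distribution the binwise criterion tests against -- the
# same bin width as the response bins, so the two samples are exchangeable
# for a unit firing at its baseline rate.
#' @noRd
baseline_bin_rates <- function(spikes) {
  edges <- seq(-500, 0, by = 100)
  out <- matrix(0, length(spikes), 5L)
  for (i in seq_along(spikes)) {
    t <- spikes[[i]]
    t <- t[t >= -500 & t < 0]
    out[i, ] <- if (length(t)) tabulate(findInterval(t, edges), 5L) else
      integer(5L)
  }
  as.vector(out) * 10
}

# Counts per trial in each of the 19 bins; spikes is a list of sorted
# timestamp vectors. Returns trials x 19 matrix of rates in Hz.
#' @noRd
bin_rates <- function(spikes, bins = response_bins()) {
  edges1 <- seq(0, 1000, by = 100)
  edges2 <- seq(50, 950, by = 100)
  out <- matrix(0, length(spikes), nrow(bins))
  for (i in seq_along(spikes)) {
    t <- spikes[[i]]
    t1 <- t[t >= 0 & t < 1000]
    c1 <- if (length(t1)) tabulate(findInterval(t1, edges1), 10L) else
      integer(10L)
    t2 <- t[t >= 50 & t < 950]
    c2 <- if (length(t2)) tabulate(findInterval(t2, edges2), 9L) else
      integer(9L)
    out[i, ] <- c(c1, c2)
  }
  out * 10  # 100 ms bins -> Hz
}

# --- response detection ----------------------------------------------------

#' Binwise rank-sum response criterion for one unit-stimulus pair
#'
#' Decides whether a stimulus is response-eliciting for a unit. Spike rates
#' in 19 overlapping 100 ms bins over the 10 presentations of the stimulus
#' (primed and control pooled) are each compared by a two-sided rank-sum
#' test against the unit's baseline distribution: the spike rates in the
#' five 100 ms bins tiling `[-500, 0)` ms of all the session's trials
#' (matching the response bin width keeps the two samples exchangeable for
#' a unit firing at its baseline rate). The stimulus counts as
#' response-eliciting iff (a) the Simes-corrected family of 19 bin tests
#' is significant at `alpha`, (b) the mean response-window (`[0, 1000)`
#' ms) rate across the 10 presentations exceeds the mean baseline rate,
#' and (c) at least one spike occurs in the response window in at least
#' half of the presentations.
#'
#' @param unit A `unit_recording`.
#' @param stimulus Stimulus id.
#' @param alpha Level of the Simes decision, default 0.001.
#' @param baseline_ref Optional precomputed baseline reference (internal;
#'   shared across stimuli by [response_decisions()]).
#' @return A one-row data frame (`response_decision`): `stimulus`,
#'   `simes_pass`, `rate_above_baseline`, `spike_presence`, `responsive`,
#'   and the 19 bin p-values as a list column `bin_p`.
#' @export
binwise_response_criterion <- function(unit, stimulus, alpha = 0.001,
                                       baseline_ref = NULL) {
  stopifnot(inherits(unit, "unit_recording"))
  idx <- which(unit$trial_stimulus == stimulus)
  if (length(idx) < 10L) {
    stop("stimulus '", stimulus, "' has ", length(idx),
         " presentations; the criterion needs 10", call. = FALSE)
  }
  if (is.null(baseline_ref)) {
    baseline_ref <- make_ranksum_ref(baseline_bin_rates(unit$spikes))
  }
  binrate <- bin_rates(unit$spikes[idx])
  p <- apply(binrate, 2L, ranksum_p_ref, ref = baseline_ref)
  simes_pass <- simes_test(p, alpha)
  resp_counts <- count_in_window(unit$spikes[idx], c(0, 1000))
  # response rate in Hz (1 s window) vs mean baseline rate in Hz
  rate_above <- mean(resp_counts) > mean(baseline_ref$sorted)
  presence <- sum(resp_counts >= 1L) >= ceiling(length(idx) / 2)
  out <- data.frame(stimulus = stimulus, simes_pass = simes_pass,
                    rate_above_baseline = rate_above,
                    spike_presence = presence,
                    responsive = simes_pass && rate_above && presence,
                    stringsAsFactors = FALSE)
  out$bin_p <- list(p)
  out
}

#' Response decisions for all stimuli of a unit
#'
#' Runs [binwise_response_criterion()] for every stimulus with >= 10
#' presentations, sharing the precomputed baseline distribution.
#'
#' @inheritParams binwise_response_criterion
#' @param stimuli Stimulus ids to test; defaults to all of the unit's.
#' @return Data frame with one row per stimulus.
#' @export
response_decisions <- function(unit, stimuli = NULL, alpha = 0.001) {
  stopifnot(inherits(unit, "unit_recording"))
  stimuli <- stimuli %||% sort(unique(unit$trial_stimulus))
  ref <- make_ranksum_ref(baseline_bin_rates(unit$spikes))
  do.call(rbind, lapply(stimuli, function(s) {
    binwise_response_criterion(unit, s, alpha, baseline_ref = ref)
  }))
}

#' Select units responding to multiple stimuli
#'
#' @param decisions Data frame with columns `unit` and `responsive`
#'   (one row per unit-stimulus pair).
#' @param min_stimuli Minimum number of response-eliciting stimuli
#'   (the headline analysis uses 4; 2 and 3 are supported variants).
#' @return Character vector of unit ids.
#' @export
select_multiresponsive_units <- function(decisions, min_stimuli = 4) {
  stopifnot(all(c("unit", "responsive") %in% names(decisions)))
  counts <- tapply(decisions$responsive, decisions$unit, sum)
  names(counts)[counts >= min_stimuli]
}

# --- tuning curves ---------------------------------------------------------

#' Build a unit's semantic tuning curve over its response-eliciting stimuli
#'
#' Stimuli are ordered by descending mean firing rate during the response
#' period (`[0, 1000)` ms, primed and control pooled); ties are broken by
#' stimulus id (stable). Per rank, the mean rate is computed separately for
#' the 5 primed and 5 control presentations and both are normalized by
#' `FRmax`, the control-condition rate of the rank-1 stimulus.
#'
#' @param unit A `unit_recording`.
#' @param responsive_stimuli Character vector of this unit's
#'   response-eliciting stimuli (e.g. from [response_decisions()]).
#' @param response_window Window in ms, default `c(0, 1000)`.
#' @return A `tuning_curve` data frame (rank, stimulus, pooled/primed/
#'   control rates in Hz, normalized primed/control values) with attributes
#'   `fr_max`, `unit_region`, `unit_class`; or `NULL` with a warning when
#'   `FRmax` is 0.
#' @export
build_tuning_curve <- function(unit, responsive_stimuli,
                               response_window = c(0, 1000)) {
  stopifnot(inherits(unit, "unit_recording"), length(responsive_stimuli) >= 1L)
  rates <- rate_in_window(unit$spikes, response_window)
  rows <- lapply(responsive_stimuli, function(s) {
    i <- unit$trial_stimulus == s
    data.frame(
      stimulus = s,
      pooled = mean(rates[i]),
      primed = mean(rates[i & unit$trial_condition == "primed"]),
      control = mean(rates[i & unit$trial_condition == "control"]),
      stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(-curve$pooled, curve$stimulus), , drop = FALSE]
  curve$rank <- seq_len(nrow(curve))
  fr_max <- curve$control[1]
  if (fr_max == 0) {
    warning("FRmax (control rate of the rank-1 stimulus) is 0; ",
            "unit excluded from tuning analyses", call. = FALSE)
    return(NULL)
  }
  curve$primed_norm <- curve$primed / fr_max
  curve$control_norm <- curve$control / fr_max
  rownames(curve) <- NULL
  structure(curve[, c("rank", "stimulus", "pooled", "primed", "control",
                      "primed_norm", "control_norm")],
            class = c("tuning_curve", "data.frame"),
            fr_max = fr_max, unit_region = unit$region,
            unit_class = unit$unit_class)
}

#' Rank-wise primed-vs-control contrast of tuning curves across units
#'
#' Per stimulus rank, contrasts the normalized primed and control values
#' across units with a two-tailed paired t-test (default; a Wilcoxon
#' signed-rank p-value is always reported alongside). Additionally
#' contrasts the attenuation (`control - primed`) between every pair of
#' ranks, which separates a uniform (fatiguing-like) from a rank-dependent
#' (sharpening-like) attenuation profile.
#'
#' @param curves List of `tuning_curve` objects from one region group.
#' @param ranks Ranks to contrast, default `1:4`. Units lacking a rank are
#'   excluded from that rank, with the per-rank `n` reported.
#' @param test `"paired_t"` (default) or `"signed_rank"`: which p-value the
#'   classification and printing lead with.
#' @return A `tuning_contrast` object: `per_rank` data frame (`rank`, `n`,
#'   condition means, `t`, `df`, CI, `p_t`, `V`, `p_wilcox`, `p`),
#'   `attenuation_pairs` data frame (pairwise rank contrasts of
#'   attenuation), `test`.
#' @export
contrast_tuning <- function(curves, ranks = 1:4,
                            test = c("paired_t", "signed_rank")) {
  test <- match.arg(test)
  curves <- Filter(Negate(is.null), curves)
  if (length(curves) < 3L) {
    stop("need >= 3 units with tuning curves", call. = FALSE)
  }
  get_rank <- function(curve, r, col) {
    i <- match(r, curve$rank)
    if (is.na(i)) NA_real_ else curve[[col]][i]
  }
  primed <- vapply(ranks, function(r) {
    vapply(curves, get_rank, numeric(1), r = r, col = "primed_norm")
  }, numeric(length(curves)))
  control <- vapply(ranks, function(r) {
    vapply(curves, get_rank, numeric(1), r = r, col = "control_norm")
  }, numeric(length(curves)))
  per_rank <- do.call(rbind, lapply(seq_along(ranks), function(j) {
    ok <- stats::complete.cases(primed[, j], control[, j])
    x <- primed[ok, j]
    y <- control[ok, j]
    if (sum(ok) < 3L || stats::sd(x - y) == 0) {
      tt <- list(statistic = c(t = NA_real_), parameter = c(df = sum(ok) - 1),
                 conf.int = c(NA_real_, NA_real_),
                 p.value = if (sum(ok) >= 3L) 1 else NA_real_)
      pw <- if (sum(ok) >= 3L) 1 else NA_real_
      vw <- NA_real_
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                exact = FALSE))
      pw <- wt$p.value
      vw <- unname(wt$statistic)
    }
    data.frame(rank = ranks[j], n = sum(ok),
               mean_primed = mean(x), mean_control = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               p_t = tt$p.value, V = vw, p_wilcox = pw)
  }))
  per_rank$p <- if (test == "paired_t") per_rank$p_t else per_rank$p_wilcox
  att <- control - primed  # units x ranks
  pairs <- utils::combn(seq_along(ranks), 2)
  attenuation_pairs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    ok <- stats::complete.cases(att[, a], att[, b])
    d <- att[ok, b] - att[ok, a]
    if (sum(ok) < 3L || stats::sd(d) == 0) {
      tt <- list(statistic = c(t = NA_real_), parameter = sum(ok) - 1,
                 p.value = if (sum(ok) >= 3L) 1 else NA_real_)
    } else {
      tt <- stats::t.test(att[ok, b], att[ok, a], paired = TRUE)
    }
    data.frame(rank_a = ranks[a], rank_b = ranks[b], n = sum(ok),
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  structure(list(per_rank = per_rank,
                 attenuation_pairs = attenuation_pairs,
                 test = test, n_units = length(curves)),
            class = "tuning_contrast")
}

#' @export
print.tuning_contrast <- function(x, ...) {
  cat(sprintf("<tuning_contrast> %d units, leading test: %s\n", x$n_units,
              x$test))
  print.data.frame(x$per_rank[, c("rank", "n", "mean_primed", "mean_control",
                                  "t", "df", "p")], digits = 3)
  cat("attenuation between ranks (rank_b - rank_a):\n")
  print.data.frame(x$attenuation_pairs, digits = 3)
  invisible(x)
}

#' Classify a population's adaptation profile
#'
#' Operationalizes the sharpening-vs-fatiguing decision from a rank
#' contrast. A rank counts as *attenuated* when its primed-vs-control test
#' is significant at `alpha` with primed < control (the mechanisms predict
#' attenuation, so the sign matters). The profile is:
#' * `"sharpening"` — rank 1 not attenuated, rank 2 attenuated, and the
#'   attenuation at rank 2 significantly exceeds that at rank 1;
#' * `"fatiguing"` — rank 1 attenuated and no significant rank-2 vs rank-1
#'   attenuation difference;
#' * `"indeterminate"` — anything else.
#'
#' @param contrast A [contrast_tuning()] result.
#' @param alpha Significance level, default 0.05.
#' @return One of `"sharpening"`, `"fatiguing"`, `"indeterminate"`.
#' @export
classify_population_profile <- function(contrast, alpha = 0.05) {
  stopifnot(inherits(contrast, "tuning_contrast"))
  pr <- contrast$per_rank
  if (!all(c(1, 2) %in% pr$rank)) {
    stop("classification needs contrasts at ranks 1 and 2", call. = FALSE)
  }
  attenuated <- function(r) {
    i <- match(r, pr$rank)
    isTRUE(pr$p[i] < alpha) && isTRUE(pr$mean_primed[i] < pr$mean_control[i])
  }
  ap <- contrast$attenuation_pairs
  i12 <- which(ap$rank_a == 1 & ap$rank_b == 2)
  att_diff_sig <- isTRUE(ap$p[i12] < alpha) && isTRUE(ap$mean_diff[i12] > 0)
  if (!attenuated(1) && attenuated(2) && att_diff_sig) return("sharpening")
  if (attenuated(1) && !att_diff_sig) return("fatiguing")
  "indeterminate"
}

# --- burst detection -------------------------------------------------------

# Poisson surprise of a spike run: S = -log10 P(>= k spikes in T seconds |
# baseline rate), Legendy & Salcman style.
#' @noRd
poisson_surprise <- function(k, duration_ms, rate_hz) {
  -stats::ppois(k - 1, rate_hz * duration_ms / 1000, lower.tail = FALSE,
                log.p = TRUE) / log(10)
}

#' Detect the firing burst of each trial
#'
#' For units with a baseline rate above `rate_cutoff` (2 Hz), the spike run
#' in `[0, 2000)` ms maximizing the Poisson surprise
#' `S = -log10 P(>= k spikes in T | baseline rate)` is located by scanning
#' all candidate run endpoints (exact maximization; per-trial spike counts
#' are small) and accepted when `S >= surprise_threshold`. Onset and offset
#' are the first and last spike of the accepted run and duration their
#' difference. For low-baseline units the fallback is the timestamp of the
#' first spike in `[100, 1000)` ms (onset only, latency analyses only).
#'
#' @param unit A `unit_recording`.
#' @param trials Integer indices of the trials to analyze (default all).
#' @param surprise_threshold Acceptance threshold on S, default 2
#'   (P < 0.01 under the baseline Poisson process).
#' @param rate_cutoff Baseline rate (Hz) above which Poisson-surprise
#'   detection is used, default 2.
#' @param search_window Window scanned for bursts, default `c(0, 2000)`.
#' @param fallback_window First-spike window for low-baseline units.
#' @return A `burst_result` data frame: `trial`, `condition`, `onset`,
#'   `offset`, `duration` (ms; `NA` when no burst is accepted or no spike
#'   falls in the window), `surprise`, `method`.
#' @export
detect_burst <- function(unit, trials = NULL, surprise_threshold = 2,
                         rate_cutoff = 2, search_window = c(0, 2000),
                         fallback_window = c(100, 1000)) {
  stopifnot(inherits(unit, "unit_recording"))
  trials <- trials %||% seq_along(unit$spikes)
  base_rate <- mean(rate_in_window(unit$spikes, c(-500, 0)))
  use_burst <- base_rate > rate_cutoff
  rows <- lapply(trials, function(i) {
    t <- unit$spikes[[i]]
    t <- t[t >= search_window[1] & t < search_window[2]]
    if (use_burst) {
      b <- best_burst(t, base_rate)
      accepted <- !is.null(b) && b$surprise >= surprise_threshold
      data.frame(trial = i, condition = unit$trial_condition[i],
                 onset = if (accepted) b$onset else NA_real_,
                 offset = if (accepted) b$offset else NA_real_,
                 duration = if (accepted) b$offset - b$onset else NA_real_,
                 surprise = if (is.null(b)) NA_real_ else b$surprise,
                 method = "poisson_burst", stringsAsFactors = FALSE)
    } else {
      tf <- t[t >= fallback_window[1] & t < fallback_window[2]]
      data.frame(trial = i, condition = unit$trial_condition[i],
                 onset = if (length(tf)) tf[1] else NA_real_,
                 offset = NA_real_, duration = NA_real_,
                 surprise = NA_real_, method = "first_spike",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("burst_result", "data.frame")
  attr(out, "baseline_rate") <- base_rate
  out
}

# Maximum-surprise spike run (>= 2 spikes) of one trial.
#' @noRd
best_burst <- function(t, rate_hz) {
  n <- length(t)
  if (n < 2L) return(NULL)
  best <- NULL
  best_s <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    s <- poisson_surprise(j - i + 1L, t[j] - t[i], rate_hz)
    k <- which.max(s)
    if (s[k] > best_s) {
      best_s <- s[k]
      best <- list(onset = t[i], offset = t[j[k]], surprise = s[k])
    }
  }
  best
}

#' Contrast burst durations between conditions across units
#'
#' Per unit, the median burst duration is computed separately for primed
#' and control trials (Poisson-surprise method only; first-spike units
#' contribute latencies, not durations), then the per-unit medians are
#' contrasted with a two-tailed paired t-test and a signed-rank test.
#'
#' @param units List of `unit_recording` objects.
#' @param trials_list Optional list (same length as `units`) of integer
#'   trial indices restricting which trials enter burst detection (e.g.
#'   trials of each unit's response-eliciting stimuli); default all trials.
#' @param ... Passed to [detect_burst()].
#' @return List with `per_unit` (unit, primed/control median duration),
#'   `t`, `df`, `p_t`, `p_wilcox`, `n`.
#' @export
contrast_burst_duration <- function(units, trials_list = NULL, ...) {
  rows <- lapply(seq_along(units), function(u) {
    unit <- units[[u]]
    tr <- if (is.null(trials_list)) seq_along(unit$spikes) else
      trials_list[[u]]
    br <- detect_burst(unit, trials = tr, ...)
    if (!all(br$method == "poisson_burst")) return(NULL)
    p <- stats::median(br$duration[br$condition == "primed"], na.rm = TRUE)
    c <- stats::median(br$duration[br$condition == "control"], na.rm = TRUE)
    if (is.na(p) || is.na(c)) return(NULL)
    data.frame(unit = u, primed = p, control = c)
  })
  per_unit <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(per_unit) || nrow(per_unit) < 3L) {
    stop("need >= 3 units with accepted bursts in both conditions",
         call. = FALSE)
  }
  d <- per_unit$primed - per_unit$control
  tt <- stats::t.test(per_unit$primed, per_unit$control, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(per_unit$primed,
                                            per_unit$control,
                                            paired = TRUE, exact = FALSE))
  list(per_unit = per_unit, mean_diff = mean(d),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_t = tt$p.value, p_wilcox = wt$p.value, n = nrow(per_unit))
}

# --- pre-stimulus spreading-activation test --------------------------------

#' Pre-stimulus activity test (spreading-activation prediction)
#'
#' For each unit responding to at least one stimulus, the mean z-scored (or
#' raw) firing rate in the `[-500, 0)` ms window before primed
#' presentations of its response-eliciting stimuli is compared with that
#' before control presentations; unit means then enter a two-tailed paired
#' t-test. Under a spreading-activation account, residual network activity
#' should elevate the primed pre-stimulus rate.
#'
#' @param units List of `unit_recording` objects.
#' @param responsive_of List (same length) of character vectors: each
#'   unit's response-eliciting stimuli; units with none are excluded.
#' @param use_zscore Use z-scored baseline rates (default); `FALSE` gives
#'   the raw-rate variant.
#' @param baseline_window Window in ms, default `c(-500, 0)`.
#' @return List with `per_unit` data frame (`primed`, `control` mean
#'   pre-stimulus activity), `mean_primed`, `sd_primed`, `mean_control`,
#'   `sd_control`, `t`, `df`, `p`, `n`.
#' @export
prestimulus_test <- function(units, responsive_of, use_zscore = TRUE,
                             baseline_window = c(-500, 0)) {
  stopifnot(length(units) == length(responsive_of))
  rows <- lapply(seq_along(units), function(u) {
    unit <- units[[u]]
    resp <- responsive_of[[u]]
    if (!length(resp)) return(NULL)
    base <- rate_in_window(unit$spikes, baseline_window)
    if (use_zscore) {
      bs <- stats::sd(base)
      if (bs == 0) return(NULL)
      base <- (base - mean(base)) / bs
    }
    i <- unit$trial_stimulus %in% resp
    p <- base[i & unit$trial_condition == "primed"]
    c <- base[i & unit$trial_condition == "control"]
    if (!length(p) || !length(c)) return(NULL)
    data.frame(unit = u, primed = mean(p), control = mean(c))
  })
  per_unit <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(per_unit) || nrow(per_unit) < 2L) {
    stop("need >= 2 units with a response-eliciting stimulus",
         call. = FALSE)
  }
  tt <- stats::t.test(per_unit$primed, per_unit$control, paired = TRUE)
  list(per_unit = per_unit,
       mean_primed = mean(per_unit$primed),
       sd_primed = stats::sd(per_unit$primed),
       mean_control = mean(per_unit$control),
       sd_control = stats::sd(per_unit$control),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = nrow(per_unit))
}
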