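#' Ground-truth mechanism specification for a simulated unit
#'
#' Describes how a unit's semantic tuning curve is modulated on primed
#' trials. The unit fires as an inhomogeneous Poisson process: at
#' `baseline_rate` Hz outside the response window and at
#' `baseline_rate * gain(stimulus)` within `[onset_latency, onset_latency +
#' response_duration)` ms. Gains attach to a small set of tuned stimuli
#' (rank 1 = strongest); all other stimuli have gain 1.
#'
#' Condition modulation on primed trials:
#' * `"fatiguing"` — all tuned gains are multiplied by `1 - attenuation`
#'   (proportional attenuation, tuning shape preserved);
#' * `"sharpening"` — the rank-1 gain is preserved, gains at ranks >= 2 are
#'   multiplied by `1 - attenuation` (disproportional attenuation of
#'   non-optimal stimuli);
#' * `"facilitation"` — the response duration is multiplied by
#'   `1 - attenuation`, gains unchanged (shorter bouts of firing);
#' * `"none"` — no condition effect.
#'
#' @param mechanism One of `"none"`, `"sharpening"`, `"fatiguing"`,
#'   `"facilitation"`.
#' @param baseline_rate Baseline firing rate in Hz (>= 0).
#' @param tuning_gains Non-increasing multiplicative gains per stimulus
#'   rank; the default graded decay `c(8, 6, 4, 3, 1)` yields a tuning
#'   curve with four response-eliciting stimuli strong enough for the
#'   binwise detection criterion to find them, emulating the selected
#'   multi-responsive subpopulation the rank analyses operate on.
#' @param attenuation Fraction in `[0, 1]` removed by the mechanism.
#' @param onset_latency Response onset in ms after stimulus onset.
#' @param response_duration Response window length in ms.
#' @return A list of class `mechanism_spec`.
#' @export
mechanism_spec <- function(mechanism = c("none", "sharpening", "fatiguing",
                                         "facilitation"),
                           baseline_rate = 5, tuning_gains = c(8, 6, 4, 3, 1),
                           attenuation = 0.3, onset_latency = 300,
                           response_duration = 600) {
  if (is.character(mechanism) && length(mechanism) == 1L &&
      !mechanism %in% c("none", "sharpening", "fatiguing", "facilitation")) {
    stop("unknown mechanism label: ", mechanism, call. = FALSE)
  }
  mechanism <- match.arg(mechanism)
  if (baseline_rate < 0) stop("`baseline_rate` must be >= 0", call. = FALSE)
  if (any(diff(tuning_gains) > 0)) {
    stop("`tuning_gains` must be non-increasing over ranks", call. = FALSE)
  }
  if (attenuation < 0 || attenuation > 1) {
    stop("`attenuation` must be in [0, 1]", call. = FALSE)
  }
  if (onset_latency < 0 || response_duration <= 0) {
    stop("`onset_latency` must be >= 0 and `response_duration` > 0",
         call. = FALSE)
  }
  structure(list(mechanism = mechanism, baseline_rate = baseline_rate,
                 tuning_gains = tuning_gains, attenuation = attenuation,
                 onset_latency = onset_latency,
                 response_duration = response_duration),
            class = "mechanism_spec")
}

#' Simulate one unit's spike trains for a session
#'
#' Draws, for every target trial of the table, spike timestamps (continuous
#' ms relative to stimulus onset, half-open windows) from the
#' inhomogeneous-Poisson model described in [mechanism_spec()]. The tuned
#' stimuli default to exemplars of a single semantic category, so primed and
#' control presentations of a response-eliciting stimulus differ only by the
#' category of their prime.
#'
#' @param tt Trial table; spikes are generated for every row with
#'   `condition != "discarded_first"`, in table order.
#' @param mech A [mechanism_spec()].
#' @param stim_set The stimulus set (used to pick tuned stimuli within one
#'   category when `tuned_stimuli` is not given).
#' @param seed Optional integer seed.
#' @param region Anatomical label (`"AM"`, `"HC"`, `"EC"`, `"PHC"`).
#' @param unit_class `"SU"` (single unit) or `"MU"` (multi unit).
#' @param tuned_stimuli Optional character vector of stimulus ids receiving
#'   `mech$tuning_gains` in rank order; drawn at random when `NULL`.
#' @param window Simulated coverage in ms, default `c(-1000, 2000)`.
#' @return A `unit_recording`: list with `spikes` (list of sorted numeric
#'   vectors, one per target trial), `trial_stimulus`, `trial_condition`,
#'   `region`, `unit_class`, `window`, and a `ground_truth` list
#'   (mechanism spec, tuned stimuli).
#' @export
simulate_unit <- function(tt, mech = mechanism_spec(), stim_set = NULL,
                          seed = NULL, region = "AM", unit_class = "SU",
                          tuned_stimuli = NULL, window = c(-1000, 2000)) {
  if (!inherits(mech, "mechanism_spec")) {
    stop("`mech` must be a mechanism_spec() object", call. = FALSE)
  }
  check_window(window)
  tg <- tt[tt$condition != "discarded_first", , drop = FALSE]
  n <- nrow(tg)
  with_seed(seed, {
    if (is.null(tuned_stimuli)) {
      k <- length(mech$tuning_gains)
      if (!is.null(stim_set)) {
        cat_pick <- sample(seq_len(stim_set$n_categories), 1L)
        pool <- stim_set$stimuli[stim_set$category_of == cat_pick]
        if (length(pool) < k) pool <- stim_set$stimuli
      } else {
        pool <- unique(tg$stimulus)
      }
      tuned_stimuli <- sample(pool, min(length(pool), k))
    }
    gains <- rep(1, n)
    ranks <- match(tg$stimulus, tuned_stimuli)
    has_rank <- !is.na(ranks)
    gains[has_rank] <- mech$tuning_gains[ranks[has_rank]]
    dur <- rep(mech$response_duration, n)
    primed <- tg$condition == "primed"
    att <- 1 - mech$attenuation
    if (mech$mechanism == "fatiguing") {
      gains[primed & has_rank] <- gains[primed & has_rank] * att
    } else if (mech$mechanism == "sharpening") {
      mod <- primed & has_rank & ranks >= 2
      gains[mod] <- gains[mod] * att
    } else if (mech$mechanism == "facilitation") {
      dur[primed] <- dur[primed] * att
    }
    on <- mech$onset_latency
    spikes <- draw_piecewise_poisson(
      n, mech$baseline_rate, gains, window, on, on + dur)
    structure(
      list(spikes = spikes,
           trial_stimulus = tg$stimulus,
           trial_condition = as.character(tg$condition),
           region = region, unit_class = unit_class, window = window,
           baseline_rate = mech$baseline_rate,
           ground_truth = list(mechanism = mech$mechanism, spec = mech,
                               tuned_stimuli = tuned_stimuli)),
      class = "unit_recording")
  })
}

# Piecewise-constant Poisson sampler: rate `base` on [w0, on) and
# [off_i, w1), rate `base * gain_i` on [on, off_i). Vectorized over trials.
#' @noRd
draw_piecewise_poisson <- function(n, base, gains, window, on, off) {
  on <- rep(on, length.out = n)
  off <- pmin(rep(off, length.out = n), window[2])
  seg_starts <- rbind(window[1], pmax(on, window[1]), off)
  seg_ends <- rbind(pmax(on, window[1]), off, window[2])
  seg_rates <- rbind(base, base * gains, base)
  lens <- pmax(seg_ends - seg_starts, 0) / 1000
  counts <- matrix(stats::rpois(3L * n, as.vector(seg_rates * lens)), 3L, n)
  total <- colSums(counts)
  u <- stats::runif(sum(total))
  seg_of <- rep(rep(1:3, n), as.vector(counts))
  trial_of <- rep(rep(seq_len(n), each = 3L), as.vector(counts))
  t_all <- seg_starts[cbind(seg_of, trial_of)] +
    u * (seg_ends[cbind(seg_of, trial_of)] - seg_starts[cbind(seg_of, trial_of)])
  out <- vector("list", n)
  split_t <- split(t_all, factor(trial_of, levels = seq_len(n)))
  for (i in seq_len(n)) out[[i]] <- sort(split_t[[i]])
  out
}

#' @export
print.unit_recording <- function(x, ...) {
  cat(sprintf(
    "<unit_recording> %s %s: %d trials, baseline %.3g Hz, mechanism '%s'\n",
    x$region, x$unit_class, length(x$spikes), x$baseline_rate,
    x$ground_truth$mechanism))
  invisible(x)
}

#' Simulate a cohort of units
#'
#' Independently simulates `n_units` units for each cohort entry, attaching
#' region labels and keeping ground truth for recovery tests. Entry fields:
#' `region`, `n_units`, and `mech` (a [mechanism_spec()]).
#'
#' @param tt Trial table.
#' @param cohort List of entries, e.g.
#'   `list(list(region = "AM", n_units = 88, mech = mechanism_spec("sharpening")))`.
#' @param stim_set Stimulus set passed to [simulate_unit()].
#' @param seed Optional integer seed.
#' @return List of `unit_recording` objects.
#' @export
simulate_population <- function(tt, cohort, stim_set = NULL, seed = NULL) {
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  for (entry in cohort) {
    if (is.null(entry$n_units) || entry$n_units < 1) {
      stop("each cohort entry needs `n_units` >= 1", call. = FALSE)
    }
    if (!inherits(entry$mech, "mechanism_spec")) {
      stop("each cohort entry needs a mechanism_spec() `mech`", call. = FALSE)
    }
  }
  with_seed(seed, {
    units <- list()
    for (entry in cohort) {
      for (i in seq_len(entry$n_units)) {
        units[[length(units) + 1L]] <- simulate_unit(
          tt, entry$mech, stim_set = stim_set, region = entry$region,
          unit_class = entry$unit_class %||% "SU")
      }
    }
    units
  })
}
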