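#' Reaction-time model parameters for the behavior simulator
#'
#' The simulator draws reaction times from a shifted lognormal,
#' `RT = shift + Lognormal(meanlog, sdlog)`, which gives realistic right
#' skew; the priming effect is additive on the median, i.e. the primed
#' median is `shift + exp(meanlog) - effect`. Defaults reproduce the study
#' conditions in the statistic the analyses report (the per-session *mean*
#' RT, which for this skewed law sits about 20 ms above the distribution
#' median after outlier trimming): control session means near 713 ms, a
#' 109 ms primed advantage, and error rates of 0.6% (primed) and 2%
#' (control).
#'
#' @param shift Lower bound of the RT distribution (ms).
#' @param meanlog,sdlog Lognormal parameters of the control condition.
#' @param effect Median primed advantage in ms (0 = null generator).
#' @param outlier_rate Probability that a trial's RT is replaced by a planted
#'   extreme value (lapses and anticipations), flagged in ground truth.
#' @param error_rate_primed,error_rate_control Per-condition probability of
#'   an incorrect manmade/natural response.
#' @return A list of class `rt_params`.
#' @export
rt_params <- function(shift = 193, meanlog = log(500), sdlog = 0.35,
                      effect = 109, outlier_rate = 0.02,
                      error_rate_primed = 0.006, error_rate_control = 0.02) {
  if (sdlog <= 0) stop("`sdlog` must be positive", call. = FALSE)
  if (shift < 0) stop("`shift` must be non-negative", call. = FALSE)
  if (effect >= exp(meanlog)) {
    stop("`effect` must be smaller than the control median exp(meanlog)",
         call. = FALSE)
  }
  if (outlier_rate < 0 || outlier_rate >= 1) {
    stop("`outlier_rate` must be in [0, 1)", call. = FALSE)
  }
  for (er in c(error_rate_primed, error_rate_control)) {
    if (er < 0 || er >= 1) stop("error rates must be in [0, 1)", call. = FALSE)
  }
  structure(list(shift = shift, meanlog = meanlog, sdlog = sdlog,
                 effect = effect, outlier_rate = outlier_rate,
                 error_rate_primed = error_rate_primed,
                 error_rate_control = error_rate_control),
            class = "rt_params")
}

#' Simulate reaction times and response correctness for a session
#'
#' Fills the `rt` and `correct` columns of a trial table. Primed targets are
#' faster by `params$effect` ms at the median; a configurable fraction of
#' trials is replaced by planted extreme RTs (slow lapses or fast
#' anticipations) and flagged in a ground-truth column so outlier-exclusion
#' rules can be evaluated against known plants. Leading discarded
#' presentations receive control-law RTs (they are real button presses) but
#' are never analyzed.
#'
#' @param tt A `trial_table` from [generate_trial_sequence()].
#' @param params An [rt_params()] object.
#' @param seed Optional integer seed.
#' @return The trial table with `rt`, `correct`, and logical
#'   `planted_outlier` columns filled.
#' @export
simulate_behavior <- function(tt, params = rt_params(), seed = NULL) {
  stopifnot(inherits(tt, "trial_table") || is.data.frame(tt))
  if (!inherits(params, "rt_params")) {
    stop("`params` must be an rt_params() object", call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(tt)
    primed <- tt$condition == "primed"
    meanlog <- ifelse(primed, log(exp(params$meanlog) - params$effect),
                      params$meanlog)
    rt <- params$shift + stats::rlnorm(n, meanlog, params$sdlog)
    # plants sit near +-3 SD of the generating law: far enough out to be
    # true outliers, mild enough not to inflate the session SD so much
    # that the 2.5 SD rule loses both tails
    planted <- stats::runif(n) < params$outlier_rate
    if (any(planted)) {
      slow <- planted & stats::runif(n) < 0.5
      fast <- planted & !slow
      rt[slow] <- stats::runif(sum(slow), 2000, 3000)
      rt[fast] <- stats::runif(sum(fast), 20, 80)
    }
    err_rate <- ifelse(primed, params$error_rate_primed,
                       params$error_rate_control)
    correct <- stats::runif(n) >= err_rate
    tt$rt <- rt
    tt$correct <- correct
    tt$planted_outlier <- planted
    tt
  })
}
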