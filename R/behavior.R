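#' Flag reaction-time outliers of a session
#'
#' A trial is excluded iff its RT lies below `M - 2.5 * SD` or above
#' `M + 2.5 * SD`, where `M` and `SD` are the mean and standard deviation of
#' all of the session's RTs, pooled over conditions (one `M`, `SD` per
#' session). The input is left untouched; only a mask is returned.
#'
#' @param tt A session trial table with an `rt` column.
#' @param k Number of SDs, default 2.5.
#' @return Logical vector, `TRUE` for excluded trials (`NA` RTs are `FALSE`:
#'   they carry no RT to exclude).
#' @examples
#' # hand-computable case: the 5000 ms trial exceeds M + 2.5 SD
#' tt <- data.frame(rt = c(500, 510, 520, 490, 5000))
#' exclude_rt_outliers(tt)
#' @export
exclude_rt_outliers <- function(tt, k = 2.5) {
  rt <- tt$rt
  obs <- !is.na(rt)
  if (sum(obs) < 2L) {
    stop("session has fewer than 2 trials with RT; SD is undefined",
         call. = FALSE)
  }
  m <- mean(rt[obs])
  s <- stats::sd(rt[obs])
  out <- obs & (rt < m - k * s | rt > m + k * s)
  out[is.na(out)] <- FALSE
  out
}

# Per-session condition means after exclusions. Returns c(primed, control)
# or NULL (with a warning) when a condition is empty.
#' @noRd
session_rt_means <- function(tt, stim_set, exclude_response_priming,
                             exclude_errors, session_label = "?") {
  mask <- exclude_rt_outliers(tt)
  keep <- !mask & tt$condition %in% c("primed", "control") & !is.na(tt$rt)
  if (exclude_errors) keep <- keep & tt$correct %in% TRUE
  if (exclude_response_priming) {
    # drop control trials whose prime is of the other meta-category (these
    # are the trials where prime and target demand different responses)
    prime_meta <- meta_of_stimulus(stim_set, tt$prime)
    drop <- tt$condition == "control" & !is.na(prime_meta) &
      prime_meta != tt$meta
    keep <- keep & !drop
  }
  p <- tt$rt[keep & tt$condition == "primed"]
  c <- tt$rt[keep & tt$condition == "control"]
  if (!length(p) || !length(c)) {
    warning("session ", session_label,
            " lacks trials in a condition after exclusions; dropped",
            call. = FALSE)
    return(NULL)
  }
  c(primed = mean(p), control = mean(c))
}

#' @noRd
session_accuracy <- function(tt, stim_set, exclude_response_priming,
                             session_label = "?") {
  keep <- tt$condition %in% c("primed", "control") & !is.na(tt$correct)
  if (exclude_response_priming) {
    prime_meta <- meta_of_stimulus(stim_set, tt$prime)
    drop <- tt$condition == "control" & !is.na(prime_meta) &
      prime_meta != tt$meta
    keep <- keep & !drop
  }
  p <- tt$correct[keep & tt$condition == "primed"]
  c <- tt$correct[keep & tt$condition == "control"]
  if (!length(p) || !length(c)) {
    warning("session ", session_label,
            " lacks trials in a condition; dropped", call. = FALSE)
    return(NULL)
  }
  c(primed = 100 * mean(p), control = 100 * mean(c))
}

# Shared contrast machinery: paired two-tailed Wilcoxon signed-rank across
# session summaries, with group median/IQR per condition.
#' @noRd
paired_signed_rank_contrast <- function(per_session, measure,
                                        exclude_response_priming,
                                        participant = NULL) {
  if (!is.null(participant)) {
    stopifnot(length(participant) == nrow(per_session))
    per_session <- stats::aggregate(
      per_session[c("primed", "control")],
      by = list(participant = participant), FUN = mean)
  }
  n <- nrow(per_session)
  d <- per_session$primed - per_session$control
  if (all(d == 0)) {
    stat <- 0; p <- 1  # no information against the null
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(per_session$primed, per_session$control,
                         paired = TRUE, exact = FALSE))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(
    list(per_session = per_session,
         md_primed = stats::median(per_session$primed),
         iqr_primed = stats::IQR(per_session$primed),
         md_control = stats::median(per_session$control),
         iqr_control = stats::IQR(per_session$control),
         statistic = stat, p_value = p, n = n, measure = measure,
         exclude_response_priming = exclude_response_priming),
    class = "behavioral_contrast")
}

#' Primed-vs-control reaction-time contrast across sessions
#'
#' Per session: RT outliers are excluded ([exclude_rt_outliers()]), error
#' trials optionally dropped, and mean RT computed per condition. With
#' `exclude_response_priming = TRUE`, control trials whose prime belongs to
#' the other manmade/natural meta-category (so prime and target require
#' different button presses) are removed first, isolating semantic from
#' response priming. Session pairs then enter a two-tailed Wilcoxon
#' signed-rank test.
#'
#' @param sessions List of session trial tables (with `rt`, `correct`).
#' @param stim_set The stimulus set (needed for meta-category lookups).
#' @param exclude_response_priming Logical, see above.
#' @param exclude_errors Drop incorrect trials from RT averaging
#'   (default `TRUE`).
#' @param participant Optional vector (one entry per session); when given,
#'   session summaries are averaged per participant before the test.
#' @return A `behavioral_contrast` object: per-session means, group
#'   median/IQR per condition, signed-rank statistic, p-value, n.
#' @export
contrast_rt <- function(sessions, stim_set, exclude_response_priming = FALSE,
                        exclude_errors = TRUE, participant = NULL) {
  stopifnot(is.list(sessions))
  if (length(sessions) < 6L) {
    stop("need >= 6 sessions for a meaningful signed-rank contrast",
         call. = FALSE)
  }
  labels <- names(sessions) %||% as.character(seq_along(sessions))
  rows <- lapply(seq_along(sessions), function(i) {
    session_rt_means(sessions[[i]], stim_set, exclude_response_priming,
                     exclude_errors, labels[i])
  })
  keep <- !vapply(rows, is.null, logical(1))
  per_session <- as.data.frame(do.call(rbind, rows[keep]))
  per_session$session <- labels[keep]
  paired_signed_rank_contrast(per_session, "rt", exclude_response_priming,
                              participant[keep])
}

#' Primed-vs-control response-accuracy contrast across sessions
#'
#' As [contrast_rt()] but on per-session percent correct; no RT outlier
#' exclusion is applied to accuracy.
#'
#' @inheritParams contrast_rt
#' @return A `behavioral_contrast` object (`measure = "accuracy"`, values
#'   in percent).
#' @export
contrast_accuracy <- function(sessions, stim_set,
                              exclude_response_priming = FALSE,
                              participant = NULL) {
  stopifnot(is.list(sessions))
  if (length(sessions) < 6L) {
    stop("need >= 6 sessions for a meaningful signed-rank contrast",
         call. = FALSE)
  }
  labels <- names(sessions) %||% as.character(seq_along(sessions))
  rows <- lapply(seq_along(sessions), function(i) {
    session_accuracy(sessions[[i]], stim_set, exclude_response_priming,
                     labels[i])
  })
  keep <- !vapply(rows, is.null, logical(1))
  per_session <- as.data.frame(do.call(rbind, rows[keep]))
  per_session$session <- labels[keep]
  paired_signed_rank_contrast(per_session, "accuracy",
                              exclude_response_priming, participant[keep])
}

#' @export
print.behavioral_contrast <- function(x, ...) {
  unit <- if (x$measure == "rt") "ms" else "%"
  cat(sprintf(
    "<behavioral_contrast> %s, %d sessions%s\n", x$measure, x$n,
    if (x$exclude_response_priming) " (response priming excluded)" else ""))
  cat(sprintf("  primed : Md %.1f %s [IQR %.1f]\n", x$md_primed, unit,
              x$iqr_primed))
  cat(sprintf("  control: Md %.1f %s [IQR %.1f]\n", x$md_control, unit,
              x$iqr_control))
  cat(sprintf("  Wilcoxon signed-rank: V = %g, p = %.3g\n", x$statistic,
              x$p_value))
  invisible(x)
}
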