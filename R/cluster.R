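# Sample-wise paired t statistics and cluster-based permutation inference
# for paired ERP condition differences (time-only clusters, one channel or
# region at a time).

#' Sample-wise paired t-test between two sets of paired traces
#'
#' Computes the two-tailed paired t statistic and p-value at every sample
#' point between condition A and condition B traces of the same sessions.
#'
#' @param pairs_a,pairs_b Numeric matrices, sessions x samples, row i of
#'   `pairs_a` paired with row i of `pairs_b`.
#' @return List with `t` (statistic per sample), `p` (two-tailed p per
#'   sample), `df`, and `n` (number of pairs). Samples with zero variance of
#'   the paired differences get `t = 0`, `p = 1` with a warning.
#' @export
samplewise_t <- function(pairs_a, pairs_b) {
  stopifnot(is.matrix(pairs_a), is.matrix(pairs_b),
            all(dim(pairs_a) == dim(pairs_b)))
  n <- nrow(pairs_a)
  if (n < 3L) {
    stop("need >= 3 pairs for a sample-wise paired t-test", call. = FALSE)
  }
  d <- pairs_a - pairs_b
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0  # numerical guard
  se <- sqrt(v / n)
  t <- m / se
  zero <- !is.finite(t)
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero variance of differences; ",
            "p set to 1 there", call. = FALSE)
    t[zero] <- 0
  }
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  p[zero] <- 1
  list(t = t, p = p, df = n - 1, n = n)
}

#' Find supra-threshold clusters in a test-statistic trace
#'
#' Clusters are maximal runs of consecutive samples with `p < cluster_alpha`
#' and a common sign of `t`; runs containing a sign change are split at the
#' change (a summed t-value of mixed sign would be uninterpretable). Each
#' cluster carries its size and the sum of its member t-values.
#'
#' @param t,p Numeric vectors of equal length (from [samplewise_t()]).
#' @param cluster_alpha Sample-wise threshold, default 0.001.
#' @return Data frame with `start`, `end` (sample indices, inclusive),
#'   `size`, `sum_t`, `sign` (+1/-1); zero rows when no sample is
#'   supra-threshold.
#' @export
find_clusters <- function(t, p, cluster_alpha = 0.001) {
  stopifnot(length(t) == length(p))
  if (cluster_alpha <= 0 || cluster_alpha > 1) {
    stop("`cluster_alpha` must be in (0, 1]", call. = FALSE)
  }
  supra <- which(p < cluster_alpha & t != 0)
  if (!length(supra)) {
    return(data.frame(start = integer(0), end = integer(0),
                      size = integer(0), sum_t = numeric(0),
                      sign = integer(0)))
  }
  sgn <- sign(t[supra])
  new_cluster <- c(TRUE, diff(supra) > 1L | diff(sgn) != 0)
  id <- cumsum(new_cluster)
  data.frame(
    start = as.integer(tapply(supra, id, min)),
    end = as.integer(tapply(supra, id, max)),
    size = as.integer(tapply(supra, id, length)),
    sum_t = as.numeric(tapply(t[supra], id, sum)),
    sign = as.integer(tapply(sgn, id, `[`, 1L)),
    row.names = NULL)
}

# Extreme cluster sums of one t trace: c(max positive run sum, min negative
# run sum), 0 for an absent tail. Threshold on |t| > tcrit (equivalent to
# p < alpha two-tailed).
#' @noRd
extreme_cluster_sums <- function(t, tcrit) {
  out <- c(0, 0)
  pos <- t > tcrit
  if (any(pos)) {
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    out[1] <- max(vapply(w, function(j) sum(t[starts[j]:ends[j]]),
                         numeric(1)))
  }
  neg <- t < -tcrit
  if (any(neg)) {
    r <- rle(neg)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    out[2] <- min(vapply(w, function(j) sum(t[starts[j]:ends[j]]),
                         numeric(1)))
  }
  out
}

# All 2^n sign assignments as a matrix (rows = assignments).
#' @noRd
all_sign_flips <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  m
}

#' Cluster-based permutation test for paired ERP differences
#'
#' Label-shuffling inference for the paired design: per permutation, the
#' condition labels of each pair are swapped independently (equivalently,
#' the sign of each pair's difference trace is flipped), the sample-wise
#' paired t trace is recomputed, and the maximum positive and minimum
#' negative cluster sums are recorded (0 when no cluster forms). An observed
#' positive cluster is significant iff its summed t exceeds the 99th
#' percentile of the positive-tail null; a negative cluster iff it falls
#' below the 1st percentile of the negative-tail null. A Monte-Carlo
#' p-value, `(1 + #{null at least as extreme}) / (1 + n_perm)`, is reported
#' alongside the percentile decision.
#'
#' When `n_perm` exceeds the number of distinct sign assignments (`2^n`),
#' the null is computed by exhaustive enumeration instead, with a warning.
#'
#' @inheritParams samplewise_t
#' @param cluster_alpha Sample-wise clustering threshold, default 0.001.
#' @param n_perm Number of label permutations, default 1000 (>= 100).
#' @param seed Optional integer seed for the permutation draws.
#' @param times Optional vector of sample times (ms) used to annotate
#'   cluster extents.
#' @param percentiles Null percentiles for the negative/positive tails.
#' @return A `cluster_result` data frame: one row per observed cluster with
#'   `start`, `end`, `start_ms`, `end_ms` (half-open), `size`, `sum_t`,
#'   `sign`, `p_mc`, `significant`. Attributes `null_pos`, `null_neg`
#'   (per-permutation extremes), `crit` (the two percentile cutoffs),
#'   `n_perm`, `exact`.
#' @export
cluster_permutation_test <- function(pairs_a, pairs_b, cluster_alpha = 0.001,
                                     n_perm = 1000, seed = NULL,
                                     times = NULL,
                                     percentiles = c(0.01, 0.99)) {
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  obs <- samplewise_t(pairs_a, pairs_b)
  clusters <- find_clusters(obs$t, obs$p, cluster_alpha)
  n <- obs$n
  d <- pairs_a - pairs_b
  css <- colSums(d^2)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  exact <- n_perm > 2^n
  with_seed(seed, {
    signs <- if (exact) {
      warning("n_perm = ", n_perm, " exceeds the ", 2^n,
              " distinct sign assignments; using exact enumeration",
              call. = FALSE)
      all_sign_flips(n)
    } else {
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
    }
    m_perm <- (signs %*% d) / n
    n_eff <- nrow(signs)
    v <- sweep(-n * m_perm^2, 2L, css, `+`) / (n - 1)
    v[v < 0] <- 0
    t_perm <- m_perm / sqrt(v / n)
    t_perm[!is.finite(t_perm)] <- 0
    extremes <- t(apply(t_perm, 1L, extreme_cluster_sums, tcrit = tcrit))
    null_pos <- extremes[, 1]
    null_neg <- extremes[, 2]
    crit <- c(neg = unname(stats::quantile(null_neg, percentiles[1])),
              pos = unname(stats::quantile(null_pos, percentiles[2])))
    if (nrow(clusters)) {
      clusters$p_mc <- NA_real_
      clusters$significant <- NA
      for (i in seq_len(nrow(clusters))) {
        s <- clusters$sum_t[i]
        if (clusters$sign[i] > 0) {
          clusters$p_mc[i] <- if (exact) mean(null_pos >= s) else
            (1 + sum(null_pos >= s)) / (1 + n_eff)
          clusters$significant[i] <- s > crit["pos"]
        } else {
          clusters$p_mc[i] <- if (exact) mean(null_neg <= s) else
            (1 + sum(null_neg <= s)) / (1 + n_eff)
          clusters$significant[i] <- s < crit["neg"]
        }
      }
    } else {
      clusters$p_mc <- numeric(0)
      clusters$significant <- logical(0)
    }
    if (!is.null(times)) {
      step <- if (length(times) > 1) times[2] - times[1] else NA_real_
      clusters$start_ms <- if (nrow(clusters)) times[clusters$start] else
        numeric(0)
      clusters$end_ms <- if (nrow(clusters)) times[clusters$end] + step else
        numeric(0)
    }
    structure(clusters, class = c("cluster_result", "data.frame"),
              null_pos = null_pos, null_neg = null_neg, crit = crit,
              n_perm = n_eff, exact = exact, cluster_alpha = cluster_alpha)
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s); %s null with %d permutation(s)\n",
    nrow(x), if (isTRUE(attr(x, "exact"))) "exact sign-flip" else "sampled",
    attr(x, "n_perm")))
  if (nrow(x)) print.data.frame(as.data.frame(x))
  invisible(x)
}
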