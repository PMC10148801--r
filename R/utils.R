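# Internal helpers shared across modules. All time windows are half-open
# [start, end) in milliseconds relative to stimulus onset.

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage seed from a global seed; keeps results < 2^31 and distinct
# per stage label.
#' @noRd
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.double(seed) * 7919 + h * 104729) %% 2147483629
}

# Number of events in [start, end) per trial; x is a list of sorted numeric
# vectors (ms). Returns counts.
#' @noRd
count_in_window <- function(x, window) {
  vapply(x, function(t) sum(t >= window[1] & t < window[2]), integer(1))
}

# Firing rate in Hz over a half-open window (ms).
#' @noRd
rate_in_window <- function(x, window) {
  count_in_window(x, window) / ((window[2] - window[1]) / 1000)
}

#' @noRd
check_window <- function(window, name = "window") {
  if (!is.numeric(window) || length(window) != 2L || window[1] >= window[2]) {
    stop(sprintf("`%s` must be c(start, end) with start < end", name),
         call. = FALSE)
  }
  invisible(window)
}

# Sample index range (1-based, half-open [i, j)) covered by a time window in
# a segment sampled at `fs` Hz whose first sample sits at `t0` ms.
#' @noRd
window_to_samples <- function(window, fs, t0) {
  step <- 1000 / fs
  i <- ceiling((window[1] - t0) / step - 1e-9) + 1L
  j <- ceiling((window[2] - t0) / step - 1e-9) + 1L
  c(max(1L, as.integer(i)), as.integer(j))
}

# Times (ms) of samples 1..n for a segment starting at t0 ms.
#' @noRd
sample_times <- function(n, fs, t0) {
  t0 + (seq_len(n) - 1L) * 1000 / fs
}

# 1/f ("pink") noise, unit variance, length n. Spectral synthesis: white
# Gaussian spectrum shaped by 1/sqrt(f).
#' @noRd
pink_noise <- function(n) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp * stats::rnorm(nf, 1, 0.2), argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) {
    full[seq(n, n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
    full[nf + 1L] <- complex(real = Re(spec[nf]))
  } else {
    full[seq(n, n - nf + 1L)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
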