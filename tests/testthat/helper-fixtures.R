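# Shared fixtures, built in code. Small stimulus sets and hand-made trial
# frames keep the unit tests fast; acceptance-scale cohorts are generated
# inside test-acceptance.R.

small_set <- function(seed = 1) generate_stimulus_set(4, 3, seed = seed)

full_set <- function(seed = 1) generate_stimulus_set(10, 10, seed = seed)

# Minimal trial frame for the spike/iEEG simulators: one row per target
# presentation of the given stimuli/conditions.
toy_trials <- function(stimulus, condition) {
  structure(
    data.frame(run = 1L, position = seq_along(stimulus), stimulus = stimulus,
               category = 1L, meta = "manmade",
               condition = factor(condition,
                                  levels = c("primed", "control",
                                             "discarded_first")),
               prime = NA_character_, rt = NA_real_, correct = NA,
               stringsAsFactors = FALSE),
    class = c("trial_table", "data.frame"))
}

# n presentations per condition of each stimulus, interleaved.
repeat_trials <- function(stimuli, n_per_cond) {
  stim <- rep(stimuli, each = 2L * n_per_cond)
  cond <- rep(rep(c("primed", "control"), each = n_per_cond),
              times = length(stimuli))
  toy_trials(stim, cond)
}

# One cached standard session (sequence + behavior), reused across files.
cached_session <- local({
  env <- new.env()
  function() {
    if (is.null(env$session)) {
      ss <- full_set(seed = 42)
      tt <- generate_trial_sequence(ss, 10, seed = 42)
      env$session <- list(stim_set = ss,
                          trials = simulate_behavior(tt, seed = 42))
    }
    env$session
  }
})

# Segments object straight from a matrix (window/rate defaults align with
# the analysis conventions).
segments_from_matrix <- function(data, fs = 256, window = c(-1000, 2000),
                                 condition = rep("control", nrow(data))) {
  mtladapt:::new_ieeg_segments(data, fs, window, condition)
}

# Empirical firing rates (Hz) of a unit's trials over a half-open window.
rate_in_window_test <- function(u, w) {
  vapply(u$spikes, function(t) sum(t >= w[1] & t < w[2]), numeric(1)) /
    ((w[2] - w[1]) / 1000)
}

rate_in_window_test_sub <- function(u, i, w) {
  rate_in_window_test(list(spikes = u$spikes[i]), w)
}

counts_in <- function(u, i, w) {
  vapply(u$spikes[i], function(t) sum(t >= w[1] & t < w[2]), numeric(1))
}

# Brute-force cluster enumeration used as oracle for find_clusters: walk
# the samples and accumulate runs by hand.
brute_force_clusters <- function(t, p, alpha) {
  out <- NULL
  i <- 1L
  n <- length(t)
  while (i <= n) {
    if (p[i] < alpha && t[i] != 0) {
      s <- sign(t[i])
      j <- i
      while (j + 1L <= n && p[j + 1L] < alpha && t[j + 1L] != 0 &&
             sign(t[j + 1L]) == s) {
        j <- j + 1L
      }
      out <- rbind(out, data.frame(start = i, end = j, size = j - i + 1L,
                                   sum_t = sum(t[i:j]), sign = s))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) {
    data.frame(start = integer(0), end = integer(0), size = integer(0),
               sum_t = numeric(0), sign = integer(0))
  } else {
    out$start <- as.integer(out$start)
    out$end <- as.integer(out$end)
    out$sign <- as.integer(out$sign)
    out
  }
}
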