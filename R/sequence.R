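#' Generate a pseudorandom primed/control trial sequence
#'
#' Arranges each of `n_runs` runs so that every stimulus appears exactly once
#' as target per run, preceded ("primed") by another exemplar of the same
#' semantic category in exactly half of its presentations across the session
#' and by a different-category exemplar ("control") in the other half. Each
#' run opens with one extra presentation that only serves as prime for the
#' first target and is discarded from analyses.
#'
#' Generation is constructive with constrained randomization: a session plan
#' first fixes, per stimulus, in which runs it is primed; within a run,
#' same-category "blocks" (a control-labelled exemplar followed by that run's
#' primed exemplars of the category) are arranged so that no two blocks of
#' the same category are adjacent. If a valid plan or arrangement is not
#' found within `max_attempts` restarts, generation fails with an error
#' rather than silently relaxing a constraint.
#'
#' @param stim_set A [generate_stimulus_set()] object.
#' @param n_runs Number of runs; must be even so the per-stimulus
#'   primed/control split is exact (default 10).
#' @param seed Optional integer seed; same seed, same table.
#' @param max_attempts Restart budget for the constrained randomization.
#'
#' @return A `trial_table` data frame with one row per presentation: `run`,
#'   `position` (0 for the leading discarded presentation), `stimulus`,
#'   `category`, `meta`, `condition` (`primed`/`control`/`discarded_first`),
#'   `prime` (the preceding stimulus id; `NA` for the leading row), and
#'   placeholder `rt`/`correct` columns filled by [simulate_behavior()].
#' @seealso [validate_trial_sequence()] for the invariant checker.
#' @examples
#' ss <- generate_stimulus_set(4, 3, seed = 1)
#' tt <- generate_trial_sequence(ss, n_runs = 4, seed = 1)
#' validate_trial_sequence(tt, ss)$valid
#' @export
generate_trial_sequence <- function(stim_set, n_runs = 10, seed = NULL,
                                    max_attempts = 200) {
  stopifnot(inherits(stim_set, "stimulus_set"))
  if (!is.numeric(n_runs) || n_runs < 2 || n_runs %% 2 != 0) {
    stop("`n_runs` must be an even number >= 2 so each stimulus can be ",
         "primed in exactly half of its presentations", call. = FALSE)
  }
  n_runs <- as.integer(n_runs)
  with_seed(seed, {
    plan <- draw_priming_plan(stim_set, n_runs, max_attempts)
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      runs[[r]] <- build_run(stim_set, plan[, r], r, max_attempts)
    }
    tt <- do.call(rbind, runs)
    rownames(tt) <- NULL
    class(tt) <- c("trial_table", "data.frame")
    chk <- validate_trial_sequence(tt, stim_set)
    if (!chk$valid) {  # construction is invariant-preserving; belt and braces
      stop("internal error: generated sequence failed validation: ",
           paste(chk$problems, collapse = "; "))
    }
    tt
  })
}

# Per-stimulus choice of primed runs, resampled until no (run, category)
# cell has all its exemplars primed (a run needs >= 1 control exemplar per
# category to lead each same-category block).
#' @noRd
draw_priming_plan <- function(stim_set, n_runs, max_attempts) {
  n_stim <- length(stim_set$stimuli)
  for (a in seq_len(max_attempts)) {
    plan <- matrix(FALSE, n_stim, n_runs,
                   dimnames = list(stim_set$stimuli, NULL))
    for (i in seq_len(n_stim)) {
      plan[i, sample.int(n_runs, n_runs %/% 2L)] <- TRUE
    }
    ok <- TRUE
    for (r in seq_len(n_runs)) {
      primed_per_cat <- tapply(plan[, r], stim_set$category_of, sum)
      if (any(primed_per_cat >= stim_set$n_exemplars)) { ok <- FALSE; break }
    }
    if (ok) return(plan)
  }
  stop("could not draw a feasible priming plan in ", max_attempts,
       " attempts", call. = FALSE)
}

# One run: build same-category blocks and arrange them with no two adjacent
# blocks of equal category, then prepend the discarded leading presentation.
#' @noRd
build_run <- function(stim_set, primed, run, max_attempts) {
  blocks <- list()
  block_cat <- integer(0)
  for (cat in seq_len(stim_set$n_categories)) {
    members <- stim_set$stimuli[stim_set$category_of == cat]
    p <- members[primed[members]]
    ctrl <- sample(members[!primed[members]])
    assign_to <- if (length(p)) sample.int(length(ctrl), length(p),
                                           replace = TRUE) else integer(0)
    for (b in seq_along(ctrl)) {
      blocks[[length(blocks) + 1L]] <- c(ctrl[b], sample(p[assign_to == b]))
      block_cat <- c(block_cat, cat)
    }
  }
  ord <- arrange_no_adjacent(block_cat, max_attempts)
  seq_stim <- unlist(blocks[ord], use.names = FALSE)
  first_cat <- stim_set$category_of[seq_stim[1]]
  lead_pool <- stim_set$stimuli[stim_set$category_of != first_cat]
  lead <- sample(lead_pool, 1L)
  stim <- c(lead, seq_stim)
  prev <- c(NA_character_, stim[-length(stim)])
  cat_of <- unname(stim_set$category_of[stim])
  condition <- ifelse(seq_along(stim) == 1L, "discarded_first",
                      ifelse(stim_set$category_of[prev] == cat_of,
                             "primed", "control"))
  data.frame(
    run = run,
    position = seq_along(stim) - 1L,
    stimulus = stim,
    category = cat_of,
    meta = meta_of_stimulus(stim_set, stim),
    condition = factor(condition,
                       levels = c("primed", "control", "discarded_first")),
    prime = prev,
    rt = NA_real_,
    correct = NA,
    stringsAsFactors = FALSE
  )
}

# Order block indices so no two consecutive labels are equal. Greedy with a
# forced pick whenever one label holds more than half of the remaining
# slots; restarts on the rare dead end.
#' @noRd
arrange_no_adjacent <- function(labels, max_attempts) {
  n <- length(labels)
  idx_by_lab <- split(seq_len(n), labels)
  for (a in seq_len(max_attempts)) {
    rem <- vapply(idx_by_lab, length, integer(1))
    # random draw order within label (guard the length-1 sample() gotcha)
    pool <- lapply(idx_by_lab, function(i) if (length(i) == 1L) i else sample(i))
    taken <- rem * 0L
    out <- integer(n)
    prev <- ""
    ok <- TRUE
    for (s in seq_len(n)) {
      left <- n - s + 1L
      forced <- names(rem)[2L * rem > left]
      if (length(forced) > 1L || (length(forced) == 1L && forced == prev)) {
        ok <- FALSE; break
      }
      lab <- if (length(forced) == 1L) {
        forced
      } else {
        avail <- names(rem)[rem > 0L & names(rem) != prev]
        if (!length(avail)) { ok <- FALSE; break }
        if (length(avail) == 1L) avail else
          sample(avail, 1L, prob = rem[avail])
      }
      taken[lab] <- taken[lab] + 1L
      out[s] <- pool[[lab]][taken[lab]]
      rem[lab] <- rem[lab] - 1L
      prev <- lab
    }
    if (ok) return(out)
  }
  stop("could not arrange category blocks without adjacent repeats in ",
       max_attempts, " attempts", call. = FALSE)
}

#' Check trial-sequence invariants
#'
#' Verifies a trial table against the design constraints: per run, one
#' leading discarded presentation followed by every stimulus exactly once as
#' target; per stimulus, an exact half/half primed/control split across the
#' session; `primed` if and only if the prime belongs to the same category;
#' never self-priming; and the recorded `prime` column consistent with the
#' actual predecessor in the sequence.
#'
#' @param tt A `trial_table`.
#' @param stim_set The [generate_stimulus_set()] object the table refers to.
#' @return A list with `valid` (logical) and `problems` (character vector,
#'   empty when valid).
#' @export
validate_trial_sequence <- function(tt, stim_set) {
  problems <- character(0)
  need <- c("run", "position", "stimulus", "condition", "prime")
  if (!all(need %in% names(tt))) {
    return(list(valid = FALSE,
                problems = paste("missing columns:",
                                 paste(setdiff(need, names(tt)),
                                       collapse = ", "))))
  }
  n_stim <- length(stim_set$stimuli)
  runs <- sort(unique(tt$run))
  n_runs <- length(runs)
  for (r in runs) {
    rows <- tt[tt$run == r, ]
    rows <- rows[order(rows$position), ]
    if (sum(rows$condition == "discarded_first") != 1L ||
        rows$condition[1] != "discarded_first") {
      problems <- c(problems, sprintf(
        "run %s: expected exactly one leading discarded_first row", r))
    }
    targets <- rows$stimulus[rows$condition != "discarded_first"]
    if (length(targets) != n_stim || !setequal(targets, stim_set$stimuli) ||
        anyDuplicated(targets)) {
      problems <- c(problems, sprintf(
        "run %s: targets are not each stimulus exactly once", r))
    }
    # prime column must be the actual predecessor
    expect_prime <- c(NA_character_, rows$stimulus[-nrow(rows)])
    bad <- which(!is.na(expect_prime) & rows$prime != expect_prime)
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "run %s: prime column disagrees with predecessor at %d row(s)",
        r, length(bad)))
    }
  }
  tg <- tt[tt$condition != "discarded_first", ]
  counts <- table(factor(tg$stimulus, levels = stim_set$stimuli),
                  factor(tg$condition, levels = c("primed", "control")))
  if (any(counts[, "primed"] != n_runs / 2) ||
      any(counts[, "control"] != n_runs / 2)) {
    problems <- c(problems, sprintf(
      "per-stimulus primed/control counts are not all (%d, %d)",
      n_runs / 2, n_runs / 2))
  }
  if (any(tg$prime == tg$stimulus, na.rm = TRUE)) {
    problems <- c(problems, "self-priming: a prime equals its target")
  }
  same_cat <- stim_set$category_of[tg$prime] == stim_set$category_of[tg$stimulus]
  mislab <- (tg$condition == "primed") != same_cat
  if (any(mislab, na.rm = TRUE)) {
    problems <- c(problems, sprintf(
      "%d row(s) whose condition label disagrees with prime/target category",
      sum(mislab, na.rm = TRUE)))
  }
  list(valid = length(problems) == 0L, problems = problems)
}

#' @export
print.trial_table <- function(x, ...) {
  tg <- x[x$condition != "discarded_first", ]
  cat(sprintf(
    "<trial_table> %d presentations (%d targets) in %d run(s), %d stimuli\n",
    nrow(x), nrow(tg), length(unique(x$run)), length(unique(tg$stimulus))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
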