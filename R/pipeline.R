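# End-to-end orchestration: one declarative config, deterministic
# per-stage seeds, and a JSON-serializable report.

#' Build a run configuration
#'
#' All named constants of the pipeline in one declarative list. Analysis
#' constants (windows, thresholds, alpha levels) default to the study's
#' values; simulation sizes default to a desk-scale session count and
#' cohort so a full run stays interactive.
#'
#' @param seed Global seed; expanded deterministically into per-stage seeds
#'   so any stage can be rerun in isolation.
#' @param n_sessions Number of synthetic sessions.
#' @param n_categories,n_exemplars,n_runs Stimulus-set and session layout.
#' @param rt [rt_params()] for the behavior simulator.
#' @param session_shift_sd SD (ms) of the between-session RT location
#'   jitter (sessions differ in overall speed).
#' @param ieeg_template [erp_template_spec()] for the iEEG simulator.
#' @param regions Regions simulated/analyzed for iEEG.
#' @param artifact_threshold Median-ratio rejection threshold.
#' @param early_window,late_window Peak-latency search windows (ms).
#' @param cluster_alpha,n_perm,percentiles Cluster-test constants.
#' @param response_alpha Simes level of the response criterion.
#' @param min_stimuli Multi-responsive selection threshold.
#' @param rank_alpha Level of the rank contrasts / classification.
#' @param burst_threshold Poisson-surprise acceptance threshold.
#' @param cohort Cohort specification for [simulate_population()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       n_sessions = 8,
                       n_categories = 10, n_exemplars = 10, n_runs = 10,
                       rt = rt_params(), session_shift_sd = 100,
                       ieeg_template = erp_template_spec(),
                       regions = c("AM", "HC", "EC", "PHC"),
                       artifact_threshold = 2.5,
                       early_window = c(200, 400),
                       late_window = c(400, 750),
                       cluster_alpha = 0.001, n_perm = 1000,
                       percentiles = c(0.01, 0.99),
                       response_alpha = 0.001, min_stimuli = 4,
                       rank_alpha = 0.05, burst_threshold = 2,
                       cohort = list(
                         list(region = "AM", n_units = 40,
                              mech = mechanism_spec("sharpening")),
                         list(region = "HC", n_units = 40,
                              mech = mechanism_spec("fatiguing")))) {
  cfg <- list(seed = seed, n_sessions = n_sessions,
              n_categories = n_categories, n_exemplars = n_exemplars,
              n_runs = n_runs, rt = rt, session_shift_sd = session_shift_sd,
              ieeg_template = ieeg_template, regions = regions,
              artifact_threshold = artifact_threshold,
              early_window = early_window, late_window = late_window,
              cluster_alpha = cluster_alpha, n_perm = n_perm,
              percentiles = percentiles, response_alpha = response_alpha,
              min_stimuli = min_stimuli, rank_alpha = rank_alpha,
              burst_threshold = burst_threshold, cohort = cohort)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every constant against its legal range before any computation.
#'
#' @param cfg A configuration list.
#' @return The config, invisibly; errors on the first violation.
#' @export
validate_run_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg,
                                         call. = FALSE)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be scalar")
  chk(cfg$n_sessions >= 1, "n_sessions must be >= 1")
  chk(cfg$n_runs >= 2 && cfg$n_runs %% 2 == 0, "n_runs must be even >= 2")
  chk(inherits(cfg$rt, "rt_params"), "rt must be rt_params()")
  chk(cfg$session_shift_sd >= 0, "session_shift_sd must be >= 0")
  chk(inherits(cfg$ieeg_template, "erp_template_spec"),
      "ieeg_template must be erp_template_spec()")
  chk(cfg$artifact_threshold > 0, "artifact_threshold must be > 0")
  chk(cfg$cluster_alpha > 0 && cfg$cluster_alpha < 1,
      "cluster_alpha must be in (0, 1)")
  chk(cfg$n_perm >= 100, "n_perm must be >= 100")
  chk(all(cfg$percentiles > 0 & cfg$percentiles < 1) &&
        cfg$percentiles[1] < cfg$percentiles[2],
      "percentiles must be increasing in (0, 1)")
  chk(cfg$response_alpha > 0 && cfg$response_alpha < 1,
      "response_alpha must be in (0, 1)")
  chk(cfg$min_stimuli >= 1, "min_stimuli must be >= 1")
  chk(cfg$rank_alpha > 0 && cfg$rank_alpha < 1,
      "rank_alpha must be in (0, 1)")
  chk(cfg$burst_threshold > 0, "burst_threshold must be > 0")
  check_window(cfg$early_window, "early_window")
  check_window(cfg$late_window, "late_window")
  for (entry in cfg$cohort) {
    chk(!is.null(entry$n_units) && entry$n_units >= 1,
        "cohort entries need n_units >= 1")
    chk(inherits(entry$mech, "mechanism_spec"),
        "cohort entries need a mechanism_spec()")
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Scalars in the file override [run_config()] defaults; nested
#' `rt`, `ieeg_template`, and `cohort` entries are passed to their
#' constructors.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$rt)) raw$rt <- do.call(rt_params, raw$rt)
  if (!is.null(raw$ieeg_template)) {
    raw$ieeg_template <- do.call(erp_template_spec, raw$ieeg_template)
  }
  if (!is.null(raw$cohort)) {
    raw$cohort <- lapply(raw$cohort, function(e) {
      e$mech <- do.call(mechanism_spec, e$mech)
      e
    })
  }
  do.call(run_config, raw)
}

#' Simulate one complete session
#'
#' Trial sequence, behavior, per-region iEEG segments, and (optionally) a
#' unit cohort, under one seed.
#'
#' @param cfg A [run_config()].
#' @param seed Session seed.
#' @param stim_set Stimulus set shared across sessions.
#' @param with_units Simulate the unit cohort too (default `FALSE`: the
#'   cohort is usually attached to one session).
#' @return List with `trials`, `ieeg` (named by region), optionally
#'   `units`.
#' @export
simulate_session <- function(cfg, seed, stim_set, with_units = FALSE) {
  tt <- generate_trial_sequence(stim_set, cfg$n_runs,
                                seed = derive_seed(seed, "sequence"))
  rtp <- cfg$rt
  if (cfg$session_shift_sd > 0) {
    jit <- with_seed(derive_seed(seed, "session_shift"),
                     stats::rnorm(1, 0, cfg$session_shift_sd))
    rtp$shift <- max(0, rtp$shift + jit)
  }
  tt <- simulate_behavior(tt, rtp, seed = derive_seed(seed, "behavior"))
  ieeg <- lapply(stats::setNames(cfg$regions, cfg$regions), function(rg) {
    simulate_ieeg(tt, cfg$ieeg_template,
                  seed = derive_seed(seed, paste0("ieeg_", rg)),
                  region = rg)
  })
  out <- list(trials = tt, ieeg = ieeg)
  if (with_units) {
    out$units <- simulate_population(tt, cfg$cohort, stim_set = stim_set,
                                     seed = derive_seed(seed, "units"))
  }
  out
}

#' Run the full pipeline on simulated sessions
#'
#' Executes, in order: session simulation, behavioral contrasts (with and
#' without response-priming exclusion, RT and accuracy), iEEG artifact
#' rejection, per-session and grand-average ERPs, cluster-based permutation
#' tests and peak-latency contrasts per region, single-unit response
#' detection, tuning-curve rank contrasts with population classification
#' (amygdala vs other-MTL groups), burst-duration contrast, and the
#' pre-stimulus test. Stage counts are logged via `message()`.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional directory; when given, the JSON report and CSV
#'   exports are written there.
#' @return The report (list, class `mtladapt_report`) containing the
#'   resolved config echo, per-stage seeds, counts, and all results. The
#'   report is fully reproducible from `cfg$seed`.
#' @export
run_all <- function(cfg = run_config(), out_dir = NULL) {
  validate_run_config(cfg)
  t_start <- proc.time()[["elapsed"]]
  stim_set <- generate_stimulus_set(cfg$n_categories, cfg$n_exemplars,
                                    seed = derive_seed(cfg$seed, "stimuli"))
  session_seeds <- vapply(seq_len(cfg$n_sessions), function(s) {
    derive_seed(cfg$seed, paste0("session_", s))
  }, numeric(1))
  message("simulating ", cfg$n_sessions, " session(s)")
  sessions <- lapply(seq_len(cfg$n_sessions), function(s) {
    simulate_session(cfg, session_seeds[s], stim_set,
                     with_units = (s == 1L))
  })
  trials <- lapply(sessions, `[[`, "trials")

  # --- behavior ---
  message("behavioral contrasts")
  behavior <- list(
    rt_all = contrast_rt(trials, stim_set, exclude_response_priming = FALSE),
    rt_no_response_priming = contrast_rt(trials, stim_set,
                                         exclude_response_priming = TRUE),
    accuracy_all = contrast_accuracy(trials, stim_set, FALSE),
    accuracy_no_response_priming = contrast_accuracy(trials, stim_set, TRUE))
  n_excluded_rt <- sum(vapply(trials, function(tt) sum(exclude_rt_outliers(tt)),
                              numeric(1)))
  message("  RT outliers excluded across sessions: ", n_excluded_rt)

  # --- iEEG ---
  ieeg <- list()
  for (rg in cfg$regions) {
    message("iEEG region ", rg)
    erps <- list()
    n_rejected <- 0L
    for (s in seq_along(sessions)) {
      seg <- baseline_correct(sessions[[s]]$ieeg[[rg]])
      mask <- reject_artifacts(seg, cfg$artifact_threshold)
      n_rejected <- n_rejected + sum(mask)
      erps[[s]] <- compute_erp(seg, mask)
    }
    pa <- do.call(rbind, lapply(erps, function(e) e$traces$primed))
    pb <- do.call(rbind, lapply(erps, function(e) e$traces$control))
    tms <- sample_times(ncol(pa), erps[[1]]$fs, erps[[1]]$window[1])
    clus <- suppressWarnings(cluster_permutation_test(
      pa, pb, cfg$cluster_alpha, cfg$n_perm,
      seed = derive_seed(cfg$seed, paste0("perm_", rg)), times = tms,
      percentiles = cfg$percentiles))
    ieeg[[rg]] <- list(
      grand_average = grand_average_erp(erps),
      n_segments_rejected = n_rejected,
      clusters = clus,
      peak_early_negative = peak_latency_contrast(erps, cfg$early_window,
                                                  "negative"),
      peak_late_positive = peak_latency_contrast(erps, cfg$late_window,
                                                 "positive"))
    message("  segments rejected: ", n_rejected, "; clusters: ", nrow(clus))
  }

  # --- spikes ---
  message("single-unit analyses (", length(sessions[[1]]$units), " units)")
  units <- sessions[[1]]$units
  decisions <- do.call(rbind, lapply(seq_along(units), function(u) {
    d <- response_decisions(units[[u]], alpha = cfg$response_alpha)
    d$unit <- u
    d
  }))
  responsive_of <- lapply(seq_along(units), function(u) {
    d <- decisions[decisions$unit == u, ]
    d$stimulus[d$responsive]
  })
  selected <- as.integer(select_multiresponsive_units(decisions,
                                                      cfg$min_stimuli))
  message("  multi-responsive units (>= ", cfg$min_stimuli, " stimuli): ",
          length(selected))
  regions_of <- vapply(units, `[[`, character(1), "region")
  groups <- list(AM = selected[regions_of[selected] == "AM"],
                 MTL = selected[regions_of[selected] != "AM"])
  spikes <- list(n_units = length(units),
                 n_responsive_pairs = sum(decisions$responsive),
                 n_multiresponsive = length(selected))
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < 3L) {
      message("  group ", g, ": ", length(ids),
              " unit(s); rank contrast skipped")
      spikes[[g]] <- list(n_units = length(ids), profile = "indeterminate")
      next
    }
    curves <- lapply(ids, function(u) {
      build_tuning_curve(units[[u]], responsive_of[[u]])
    })
    ctr <- contrast_tuning(curves)
    spikes[[g]] <- list(n_units = length(ids), contrast = ctr,
                        profile = classify_population_profile(
                          ctr, cfg$rank_alpha))
    message("  group ", g, ": profile '", spikes[[g]]$profile, "'")
  }
  has_resp <- which(vapply(responsive_of, length, integer(1)) > 0)
  spikes$prestimulus <- if (length(has_resp) >= 2L) {
    prestimulus_test(units[has_resp], responsive_of[has_resp])
  } else NULL
  spikes$burst <- tryCatch(
    contrast_burst_duration(
      units[has_resp],
      trials_list = lapply(has_resp, function(u) {
        which(units[[u]]$trial_stimulus %in% responsive_of[[u]])
      }),
      surprise_threshold = cfg$burst_threshold),
    error = function(e) {
      message("  burst contrast skipped: ", conditionMessage(e))
      NULL
    })

  report <- build_report(cfg, behavior, ieeg, spikes, session_seeds,
                         elapsed = proc.time()[["elapsed"]] - t_start)
  if (!is.null(out_dir)) write_report(report, ieeg, out_dir)
  class(report) <- "mtladapt_report"
  report
}

# Numeric summary of every stage: plain lists only so JSON output is stable
# and byte-identical for a fixed seed.
#' @noRd
build_report <- function(cfg, behavior, ieeg, spikes, session_seeds,
                         elapsed) {
  strip_contrast <- function(x) {
    list(md_primed = x$md_primed, iqr_primed = x$iqr_primed,
         md_control = x$md_control, iqr_control = x$iqr_control,
         statistic = x$statistic, p_value = x$p_value, n = x$n)
  }
  ieeg_out <- lapply(ieeg, function(rg) {
    list(n_segments_rejected = rg$n_segments_rejected,
         clusters = as.data.frame(rg$clusters),
         peak_early_negative = strip_contrast(rg$peak_early_negative),
         peak_late_positive = strip_contrast(rg$peak_late_positive))
  })
  spikes_out <- list(n_units = spikes$n_units,
                     n_responsive_pairs = spikes$n_responsive_pairs,
                     n_multiresponsive = spikes$n_multiresponsive)
  for (g in c("AM", "MTL")) {
    if (!is.null(spikes[[g]])) {
      spikes_out[[g]] <- list(
        n_units = spikes[[g]]$n_units,
        profile = spikes[[g]]$profile,
        per_rank = if (!is.null(spikes[[g]]$contrast))
          spikes[[g]]$contrast$per_rank[, c("rank", "n", "mean_primed",
                                            "mean_control", "t", "p")]
        else NULL)
    }
  }
  if (!is.null(spikes$prestimulus)) {
    ps <- spikes$prestimulus
    spikes_out$prestimulus <- list(mean_primed = ps$mean_primed,
                                   mean_control = ps$mean_control,
                                   t = ps$t, df = ps$df, p = ps$p, n = ps$n)
  }
  if (!is.null(spikes$burst)) {
    b <- spikes$burst
    spikes_out$burst <- list(mean_duration_diff = b$mean_diff, t = b$t,
                             df = b$df, p_t = b$p_t, n = b$n)
  }
  list(
    package_version = as.character(utils::packageVersion("mtladapt")),
    seed = cfg$seed,
    session_seeds = session_seeds,
    config_hash = config_hash(cfg),
    elapsed_s = round(elapsed, 1),
    behavior = lapply(behavior, strip_contrast),
    ieeg = ieeg_out,
    spikes = spikes_out)
}

#' @noRd
config_hash <- function(cfg) {
  bytes <- serialize(cfg, NULL, version = 3L)
  sprintf("%08x", sum(as.integer(bytes) * (seq_along(bytes) %% 251)) %%
            .Machine$integer.max)
}

#' @noRd
write_report <- function(report, ieeg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- report
  out$elapsed_s <- NULL  # wall time must not break byte-identity
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (rg in names(ieeg)) {
    export_cluster_results(ieeg[[rg]]$clusters, rg,
                           file.path(out_dir,
                                     paste0("clusters_", rg, ".csv")))
    export_erp(ieeg[[rg]]$grand_average,
               file.path(out_dir, paste0("erp_", rg, ".csv")))
  }
  invisible(out_dir)
}

#' @export
print.mtladapt_report <- function(x, ...) {
  cat("<mtladapt_report> seed", x$seed, "| config", x$config_hash, "\n")
  cat(sprintf("  behavior: RT Md primed %.0f / control %.0f ms (p = %.2g)\n",
              x$behavior$rt_all$md_primed, x$behavior$rt_all$md_control,
              x$behavior$rt_all$p_value))
  for (rg in names(x$ieeg)) {
    cat(sprintf("  iEEG %s: %d cluster(s), early negative-peak shift p = %.2g\n",
                rg, nrow(x$ieeg[[rg]]$clusters),
                x$ieeg[[rg]]$peak_early_negative$p_value))
  }
  for (g in c("AM", "MTL")) {
    if (!is.null(x$spikes[[g]])) {
      cat(sprintf("  units %s: n = %d, profile '%s'\n", g,
                  x$spikes[[g]]$n_units, x$spikes[[g]]$profile))
    }
  }
  invisible(x)
}
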