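# Plain-text session serialization: trial table as CSV, spikes as a long
# CSV (unit, trial, timestamp), iEEG segments as one wide CSV per region,
# and a JSON manifest tying the files into a session.

#' Write a session to a directory
#'
#' @param session List with `trials` (trial table), optional `units` (list
#'   of `unit_recording`), optional `ieeg` (named list of `ieeg_segments`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format_version = 1L, files = list())
  tt <- session$trials
  utils::write.csv(as.data.frame(tt), file.path(dir, "trials.csv"),
                   row.names = FALSE)
  manifest$files$trials <- "trials.csv"
  if (!is.null(session$units)) {
    meta <- do.call(rbind, lapply(seq_along(session$units), function(u) {
      un <- session$units[[u]]
      data.frame(unit = u, region = un$region, unit_class = un$unit_class,
                 baseline_rate = un$baseline_rate,
                 window_start = un$window[1], window_end = un$window[2],
                 mechanism = un$ground_truth$mechanism,
                 tuned_stimuli = paste(un$ground_truth$tuned_stimuli,
                                       collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(meta, file.path(dir, "units.csv"), row.names = FALSE)
    spk <- do.call(rbind, lapply(seq_along(session$units), function(u) {
      s <- session$units[[u]]$spikes
      n <- lengths(s)
      data.frame(unit = u, trial = rep(seq_along(s), n),
                 t_ms = unlist(s, use.names = FALSE))
    }))
    utils::write.csv(spk, file.path(dir, "spikes.csv"), row.names = FALSE)
    manifest$files$units <- "units.csv"
    manifest$files$spikes <- "spikes.csv"
  }
  if (!is.null(session$ieeg)) {
    manifest$files$ieeg <- list()
    for (rg in names(session$ieeg)) {
      seg <- session$ieeg[[rg]]
      fn <- paste0("ieeg_", rg, ".csv")
      utils::write.csv(as.data.frame(seg$data), file.path(dir, fn),
                       row.names = FALSE)
      manifest$files$ieeg[[rg]] <- list(
        data = fn, fs = seg$fs, window = seg$window,
        condition = seg$condition, region = rg,
        artifact_truth = seg$artifact_truth,
        baseline_corrected = isTRUE(seg$baseline_corrected))
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory containing `manifest.json`.
#' @return List with `trials` and, when present, `units` and `ieeg`.
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tt <- utils::read.csv(file.path(dir, manifest$files$trials),
                        stringsAsFactors = FALSE)
  tt$condition <- factor(tt$condition,
                         levels = c("primed", "control", "discarded_first"))
  class(tt) <- c("trial_table", "data.frame")
  out <- list(trials = tt)
  if (!is.null(manifest$files$units)) {
    meta <- utils::read.csv(file.path(dir, manifest$files$units),
                            stringsAsFactors = FALSE)
    spk <- utils::read.csv(file.path(dir, manifest$files$spikes))
    tg <- tt[tt$condition != "discarded_first", ]
    out$units <- lapply(seq_len(nrow(meta)), function(u) {
      su <- spk[spk$unit == u, ]
      spikes <- rep(list(numeric(0)), nrow(tg))
      filled <- split(su$t_ms, factor(su$trial, levels = seq_len(nrow(tg))))
      for (i in seq_along(filled)) spikes[[i]] <- as.numeric(filled[[i]])
      structure(
        list(spikes = spikes, trial_stimulus = tg$stimulus,
             trial_condition = as.character(tg$condition),
             region = meta$region[u], unit_class = meta$unit_class[u],
             window = c(meta$window_start[u], meta$window_end[u]),
             baseline_rate = meta$baseline_rate[u],
             ground_truth = list(
               mechanism = meta$mechanism[u],
               tuned_stimuli = strsplit(meta$tuned_stimuli[u], ";")[[1]])),
        class = "unit_recording")
    })
  }
  if (!is.null(manifest$files$ieeg)) {
    out$ieeg <- lapply(manifest$files$ieeg, function(m) {
      data <- as.matrix(utils::read.csv(file.path(dir, m$data)))
      dimnames(data) <- NULL
      new_ieeg_segments(data, m$fs, m$window, m$condition, m$region,
                        artifact_truth = m$artifact_truth,
                        baseline_corrected = isTRUE(m$baseline_corrected))
    })
  }
  out
}

#' Export cluster results as CSV
#'
#' One row per cluster with region, direction, extent in ms, size, summed
#' t-value, and the Monte-Carlo p-value.
#'
#' @param clusters A `cluster_result`.
#' @param region Region label written into the table.
#' @param file Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_cluster_results <- function(clusters, region, file) {
  df <- as.data.frame(clusters)
  out <- data.frame(
    region = rep(region, nrow(df)),
    direction = ifelse(df$sign > 0, "primed>control", "primed<control"),
    start_ms = df$start_ms %||% df$start,
    end_ms = df$end_ms %||% df$end,
    clustersize = df$size,
    sum_t = df$sum_t,
    p = df$p_mc,
    significant = df$significant)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Export an ERP as tidy CSV
#'
#' Long format: time in ms, condition, mean, SEM, n.
#'
#' @param erp An `erp` object.
#' @param file Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_erp <- function(erp, file) {
  t <- sample_times(length(erp$traces[[1]]), erp$fs, erp$window[1])
  out <- do.call(rbind, lapply(names(erp$traces), function(cond) {
    data.frame(time_ms = t, condition = cond, mean = erp$traces[[cond]],
               sem = erp$sem[[cond]], n = erp$n[[cond]])
  }))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Export tuning curves as a rank x condition table
#'
#' One row per unit, rank, and condition with the normalized firing rate —
#' the layout used to hand the data to an external mixed ANOVA.
#'
#' @param curves Named or indexed list of `tuning_curve` objects.
#' @param file Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_tuning_table <- function(curves, file) {
  out <- do.call(rbind, lapply(seq_along(curves), function(u) {
    cv <- curves[[u]]
    if (is.null(cv)) return(NULL)
    rbind(
      data.frame(unit = u, region = attr(cv, "unit_region"), rank = cv$rank,
                 condition = "primed", norm_rate = cv$primed_norm),
      data.frame(unit = u, region = attr(cv, "unit_region"), rank = cv$rank,
                 condition = "control", norm_rate = cv$control_norm))
  }))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
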