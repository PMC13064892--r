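#' Configuration for simulated mitosis time-lapse traces
#'
#' Each simulated cell is imaged as a per-timepoint mean centromere
#' intensity (normalized units). The trace sits at `pre_level` until the
#' cell enters mitosis, has no valid measurement during mitosis (foci are
#' not followed as a per-cell average during chromosome congression), and
#' then continues as two daughter traces that remain at `pre_level` until
#' `recovery_delay` hours after mitotic exit, when intensity steps up to
#' `post_level` (emulating post-mitotic deposition of new centromere
#' protein). Gaussian noise is added to every observation.
#'
#' @param sampling_interval Minutes between frames (default 15).
#' @param duration Total imaging time in hours (default 36).
#' @param mitosis_time Mean time of mitotic entry, hours.
#' @param mitosis_time_jitter_sd Per-cell sd of mitotic entry time, hours.
#' @param mitosis_duration Minutes from mitotic entry to exit (default 30).
#' @param pre_level,post_level Normalized intensity before mitosis and
#'   after recovery.
#' @param recovery_delay Hours after mitotic exit before `post_level` is
#'   reached.
#' @param noise_sd Sd of additive Gaussian measurement noise.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(sampling_interval = 15, duration = 36,
                         mitosis_time = 18, mitosis_time_jitter_sd = 2,
                         mitosis_duration = 30,
                         pre_level = 0.4, post_level = 1.0,
                         recovery_delay = 1, noise_sd = 0.05,
                         seed = NULL) {
  if (sampling_interval <= 0) stop("sampling_interval must be > 0")
  stopifnot(duration > 0, mitosis_time > 0, mitosis_time < duration,
            mitosis_duration > 0, pre_level >= 0, post_level >= 0,
            recovery_delay >= 0, noise_sd >= 0,
            mitosis_time_jitter_sd >= 0)
  cfg <- list(sampling_interval = sampling_interval, duration = duration,
              mitosis_time = mitosis_time,
              mitosis_time_jitter_sd = mitosis_time_jitter_sd,
              mitosis_duration = mitosis_duration,
              pre_level = pre_level, post_level = post_level,
              recovery_delay = recovery_delay, noise_sd = noise_sd,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "trace_config"
  cfg
}

#' Simulate mitosis-spanning centromere intensity traces
#'
#' Produces a long-format trace table in the package's trace CSV layout:
#' one row per (cell, timepoint), with daughter cells linked to their
#' parent via `parent_id` and the parent's mitotic entry/exit annotated on
#' every row of the lineage.
#'
#' @param config A [trace_config()].
#' @param n_cells Number of parent cells.
#' @param replicate Replicate label attached to all rows.
#' @return A data frame with columns `cell_id`, `parent_id`, `time_h`,
#'   `value`, `mitosis_entry_h`, `mitosis_exit_h`, `replicate`.
#' @export
generate_timelapse <- function(config, n_cells = 30, replicate = 1L) {
  stopifnot(inherits(config, "trace_config"), n_cells >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  dt <- config$sampling_interval / 60   # hours
  grid <- seq(0, config$duration, by = dt)
  mit_len <- config$mitosis_duration / 60

  rows <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    entry <- config$mitosis_time +
      if (config$mitosis_time_jitter_sd > 0)
        stats::rnorm(1, 0, config$mitosis_time_jitter_sd) else 0
    entry <- min(max(entry, 2 * dt), config$duration - mit_len - 2 * dt)
    exit <- entry + mit_len
    pid <- sprintf("cell%03d", k)

    pre_t <- grid[grid < entry]
    parent <- data.frame(
      cell_id = pid, parent_id = NA_character_,
      time_h = pre_t,
      value = config$pre_level +
        stats::rnorm(length(pre_t), 0, config$noise_sd),
      mitosis_entry_h = entry, mitosis_exit_h = exit,
      replicate = replicate, stringsAsFactors = FALSE)

    post_t <- grid[grid > exit]
    level <- ifelse(post_t >= exit + config$recovery_delay,
                    config$post_level, config$pre_level)
    daughters <- lapply(1:2, function(d)
      data.frame(
        cell_id = sprintf("%s.%d", pid, d), parent_id = pid,
        time_h = post_t,
        value = level + stats::rnorm(length(post_t), 0, config$noise_sd),
        mitosis_entry_h = entry, mitosis_exit_h = exit,
        replicate = replicate, stringsAsFactors = FALSE))
    rows[[k]] <- rbind(parent, daughters[[1]], daughters[[2]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
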