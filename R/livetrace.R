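#' Snap trace timepoints to a common timebase
#'
#' Each observation is moved to the nearest multiple of
#' `target_interval` minutes, with no interpolation: grid marks with no
#' observation stay missing, and when two observations of the same cell
#' snap to the same mark only the one nearer in time is kept (ties keep
#' the earlier observation). This merges mixed acquisition intervals
#' (e.g. 15-min and 20-min series) onto one grid.
#'
#' @param traces Trace table (`cell_id`, `time_h`, `value`, ...). Exact
#'   duplicate timestamps within a cell are an error.
#' @param target_interval Grid spacing in minutes (default 5).
#' @return The trace table with `time_h` snapped, sorted by cell and
#'   time.
#' @export
resample_timebase <- function(traces, target_interval = 5) {
  stopifnot(target_interval > 0,
            all(c("cell_id", "time_h", "value") %in% names(traces)))
  if (anyDuplicated(traces[, c("cell_id", "time_h")]))
    stop("duplicate exact timestamps within a cell")
  dt <- target_interval / 60
  snapped <- round(traces$time_h / dt) * dt
  dist <- abs(traces$time_h - snapped)
  ## collisions: keep the observation nearest its mark, earlier one on ties
  o <- order(traces$cell_id, snapped, dist, traces$time_h)
  t2 <- traces[o, , drop = FALSE]
  s2 <- snapped[o]
  keep <- !duplicated(data.frame(cell_id = t2$cell_id, mark = s2))
  out <- t2[keep, , drop = FALSE]
  out$time_h <- s2[keep]
  out <- out[order(out$cell_id, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align traces to mitosis and build the ensemble mean and SD
#'
#' Shifts each trace's clock so that mitotic entry is time zero (daughter
#' traces inherit the parent's clock through their annotated
#' `mitosis_entry_h`), restricts to a window around mitosis, and computes
#' the across-trace mean, sample SD, and trace count at each gridpoint.
#' Traces without a mitosis annotation are excluded with a warning.
#'
#' @param traces Trace table with `mitosis_entry_h` per row.
#' @param window Length-2 numeric, hours relative to mitotic entry
#'   (default `c(-12, 12)`).
#' @param grid_interval Gridpoint spacing in minutes; default 15. Shifted
#'   times are snapped to this grid.
#' @return A data frame of class `aligned_ensemble`: `rel_time_h`,
#'   `mean`, `sd`, `n`.
#' @export
align_to_mitosis <- function(traces, window = c(-12, 12),
                             grid_interval = 15) {
  stopifnot(length(window) == 2, window[1] < window[2])
  no_mit <- is.na(traces$mitosis_entry_h)
  if (any(no_mit)) {
    warning("excluding ", length(unique(traces$cell_id[no_mit])),
            " trace(s) without a mitosis annotation")
    traces <- traces[!no_mit, , drop = FALSE]
  }
  if (nrow(traces) == 0) stop("no annotated traces to align")
  dt <- grid_interval / 60
  ## integer gridpoint index avoids floating-point grouping artefacts
  idx <- as.integer(round((traces$time_h - traces$mitosis_entry_h) / dt))
  sel <- idx * dt >= window[1] - 1e-9 & idx * dt <= window[2] + 1e-9 &
    !is.na(traces$value)
  idx <- idx[sel]
  val <- traces$value[sel]
  grid <- sort(unique(idx))
  agg <- function(f) vapply(grid, function(g) f(val[idx == g]), numeric(1))
  out <- data.frame(
    rel_time_h = grid * dt,
    mean = agg(mean),
    sd = agg(function(v) if (length(v) > 1) stats::sd(v) else NA_real_),
    n = vapply(grid, function(g) sum(idx == g), numeric(1)))
  rownames(out) <- NULL
  class(out) <- c("aligned_ensemble", "data.frame")
  out
}

#' Pre- and post-mitosis window averages per cell lineage
#'
#' For each parent cell: the pre-mitosis mean is the average of all its
#' observations from the start of its trace up to (but excluding) mitotic
#' entry; the post-mitosis mean averages all observations from
#' `post_gap_h` hours after mitotic exit (inclusive) to the end of the
#' trace. Daughter traces contribute to their parent's post window; to
#' avoid double-weighting divided cells, the parent's post value is the
#' mean of its daughters' post-window means. An empty window yields a
#' missing value.
#'
#' @param traces Trace table with `parent_id`, `mitosis_entry_h`,
#'   `mitosis_exit_h`.
#' @param post_gap_h Hours after mitotic exit at which the post window
#'   opens (default 1; an observation at exactly exit + `post_gap_h` is
#'   included).
#' @return Data frame with `cell_id`, `pre_mean`, `post_mean`,
#'   `replicate`.
#' @export
pre_post_mitosis_means <- function(traces, post_gap_h = 1) {
  parents <- traces[is.na(traces$parent_id), , drop = FALSE]
  if (nrow(parents) == 0) stop("no parent traces found")
  ids <- unique(parents$cell_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- parents[parents$cell_id == ids[i], , drop = FALSE]
    entry <- p$mitosis_entry_h[1]
    exit <- p$mitosis_exit_h[1]
    pre_v <- p$value[p$time_h < entry & !is.na(p$value)]
    pre_mean <- if (length(pre_v)) mean(pre_v) else NA_real_

    post_mean <- NA_real_
    if (is.finite(exit)) {
      open <- exit + post_gap_h
      kids <- traces[!is.na(traces$parent_id) &
                       traces$parent_id == ids[i], , drop = FALSE]
      if (nrow(kids) > 0) {
        km <- vapply(split(kids, kids$cell_id), function(d) {
          v <- d$value[d$time_h >= open & !is.na(d$value)]
          if (length(v)) mean(v) else NA_real_
        }, numeric(1))
        km <- km[is.finite(km)]
        if (length(km)) post_mean <- mean(km)
      } else {
        v <- p$value[p$time_h >= open & !is.na(p$value)]
        if (length(v)) post_mean <- mean(v)
      }
    }
    out[[i]] <- data.frame(cell_id = ids[i], pre_mean = pre_mean,
                           post_mean = post_mean,
                           replicate = p$replicate[1],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
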