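#' Normalize per-cell intensities to a reference condition
#'
#' Divides each per-cell value by the mean (or median) per-cell value of
#' the reference condition, by default within each replicate so that
#' between-replicate staining differences cancel. After normalization the
#' reference condition averages to exactly 1 (per replicate in
#' `per_replicate` mode, overall in `pooled` mode).
#'
#' @param cell_records Data frame with `condition`, `replicate`, and the
#'   value column.
#' @param reference_condition Condition to normalize to.
#' @param mode `"per_replicate"` (default) or `"pooled"`.
#' @param value_col Column to normalize (default
#'   `"mean_target_adjusted"`).
#' @param stat Reference statistic, `"mean"` (default; makes the
#'   normalized reference average exactly 1) or `"median"`.
#' @return The input with an added `value_norm` column and attributes
#'   `reference_condition`, `normalization_mode`.
#' @export
normalize_to_reference <- function(cell_records, reference_condition,
                                   mode = c("per_replicate", "pooled"),
                                   value_col = "mean_target_adjusted",
                                   stat = c("mean", "median")) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  stopifnot(value_col %in% names(cell_records))
  statf <- if (stat == "mean") mean else stats::median
  v <- cell_records[[value_col]]
  is_ref <- cell_records$condition == reference_condition
  if (!any(is_ref))
    stop("reference condition '", reference_condition, "' not present")
  if (mode == "pooled") {
    ref <- statf(v[is_ref], na.rm = TRUE)
    if (!is.finite(ref))
      stop("reference condition '", reference_condition,
           "' has no non-missing values")
    cell_records$value_norm <- v / ref
  } else {
    cell_records$value_norm <- NA_real_
    for (r in unique(cell_records$replicate)) {
      in_r <- cell_records$replicate == r
      ref <- statf(v[in_r & is_ref], na.rm = TRUE)
      if (!is.finite(ref))
        stop("replicate '", r, "' has no non-missing values for ",
             "reference condition '", reference_condition, "'")
      cell_records$value_norm[in_r] <- v[in_r] / ref
    }
  }
  attr(cell_records, "reference_condition") <- reference_condition
  attr(cell_records, "normalization_mode") <- mode
  cell_records
}

#' Per-replicate per-condition means of normalized per-cell values
#'
#' The replicate averages are the statistical units for all hypothesis
#' tests (superplot convention): cells within a replicate are not
#' independent, so tests run on these averages, never on pooled cells.
#' Missing per-cell values are excluded; an empty (condition, replicate)
#' cell is dropped with a warning.
#'
#' @param normalized Output of [normalize_to_reference()] (or any data
#'   frame with `condition`, `replicate` and the value column).
#' @param value_col Column to average (default `"value_norm"`).
#' @return Data frame with `condition`, `replicate`, `mean_value`,
#'   `n_cells`.
#' @export
replicate_means <- function(normalized, value_col = "value_norm") {
  stopifnot(value_col %in% names(normalized))
  sp <- split(normalized,
              list(condition = normalized$condition,
                   replicate = normalized$replicate), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d[[value_col]][!is.na(d[[value_col]])]
    data.frame(condition = d$condition[1], replicate = d$replicate[1],
               mean_value = if (length(v)) mean(v) else NA_real_,
               n_cells = length(v), stringsAsFactors = FALSE)
  }))
  if (any(is.na(out$mean_value))) {
    bad <- out[is.na(out$mean_value), ]
    warning("dropping empty replicate cell(s): ",
            paste(bad$condition, bad$replicate, sep = "/",
                  collapse = ", "))
    out <- out[!is.na(out$mean_value), ]
  }
  out <- out[order(out$condition, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Welch's unpaired two-sample t test
#'
#' Unpaired, parametric, two-tailed t test with Welch's correction
#' (unequal variances; Welch-Satterthwaite degrees of freedom), intended
#' to be run on replicate averages. Requires at least two values per
#' group; degenerate input with no variance in either group is an error.
#'
#' @param group_a,group_b Numeric vectors (replicate means).
#' @return A list of class `welch_result`: `t`, `df`, `p`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("Welch's t test needs at least 2 replicate values per group ",
         "(got ", length(a), " and ", length(b), ")")
  ht <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                 error = function(e)
                   stop("Welch's t test undefined: ", conditionMessage(e),
                        call. = FALSE))
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "welch_result")
}

#' All pairwise Welch tests over replicate means
#'
#' Mirrors the convention of reporting every pairwise condition
#' comparison with its raw (uncorrected) p value.
#'
#' @param rep_means Output of [replicate_means()].
#' @return Data frame with one row per condition pair: `condition_a`,
#'   `condition_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `test_missing` (TRUE when a group had fewer than 2 replicates or no
#'   variance).
#' @export
pairwise_welch <- function(rep_means) {
  conds <- sort(unique(rep_means$condition))
  if (length(conds) < 2)
    stop("need at least two conditions for pairwise comparisons")
  pairs <- utils::combn(conds, 2)
  out <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- rep_means$mean_value[rep_means$condition == pairs[1, i]]
    b <- rep_means$mean_value[rep_means$condition == pairs[2, i]]
    w <- tryCatch(welch_t_test(a, b), error = function(e) NULL)
    out[[i]] <- data.frame(
      condition_a = pairs[1, i], condition_b = pairs[2, i],
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      t = if (is.null(w)) NA_real_ else w$t,
      df = if (is.null(w)) NA_real_ else w$df,
      p = if (is.null(w)) NA_real_ else w$p,
      test_missing = is.null(w), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cell regression of centromere intensity on nuclear EdU intensity
#'
#' Ordinary least squares of the per-cell background-adjusted centromere
#' intensity on the per-cell mean nuclear EdU intensity, with both
#' variables normalized within each replicate (divided by their replicate
#' mean) by default, matching how such scatter plots pool replicates.
#'
#' @param cell_records Data frame with `mean_target_adjusted`,
#'   `mean_nuclear_edu` and (if normalizing) `replicate`.
#' @param normalize_within_replicate Logical (default `TRUE`).
#' @return A list of class `edu_regression`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
intensity_edu_regression <- function(cell_records,
                                     normalize_within_replicate = TRUE) {
  d <- cell_records[is.finite(cell_records$mean_target_adjusted) &
                      is.finite(cell_records$mean_nuclear_edu), ,
                    drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 cells with both measurements (got ",
         nrow(d), ")")
  y <- d$mean_target_adjusted
  x <- d$mean_nuclear_edu
  if (normalize_within_replicate) {
    for (r in unique(d$replicate)) {
      i <- d$replicate == r
      y[i] <- y[i] / mean(y[i])
      x[i] <- x[i] / mean(x[i])
    }
  }
  if (stats::var(x) == 0) stop("zero variance in the EdU predictor")
  if (stats::var(y) == 0) stop("zero variance in the intensity response")
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = nrow(d)), class = "edu_regression")
}
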