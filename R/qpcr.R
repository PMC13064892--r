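#' Housekeeping-normalized Ct values per sample
#'
#' Technical replicates are averaged on the cycle (Ct) scale per
#' (gene, sample); the sample's delta Ct for a gene is then the gene's
#' mean Ct minus the housekeeping gene's mean Ct. Any per-sample additive
#' Ct offset (e.g. input amount) cancels in this difference.
#'
#' @param records Ct table with columns `gene`, `sample_id`, `ct`, and
#'   the design columns `condition`, `timepoint_h`, `bio_rep` (carried
#'   through).
#' @param housekeeping_gene Reference gene name (default `"GAPDH"`).
#' @return Data frame with one row per (gene, sample): `gene`,
#'   `sample_id`, `condition`, `timepoint_h`, `bio_rep`, `mean_ct`,
#'   `delta_ct`. The housekeeping gene is retained with `delta_ct` 0.
#' @export
delta_ct <- function(records, housekeeping_gene = "GAPDH") {
  stopifnot(all(c("gene", "sample_id", "ct") %in% names(records)))
  if (!housekeeping_gene %in% records$gene)
    stop("housekeeping gene '", housekeeping_gene,
         "' absent from the Ct table")
  keys <- c("gene", "sample_id",
            intersect(c("condition", "timepoint_h", "bio_rep"),
                      names(records)))
  sp <- split(records, records[, c("gene", "sample_id")], drop = TRUE)
  avg <- do.call(rbind, lapply(sp, function(d) {
    out <- d[1, keys, drop = FALSE]
    out$mean_ct <- mean(d$ct)
    out
  }))
  hk <- avg[avg$gene == housekeeping_gene, c("sample_id", "mean_ct")]
  names(hk)[2] <- "hk_ct"
  missing_hk <- setdiff(unique(avg$sample_id), hk$sample_id)
  if (length(missing_hk) > 0)
    stop("no housekeeping Ct for sample(s): ",
         paste(missing_hk, collapse = ", "))
  m <- merge(avg, hk, by = "sample_id", sort = FALSE)
  m$delta_ct <- m$mean_ct - m$hk_ct
  m <- m[order(m$gene, m$sample_id), c(keys, "mean_ct", "delta_ct")]
  rownames(m) <- NULL
  m
}

#' Fold change between two conditions by the 2^-ddCt method
#'
#' For each gene and biological replicate, the delta-delta Ct is the test
#' sample's delta Ct minus the matching reference sample's delta Ct, and
#' the fold change is `2^-ddCt` (amplification efficiency fixed at 2).
#' Per-replicate fold changes are computed before summarizing as mean and
#' SD across biological replicates.
#'
#' @param dct Output of [delta_ct()].
#' @param test_condition,reference_condition Condition labels to compare.
#' @param timepoint Optional timepoint (hours) to restrict to; default
#'   uses all rows (suitable when the design has a single timepoint).
#' @return Data frame of class `fold_change_table`: `gene`,
#'   `comparison`, `fold_change` (mean across bio reps), `sd`, `n_reps`,
#'   plus a `per_rep` attribute with the per-replicate values.
#' @export
fold_change <- function(dct, test_condition, reference_condition,
                        timepoint = NULL) {
  if (!is.null(timepoint))
    dct <- dct[dct$timepoint_h == timepoint, , drop = FALSE]
  genes <- setdiff(unique(dct$gene), character(0))
  per_rep <- list()
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- dct[dct$gene == genes[i], , drop = FALSE]
    te <- g[g$condition == test_condition, c("bio_rep", "delta_ct")]
    re <- g[g$condition == reference_condition, c("bio_rep", "delta_ct")]
    if (nrow(te) == 0 || nrow(re) == 0)
      stop("condition missing for gene ", genes[i])
    m <- merge(te, re, by = "bio_rep", suffixes = c("_test", "_ref"))
    fc <- 2^-(m$delta_ct_test - m$delta_ct_ref)
    per_rep[[genes[i]]] <- data.frame(gene = genes[i],
                                      bio_rep = m$bio_rep,
                                      fold_change = fc)
    out[[i]] <- data.frame(
      gene = genes[i],
      comparison = paste(test_condition, "vs", reference_condition),
      fold_change = mean(fc), sd = stats::sd(fc), n_reps = length(fc),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "per_rep") <- do.call(rbind, per_rep)
  class(res) <- c("fold_change_table", "data.frame")
  res
}

#' Transcription-shutoff decay course as fold change vs 0 h
#'
#' Within each condition, the fold change at every timepoint is computed
#' against the same condition's untreated (0 h) samples via the 2^-ddCt
#' method, per biological replicate then summarized as mean and SD.
#' Optionally a log-linear fit of the per-replicate fold changes against
#' time estimates a first-order decay rate and half-life per
#' (gene, condition) — an extension beyond plotted fold changes.
#'
#' @param records Raw Ct table (see [delta_ct()]) with a `timepoint_h`
#'   column including 0 for every condition.
#' @param housekeeping_gene Reference gene.
#' @param fit_half_life Logical; add a decay-rate fit.
#' @return A list with `folds` (gene, condition, timepoint_h,
#'   fold_change, sd, n_reps) and, when fitted, `half_life` (gene,
#'   condition, decay_rate_per_h, half_life_h).
#' @export
decay_course <- function(records, housekeeping_gene = "GAPDH",
                         fit_half_life = FALSE) {
  dct <- delta_ct(records, housekeeping_gene)
  genes <- setdiff(unique(dct$gene), housekeeping_gene)
  conds <- unique(dct$condition)
  tps <- sort(unique(dct$timepoint_h))
  if (!0 %in% tps) stop("decay course requires a 0 h timepoint")

  folds <- list(); fits <- list()
  for (g in genes) for (cn in conds) {
    d <- dct[dct$gene == g & dct$condition == cn, , drop = FALSE]
    base <- d[d$timepoint_h == 0, c("bio_rep", "delta_ct")]
    if (nrow(base) == 0)
      stop("missing 0 h samples for gene ", g, ", condition ", cn)
    rep_rows <- list()
    for (tp in tps) {
      dt <- d[d$timepoint_h == tp, c("bio_rep", "delta_ct")]
      m <- merge(dt, base, by = "bio_rep", suffixes = c("", "_0"))
      fc <- 2^-(m$delta_ct - m$delta_ct_0)
      folds[[length(folds) + 1L]] <- data.frame(
        gene = g, condition = cn, timepoint_h = tp,
        fold_change = mean(fc), sd = stats::sd(fc), n_reps = length(fc),
        stringsAsFactors = FALSE)
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(timepoint_h = tp, fold = fc)
    }
    if (fit_half_life) {
      pr <- do.call(rbind, rep_rows)
      pr <- pr[pr$fold > 0, , drop = FALSE]
      fit <- stats::lm(log(fold) ~ timepoint_h, data = pr)
      k <- -unname(stats::coef(fit)[2])
      fits[[length(fits) + 1L]] <- data.frame(
        gene = g, condition = cn, decay_rate_per_h = k,
        half_life_h = if (k > 0) log(2) / k else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(folds = do.call(rbind, folds))
  if (fit_half_life) out$half_life <- do.call(rbind, fits)
  out
}
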