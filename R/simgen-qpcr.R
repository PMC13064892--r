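#' Configuration for a simulated qPCR Ct table
#'
#' Emulates a housekeeping-normalized qPCR experiment comparing two
#' conditions and, optionally, a transcription-shutoff (actinomycin D)
#' time course. Relative mRNA abundance for a gene is its condition fold
#' change times `exp(-k * t)` decay after shutoff; the housekeeping gene
#' has fold change 1 and decay 0 by construction. The well Ct is
#' `base_ct - log2(abundance) + sample offset + noise`, where the
#' per-sample offset (shared by all genes of a biological sample, e.g.
#' input amount) is cancelled by housekeeping normalization, and technical
#' replicates share the biological sample's abundance.
#'
#' @param genes Character vector of gene names (must include
#'   `housekeeping_gene`).
#' @param housekeeping_gene Reference gene (default `"GAPDH"`).
#' @param true_fold_changes Named ratios (> 0), test vs reference
#'   condition, for non-housekeeping genes; genes not named get 1.
#' @param decay_rates Named per-hour decay rates (>= 0) after
#'   transcription shutoff; genes not named get 0.
#' @param timepoints Hours after shutoff (must include 0 for a decay
#'   course; `0` alone gives a plain two-condition comparison).
#' @param conditions Length-2 character: reference then test condition.
#' @param base_ct Named baseline Ct per gene; genes not named get 24.
#' @param n_bio_reps,n_tech_reps Replicate counts (>= 1).
#' @param ct_noise_sd Per-well Gaussian Ct noise, cycles.
#' @param sample_offset_sd Sd of the per-sample additive Ct offset, cycles.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `ct_config`.
#' @export
ct_config <- function(genes = c("CENPT", "CENPC", "GAPDH"),
                      housekeeping_gene = "GAPDH",
                      true_fold_changes = c(CENPT = 0.7, CENPC = 2.0),
                      decay_rates = c(CENPT = log(2) / 4,
                                      CENPC = log(2) / 6),
                      timepoints = 0,
                      conditions = c("cycling", "quiescent"),
                      base_ct = c(GAPDH = 20),
                      n_bio_reps = 3, n_tech_reps = 3,
                      ct_noise_sd = 0.15, sample_offset_sd = 0.3,
                      seed = NULL) {
  if (!housekeeping_gene %in% genes)
    stop("housekeeping gene '", housekeeping_gene,
         "' is not in the gene list")
  stopifnot(all(true_fold_changes > 0), all(decay_rates >= 0),
            n_bio_reps >= 1, n_tech_reps >= 1, ct_noise_sd >= 0,
            sample_offset_sd >= 0, length(conditions) == 2,
            all(timepoints >= 0))
  fc <- stats::setNames(rep(1, length(genes)), genes)
  fc[names(true_fold_changes)[names(true_fold_changes) %in% genes]] <-
    true_fold_changes[names(true_fold_changes) %in% genes]
  k <- stats::setNames(rep(0, length(genes)), genes)
  k[names(decay_rates)[names(decay_rates) %in% genes]] <-
    decay_rates[names(decay_rates) %in% genes]
  fc[housekeeping_gene] <- 1
  k[housekeeping_gene] <- 0
  bc <- stats::setNames(rep(24, length(genes)), genes)
  bc[names(base_ct)[names(base_ct) %in% genes]] <-
    base_ct[names(base_ct) %in% genes]
  cfg <- list(genes = genes, housekeeping_gene = housekeeping_gene,
              true_fold_changes = fc, decay_rates = k,
              timepoints = sort(unique(timepoints)),
              conditions = conditions, base_ct = bc,
              n_bio_reps = as.integer(n_bio_reps),
              n_tech_reps = as.integer(n_tech_reps),
              ct_noise_sd = ct_noise_sd,
              sample_offset_sd = sample_offset_sd,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "ct_config"
  cfg
}

#' Simulate a qPCR Ct table with known ground truth
#'
#' @param config A [ct_config()].
#' @return A data frame with columns `gene`, `sample_id`, `condition`,
#'   `timepoint_h`, `bio_rep`, `tech_rep`, `ct`, with attributes
#'   `true_fold_changes` and `decay_rates`.
#' @export
generate_ct_table <- function(config) {
  stopifnot(inherits(config, "ct_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ref <- config$conditions[1]
  grid <- expand.grid(condition = config$conditions,
                      timepoint_h = config$timepoints,
                      bio_rep = seq_len(config$n_bio_reps),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sample_id <- sprintf("%s_t%g_b%d", g$condition, g$timepoint_h,
                         g$bio_rep)
    offset <- if (config$sample_offset_sd > 0)
      stats::rnorm(1, 0, config$sample_offset_sd) else 0
    fc <- if (g$condition == ref)
      stats::setNames(rep(1, length(config$genes)), config$genes)
    else config$true_fold_changes
    abundance <- fc * exp(-config$decay_rates * g$timepoint_h)
    ct0 <- config$base_ct - log2(abundance) + offset
    n_g <- length(config$genes)
    noise <- if (config$ct_noise_sd > 0)
      stats::rnorm(n_g * config$n_tech_reps, 0, config$ct_noise_sd) else 0
    rows[[i]] <- data.frame(
      gene = rep(config$genes, each = config$n_tech_reps),
      sample_id = sample_id,
      condition = g$condition, timepoint_h = g$timepoint_h,
      bio_rep = g$bio_rep,
      tech_rep = rep(seq_len(config$n_tech_reps), n_g),
      ct = rep(ct0, each = config$n_tech_reps) + noise,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_fold_changes") <- config$true_fold_changes
  attr(out, "decay_rates") <- config$decay_rates
  out
}
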