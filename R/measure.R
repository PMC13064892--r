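## Integer pixel offsets for a disk and an annulus (0-based distances
## measured between pixel centres).
ring_offsets <- function(rmin, rmax) {
  h <- ceiling(rmax)
  d <- expand.grid(dr = -h:h, dc = -h:h)
  dist <- sqrt(d$dr^2 + d$dc^2)
  d[dist >= rmin & dist <= rmax, , drop = FALSE]
}

#' Measure background-adjusted target intensity at detected foci
#'
#' For each focus, the adjusted intensity is the mean target intensity in
#' a disk of `disk_radius` pixels around the focus minus the median
#' intensity of an annulus of radii `[annulus_inner, annulus_outer]`
#' restricted to the focus's own nucleus (local background). Negative
#' adjusted values are retained so that condition means near zero stay
#' unbiased. A focus whose annulus has no in-nucleus pixels is flagged
#' and excluded from per-cell means.
#'
#' @param target_image Numeric matrix, projected target channel.
#' @param foci A `focus_table` from [detect_foci()].
#' @param nuclei The `nucleus_label_map` the foci were assigned to.
#' @param disk_radius Measurement disk radius, pixels.
#' @param annulus_inner,annulus_outer Background annulus radii, pixels;
#'   `annulus_outer > annulus_inner >= disk_radius` is required.
#' @param background One of `"annulus"` (default) or `"nucleus"`: local
#'   annulus median, or the median over the whole nucleus mask.
#' @param exclude_neighbors Logical (default `TRUE`): pixels within
#'   `disk_radius` of any other detected focus are excluded from the
#'   background estimate, so that crowded neighbouring centromeres do
#'   not inflate the local background.
#' @return `foci` with added columns `target_adjusted`,
#'   `local_background`, `flagged`.
#' @export
measure_foci <- function(target_image, foci, nuclei,
                         disk_radius = 3, annulus_inner = 4,
                         annulus_outer = 7,
                         background = c("annulus", "nucleus"),
                         exclude_neighbors = TRUE) {
  background <- match.arg(background)
  stopifnot(is.matrix(target_image),
            annulus_outer > annulus_inner, annulus_inner >= disk_radius)
  n <- nrow(foci)
  foci$target_adjusted <- numeric(n)
  foci$local_background <- numeric(n)
  foci$flagged <- logical(n)
  if (n == 0) return(foci)

  disk <- ring_offsets(0, disk_radius)
  ann <- ring_offsets(annulus_inner, annulus_outer)
  nr <- nrow(target_image); nc <- ncol(target_image)
  L <- nuclei$labels

  ## mask of pixels occupied by any focus footprint
  spot_mask <- matrix(FALSE, nr, nc)
  if (exclude_neighbors) {
    for (f in seq_len(n)) {
      di <- round(foci$row[f]) + 1L + disk$dr
      dj <- round(foci$col[f]) + 1L + disk$dc
      ok <- di >= 1L & di <= nr & dj >= 1L & dj <= nc
      spot_mask[cbind(di[ok], dj[ok])] <- TRUE
    }
  }

  nuc_median <- NULL
  if (background == "nucleus") {
    nuc_median <- vapply(seq_len(nuclei$n_nuclei), function(k)
      stats::median(target_image[L == k & !spot_mask]), numeric(1))
  }

  for (f in seq_len(n)) {
    ci <- round(foci$row[f]) + 1L   # to 1-based pixel index
    cj <- round(foci$col[f]) + 1L
    di <- ci + disk$dr; dj <- cj + disk$dc
    ok <- di >= 1L & di <= nr & dj >= 1L & dj <= nc
    disk_vals <- target_image[cbind(di[ok], dj[ok])]

    if (background == "annulus") {
      ai <- ci + ann$dr; aj <- cj + ann$dc
      aok <- ai >= 1L & ai <= nr & aj >= 1L & aj <= nc
      aidx <- cbind(ai[aok], aj[aok])
      use <- L[aidx] == foci$nucleus_id[f]
      if (exclude_neighbors) use <- use & !spot_mask[aidx]
      bg_vals <- target_image[aidx[use, , drop = FALSE]]
    } else {
      bg_vals <- nuc_median[foci$nucleus_id[f]]
    }

    if (length(bg_vals) == 0 || length(disk_vals) == 0) {
      foci$flagged[f] <- TRUE
      foci$target_adjusted[f] <- NA_real_
      foci$local_background[f] <- NA_real_
    } else {
      bg <- stats::median(bg_vals)
      foci$local_background[f] <- bg
      foci$target_adjusted[f] <- mean(disk_vals) - bg
    }
  }
  foci
}

#' Summarize measured foci into per-cell records
#'
#' One record per segmented nucleus: focus count, arithmetic mean of the
#' background-adjusted target intensity over the cell's unflagged foci
#' (missing, not 0, for cells with no usable focus), and, when an EdU
#' channel is supplied, the mean raw EdU intensity over the nucleus mask.
#'
#' @param foci Output of [measure_foci()].
#' @param nuclei The `nucleus_label_map`.
#' @param edu_image Optional numeric matrix, projected EdU channel.
#' @param field_id,condition,replicate Labels copied onto every record.
#' @return A data frame (class `cell_table`) with columns `field_id`,
#'   `nucleus_id`, `condition`, `replicate`, `n_foci`,
#'   `mean_target_adjusted`, `mean_nuclear_edu`, `border_flag`.
#' @export
measure_cells <- function(foci, nuclei, edu_image = NULL,
                          field_id = NA_character_,
                          condition = NA_character_, replicate = NA) {
  n <- nuclei$n_nuclei
  n_foci <- integer(n)
  mean_adj <- rep(NA_real_, n)
  if (nrow(foci) > 0) {
    usable <- foci[!foci$flagged & !is.na(foci$target_adjusted), ,
                   drop = FALSE]
    cnt <- table(factor(foci$nucleus_id, levels = seq_len(n)))
    n_foci <- as.integer(cnt)
    if (nrow(usable) > 0) {
      agg <- tapply(usable$target_adjusted,
                    factor(usable$nucleus_id, levels = seq_len(n)), mean)
      mean_adj <- as.numeric(agg)
    }
  }
  mean_edu <- rep(NA_real_, n)
  if (!is.null(edu_image)) {
    stopifnot(all(dim(edu_image) == dim(nuclei$labels)))
    lab <- nuclei$labels
    sel <- lab > 0L
    if (any(sel)) {
      sums <- tapply(edu_image[sel], lab[sel], mean)
      mean_edu[as.integer(names(sums))] <- as.numeric(sums)
    }
  }
  out <- data.frame(
    field_id = rep(field_id, n),
    nucleus_id = seq_len(n),
    condition = rep(condition, n),
    replicate = rep(replicate, n),
    n_foci = n_foci,
    mean_target_adjusted = mean_adj,
    mean_nuclear_edu = mean_edu,
    border_flag = rep(FALSE, n),
    stringsAsFactors = FALSE)
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Quantify one field end to end
#'
#' Convenience wrapper: maximum projection, nuclear segmentation on the
#' DNA channel, focus detection on the reference channel, target
#' measurement at the detected foci, and per-cell summaries (including
#' mean nuclear EdU when the field has an EdU channel).
#'
#' @param field An `image_field`.
#' @param segment,detect,measure Named lists of parameter overrides for
#'   [segment_nuclei()], [detect_foci()] and [measure_foci()].
#' @return A list with `cells`, `foci`, `nuclei`.
#' @export
quantify_field <- function(field, segment = list(), detect = list(),
                           measure = list()) {
  proj <- if (field$n_z > 1L) max_project(field) else field
  dna <- get_channel(proj, "dna")
  nuc <- do.call(segment_nuclei, c(list(dna_image = dna), segment))
  ref <- get_channel(proj, "reference")
  foci <- do.call(detect_foci,
                  c(list(ref_image = ref, nuclei = nuc), detect))
  tgt <- get_channel(proj, "target")
  foci <- do.call(measure_foci,
                  c(list(target_image = tgt, foci = foci, nuclei = nuc),
                    measure))
  edu <- if ("edu" %in% proj$channel_roles) get_channel(proj, "edu")
  cells <- measure_cells(foci, nuc, edu_image = edu,
                         field_id = proj$field_id,
                         condition = proj$condition,
                         replicate = proj$replicate)
  if (nrow(foci) > 0) {
    foci$field_id <- proj$field_id
    foci$condition <- proj$condition
    foci$replicate <- proj$replicate
  }
  list(cells = cells, foci = foci, nuclei = nuc)
}
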