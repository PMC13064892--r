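#' Configuration for a simulated fluorescence field
#'
#' Describes one synthetic field of view emulating a fixed-cell
#' immunofluorescence experiment: disk-shaped interphase nuclei in the DNA
#' channel, diffraction-limited centromere foci rendered as isotropic
#' Gaussian spots in the reference (ACA) and target channels, an optional
#' EdU channel filled uniformly inside each nucleus, a linear background
#' ramp, and Poisson photon noise plus Gaussian camera read noise.
#'
#' Intensities are in photon units before noise. Foci are placed by
#' rejection sampling with a minimum pairwise separation of
#' `4 * spot_sigma` inside a concentric disk of radius
#' `foci_region_fraction * nucleus_radius`, keeping neighbouring spots
#' resolvable by default.
#'
#' @param image_height,image_width Field size in pixels.
#' @param n_cells Number of nuclei to place (may be 0).
#' @param nucleus_radius_range Length-2 numeric, min and max nucleus radius
#'   in pixels.
#' @param foci_per_nucleus Number of centromere foci per nucleus. The
#'   default 46 is the karyotypic expectation for a diploid human cell, not
#'   an empirical claim about resolvable foci.
#' @param spot_sigma Gaussian spot width (sd) in pixels.
#' @param channel_amplitudes Named numeric with entries `dna`, `reference`,
#'   `target`: peak photon amplitudes. The target amplitude is further
#'   scaled by `target_multiplier` in [generate_field()].
#' @param background_level Uniform background, photons.
#' @param background_gradient Linear ramp coefficient, photons per pixel
#'   along the column axis.
#' @param read_noise_sd Gaussian read noise sd, intensity units (0 disables).
#' @param poisson_noise Logical; apply per-pixel Poisson noise to the
#'   expected photon count.
#' @param edu_positive_fraction Probability that a cell is EdU-positive
#'   (has passed through S phase during labelling).
#' @param edu_component_params List with elements `negative` and `positive`,
#'   each `c(meanlog, sdlog)`: parameters of the lognormal nuclear EdU
#'   intensity for each class (Gaussian on log intensity).
#' @param foci_region_fraction Fraction of the nucleus radius within which
#'   foci are placed.
#' @param n_z Number of z planes (>= 1); spots are rendered on the middle
#'   plane so that maximum-intensity projection is exercised.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `field_config`.
#' @seealso [generate_field()], [generate_condition_set()]
#' @export
field_config <- function(image_height = 448, image_width = 448,
                         n_cells = 12,
                         nucleus_radius_range = c(21, 25),
                         foci_per_nucleus = 46,
                         spot_sigma = 1.0,
                         channel_amplitudes = c(dna = 400, reference = 600,
                                                target = 600),
                         background_level = 100,
                         background_gradient = 0.02,
                         read_noise_sd = 3,
                         poisson_noise = TRUE,
                         edu_positive_fraction = 0.95,
                         edu_component_params = list(
                           negative = c(meanlog = log(50),  sdlog = 0.35),
                           positive = c(meanlog = log(500), sdlog = 0.35)),
                         foci_region_fraction = 0.9,
                         n_z = 3,
                         seed = NULL) {
  stopifnot(image_height >= 8, image_width >= 8,
            n_cells >= 0, foci_per_nucleus >= 0,
            length(nucleus_radius_range) == 2,
            nucleus_radius_range[1] > 0,
            nucleus_radius_range[2] >= nucleus_radius_range[1],
            spot_sigma > 0,
            all(channel_amplitudes >= 0),
            all(c("dna", "reference", "target") %in%
                  names(channel_amplitudes)),
            background_level >= 0, read_noise_sd >= 0,
            edu_positive_fraction >= 0, edu_positive_fraction <= 1,
            foci_region_fraction > 0, foci_region_fraction <= 1,
            n_z >= 1)
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              n_cells = as.integer(n_cells),
              nucleus_radius_range = as.numeric(nucleus_radius_range),
              foci_per_nucleus = as.integer(foci_per_nucleus),
              spot_sigma = spot_sigma,
              channel_amplitudes = channel_amplitudes,
              background_level = background_level,
              background_gradient = background_gradient,
              read_noise_sd = read_noise_sd,
              poisson_noise = poisson_noise,
              edu_positive_fraction = edu_positive_fraction,
              edu_component_params = edu_component_params,
              foci_region_fraction = foci_region_fraction,
              n_z = as.integer(n_z),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "field_config"
  cfg
}

## Place n disk centres so that disks (radius + margin) do not overlap.
## Returns data.frame(row, col, radius) in 0-based pixel coordinates.
place_nuclei <- function(cfg, margin = 4) {
  n <- cfg$n_cells
  out <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  if (n == 0L) return(out)
  max_attempts <- 400L * n
  attempts <- 0L
  rows <- cols <- radii <- numeric(0)
  while (length(rows) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- stats::runif(1, cfg$nucleus_radius_range[1],
                      cfg$nucleus_radius_range[2])
    cr <- stats::runif(1, r + 2, cfg$image_height - 1 - r - 2)
    cc <- stats::runif(1, r + 2, cfg$image_width - 1 - r - 2)
    ok <- TRUE
    if (length(rows) > 0) {
      d <- sqrt((rows - cr)^2 + (cols - cc)^2)
      ok <- all(d >= radii + r + margin)
    }
    if (ok) {
      rows <- c(rows, cr); cols <- c(cols, cc); radii <- c(radii, r)
    }
  }
  if (length(rows) < n)
    stop("could not place ", n, " non-overlapping nuclei of radius ",
         cfg$nucleus_radius_range[1], "-", cfg$nucleus_radius_range[2],
         " in a ", cfg$image_height, "x", cfg$image_width,
         " field after ", max_attempts, " attempts")
  data.frame(row = rows, col = cols, radius = radii)
}

## Rejection-sample n points in a disk with minimum pairwise separation.
place_foci_in_disk <- function(n, center_row, center_col, region_radius,
                               min_sep, max_attempts = 400L * max(n, 1L)) {
  if (n == 0L)
    return(data.frame(row = numeric(0), col = numeric(0)))
  rows <- cols <- numeric(0)
  attempts <- 0L
  while (length(rows) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    rad <- region_radius * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    pr <- center_row + rad * sin(th)
    pc <- center_col + rad * cos(th)
    if (length(rows) == 0 ||
        min((rows - pr)^2 + (cols - pc)^2) >= min_sep^2) {
      rows <- c(rows, pr); cols <- c(cols, pc)
    }
  }
  if (length(rows) < n)
    stop("could not place ", n, " foci with separation ", min_sep,
         " px in a disk of radius ", round(region_radius, 1),
         " px; enlarge the nucleus or reduce foci_per_nucleus")
  data.frame(row = rows, col = cols)
}

## Add isotropic Gaussian spots to a plane (matrix, 1-based indexing;
## positions 0-based). Evaluated at pixel centres on a local patch.
render_spots <- function(plane, rows, cols, amps, sigma) {
  if (length(rows) == 0) return(plane)
  half <- ceiling(4 * sigma) + 1L
  nr <- nrow(plane); nc <- ncol(plane)
  for (k in seq_along(rows)) {
    i0 <- max(1L, floor(rows[k]) + 1L - half)
    i1 <- min(nr, floor(rows[k]) + 1L + half)
    j0 <- max(1L, floor(cols[k]) + 1L - half)
    j1 <- min(nc, floor(cols[k]) + 1L + half)
    ii <- i0:i1; jj <- j0:j1
    dr <- (ii - 1L) - rows[k]
    dc <- (jj - 1L) - cols[k]
    g <- exp(-dr^2 / (2 * sigma^2)) %o% exp(-dc^2 / (2 * sigma^2))
    plane[ii, jj] <- plane[ii, jj] + amps[k] * g
  }
  plane
}

## Pixel-centre disk mask for a nucleus, as a logical matrix section.
disk_mask_indices <- function(center_row, center_col, radius, nr, nc) {
  i0 <- max(1L, floor(center_row - radius) + 1L)
  i1 <- min(nr, ceiling(center_row + radius) + 1L)
  j0 <- max(1L, floor(center_col - radius) + 1L)
  j1 <- min(nc, ceiling(center_col + radius) + 1L)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer(((ii - 1L) - center_row)^2, ((jj - 1L) - center_col)^2, "+")
  list(ii = ii, jj = jj, inside = d2 <= radius^2)
}

#' Simulate one multi-channel fluorescence field with ground truth
#'
#' Renders the field described by a [field_config()]: DNA-channel disks for
#' nuclei (present on every z plane), Gaussian centromere spots on the
#' middle z plane of the reference and target channels, and a uniform EdU
#' fill inside each nucleus. A linear background ramp is added to every
#' channel, then per-pixel Poisson noise and additive Gaussian read noise.
#' Identical config and seed give bit-identical output.
#'
#' @param config A [field_config()].
#' @param condition,replicate,field_id Labels attached to the field.
#' @param target_multiplier Scales the target-channel spot amplitude, e.g.
#'   1.0 for cycling cells and 0.25 for the quiescent CENP-C plateau.
#' @param edu Logical; include an EdU channel.
#' @return A list with elements `field` (an `image_field`: `pixels` array
#'   indexed `[channel, z, row, col]`, `channel_roles`, labels) and `truth`
#'   (a `sim_truth`: `cells` and `foci` data frames with 0-based positions,
#'   true amplitudes, EdU classes and means).
#' @export
generate_field <- function(config, condition = "cycling", replicate = 1L,
                           target_multiplier = 1, field_id = "field_01",
                           edu = TRUE) {
  stopifnot(inherits(config, "field_config"), target_multiplier >= 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  nr <- config$image_height; nc <- config$image_width
  nz <- config$n_z
  spot_z <- (nz + 1L) %/% 2L

  nuclei <- place_nuclei(config)
  n <- nrow(nuclei)

  ## per-cell EdU class and mean nuclear intensity (lognormal per class)
  if (n > 0) {
    edu_class <- ifelse(stats::runif(n) < config$edu_positive_fraction,
                        "positive", "negative")
    p <- config$edu_component_params
    edu_mean <- vapply(edu_class, function(cl)
      stats::rlnorm(1, p[[cl]][["meanlog"]], p[[cl]][["sdlog"]]),
      numeric(1), USE.NAMES = FALSE)
  } else {
    edu_class <- character(0); edu_mean <- numeric(0)
  }

  ## foci positions and true amplitudes
  amp <- config$channel_amplitudes
  foci_list <- vector("list", n)
  for (k in seq_len(n)) {
    f <- place_foci_in_disk(config$foci_per_nucleus,
                            nuclei$row[k], nuclei$col[k],
                            config$foci_region_fraction * nuclei$radius[k],
                            4 * config$spot_sigma)
    if (nrow(f) > 0) {
      f$cell_id <- k
      f$amp_reference <- rep(amp[["reference"]], nrow(f))
      f$amp_target <- rep(amp[["target"]] * target_multiplier, nrow(f))
    }
    foci_list[[k]] <- f
  }
  foci <- if (n > 0) do.call(rbind, foci_list) else
    data.frame(row = numeric(0), col = numeric(0), cell_id = integer(0),
               amp_reference = numeric(0), amp_target = numeric(0))

  roles <- c("dna", "reference", "target", if (edu) "edu")
  pix <- array(0, dim = c(length(roles), nz, nr, nc))

  ## background ramp (same for every channel and plane)
  bg <- matrix(config$background_level, nr, nc) +
    config$background_gradient *
    matrix(0:(nc - 1L), nr, nc, byrow = TRUE)

  dna_plane <- matrix(0, nr, nc)
  edu_plane <- matrix(0, nr, nc)
  for (k in seq_len(n)) {
    m <- disk_mask_indices(nuclei$row[k], nuclei$col[k], nuclei$radius[k],
                           nr, nc)
    dna_plane[m$ii, m$jj][m$inside] <-
      dna_plane[m$ii, m$jj][m$inside] + amp[["dna"]]
    edu_plane[m$ii, m$jj][m$inside] <-
      edu_plane[m$ii, m$jj][m$inside] + edu_mean[k]
  }
  ref_spot <- render_spots(matrix(0, nr, nc), foci$row, foci$col,
                           foci$amp_reference, config$spot_sigma)
  tgt_spot <- render_spots(matrix(0, nr, nc), foci$row, foci$col,
                           foci$amp_target, config$spot_sigma)

  for (z in seq_len(nz)) {
    pix[1, z, , ] <- dna_plane + bg
    pix[2, z, , ] <- bg + if (z == spot_z) ref_spot else 0
    pix[3, z, , ] <- bg + if (z == spot_z) tgt_spot else 0
    if (edu) pix[4, z, , ] <- edu_plane + bg
  }

  if (config$poisson_noise)
    pix[] <- stats::rpois(length(pix), lambda = pix)
  if (config$read_noise_sd > 0)
    pix[] <- pix + stats::rnorm(length(pix), 0, config$read_noise_sd)

  field <- structure(
    list(pixels = pix, channel_roles = roles, n_z = nz,
         condition = condition, replicate = replicate, field_id = field_id),
    class = "image_field")

  cells <- data.frame(
    field_id = rep(field_id, n),
    cell_id = seq_len(n),
    center_row = nuclei$row, center_col = nuclei$col,
    radius = nuclei$radius,
    edu_class = edu_class, edu_mean = edu_mean,
    condition = rep(condition, n), replicate = rep(replicate, n),
    stringsAsFactors = FALSE)
  if (nrow(foci) > 0) {
    foci$field_id <- field_id
    foci <- foci[, c("field_id", "cell_id", "row", "col",
                     "amp_reference", "amp_target")]
  } else {
    foci <- data.frame(field_id = character(0), cell_id = integer(0),
                       row = numeric(0), col = numeric(0),
                       amp_reference = numeric(0), amp_target = numeric(0))
  }
  truth <- structure(list(cells = cells, foci = foci,
                          target_multiplier = target_multiplier),
                     class = "sim_truth")
  list(field = field, truth = truth)
}

#' Draw a population of per-cell mean nuclear EdU intensities
#'
#' Samples the same generative EdU model used inside [generate_field()]
#' (a two-class lognormal mixture: Gaussian components on log intensity)
#' without rendering images, for testing and calibrating the EdU gate at
#' large n.
#'
#' @param n Number of cells.
#' @param edu_positive_fraction Probability of the positive class.
#' @param edu_component_params As in [field_config()].
#' @param seed Integer seed or `NULL`.
#' @return Data frame with `edu_mean` and the true `edu_class`.
#' @export
generate_edu_population <- function(n,
                                    edu_positive_fraction = 0.95,
                                    edu_component_params =
                                      field_config()$edu_component_params,
                                    seed = NULL) {
  stopifnot(n >= 1, edu_positive_fraction >= 0,
            edu_positive_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  cl <- ifelse(stats::runif(n) < edu_positive_fraction,
               "positive", "negative")
  v <- vapply(cl, function(c1)
    stats::rlnorm(1, edu_component_params[[c1]][["meanlog"]],
                  edu_component_params[[c1]][["sdlog"]]),
    numeric(1), USE.NAMES = FALSE)
  data.frame(edu_mean = v, edu_class = cl, stringsAsFactors = FALSE)
}

#' Simulate a multi-condition, multi-replicate experiment
#'
#' Generates labelled fields for each condition and biological replicate.
#' Each condition scales the target-channel spot amplitude by its
#' multiplier (e.g. cycling 1.0 vs quiescent 0.25). Each replicate draws
#' one multiplicative staining-efficiency factor shared across its
#' conditions, emulating day-to-day immunofluorescence variability, so
#' that per-replicate normalization and superplot statistics are
#' exercised.
#'
#' @param config A [field_config()] used for every field; its `seed` (if
#'   any) is ignored in favour of `seed`.
#' @param conditions Named numeric vector of target-amplitude multipliers
#'   (all >= 0), e.g. `c(cycling = 1, quiescent = 0.25)`.
#' @param n_fields_per_condition Fields per condition per replicate.
#' @param n_replicates Biological replicates.
#' @param replicate_effect_sd Sd of the per-replicate multiplicative
#'   effect around 1.
#' @param edu Logical; include an EdU channel in every field.
#' @param edu_positive_fractions Optional named vector giving the
#'   EdU-positive fraction per condition (e.g. `c(cycling = 0.95,
#'   quiescent = 0.002)` for a 48-h labelling window); conditions not
#'   named fall back to the config's `edu_positive_fraction`.
#' @param seed Integer seed for the whole set.
#' @return A list of `list(field =, truth =)` entries, with attribute
#'   `replicate_factors` holding the drawn per-replicate effects.
#' @export
generate_condition_set <- function(config,
                                   conditions = c(cycling = 1,
                                                  quiescent = 0.25),
                                   n_fields_per_condition = 3,
                                   n_replicates = 3,
                                   replicate_effect_sd = 0.05,
                                   edu = TRUE,
                                   edu_positive_fractions = NULL,
                                   seed = 1L) {
  stopifnot(inherits(config, "field_config"))
  if (length(conditions) == 0 || is.null(names(conditions)) ||
      any(!nzchar(names(conditions))))
    stop("'conditions' must be a non-empty named vector of multipliers")
  if (any(conditions < 0)) stop("condition multipliers must be >= 0")
  set.seed(as.integer(seed))
  rep_factor <- stats::rnorm(n_replicates, mean = 1,
                             sd = replicate_effect_sd)
  n_total <- length(conditions) * n_fields_per_condition * n_replicates
  child_seeds <- sample.int(.Machine$integer.max, n_total)

  out <- vector("list", n_total)
  idx <- 0L
  for (r in seq_len(n_replicates)) {
    for (ci in seq_along(conditions)) {
      for (fi in seq_len(n_fields_per_condition)) {
        idx <- idx + 1L
        cfg <- config
        cfg$seed <- child_seeds[idx]
        cond_name <- names(conditions)[ci]
        if (!is.null(edu_positive_fractions) &&
            cond_name %in% names(edu_positive_fractions))
          cfg$edu_positive_fraction <-
            unname(edu_positive_fractions[cond_name])
        fid <- sprintf("r%02d_%s_f%02d", r, cond_name, fi)
        out[[idx]] <- generate_field(
          cfg, condition = names(conditions)[ci], replicate = r,
          target_multiplier = conditions[ci] * rep_factor[r],
          field_id = fid, edu = edu)
        out[[idx]]$truth$condition_multiplier <- unname(conditions[ci])
        out[[idx]]$truth$replicate_factor <- rep_factor[r]
      }
    }
  }
  attr(out, "replicate_factors") <- rep_factor
  out
}
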