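# Shared fixtures: small, fast field configurations used across tests.

# Small noise-free field: few cells, modest foci count, quick to render.
small_clean_cfg <- function(n_cells = 3, foci = 12, seed = 1, ...) {
  field_config(image_height = 224, image_width = 224, n_cells = n_cells,
               nucleus_radius_range = c(16, 19), foci_per_nucleus = foci,
               read_noise_sd = 0, poisson_noise = FALSE,
               background_gradient = 0, n_z = 1, seed = seed, ...)
}

# Tiny full-pipeline config (2 conditions x 2 replicates x 1 field).
tiny_run_cfg <- function(seed = 5L, ...) {
  default_run_config(
    simulate = list(
      field = list(image_height = 256, image_width = 256, n_cells = 4,
                   nucleus_radius_range = c(16, 19),
                   foci_per_nucleus = 12, n_z = 1),
      n_fields_per_condition = 1, n_replicates = 2),
    ...) -> cfg
  cfg$seed <- seed
  cfg
}

# Nucleus label map containing a single centred disk, for tests that
# need a known mask without running segmentation.
disk_label_map <- function(size, center, radius) {
  L <- matrix(0L, size, size)
  for (i in seq_len(size))
    for (j in seq_len(size))
      if ((i - 1 - center[1])^2 + (j - 1 - center[2])^2 <= radius^2)
        L[i, j] <- 1L
  structure(list(labels = L, n_nuclei = 1L, areas = sum(L)),
            class = "nucleus_label_map")
}

# Evaluate the generative spot-plus-background model at pixel centres:
# the independent oracle for rendered intensities.
spot_model_value <- function(i, j, spots, amp, sigma, background) {
  v <- background
  for (s in seq_len(nrow(spots))) {
    d2 <- (i - spots$row[s])^2 + (j - spots$col[s])^2
    v <- v + amp[s] * exp(-d2 / (2 * sigma^2))
  }
  v
}
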