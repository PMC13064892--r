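make_focus <- function(row, col, nucleus_id = 1L) {
  data.frame(row = row, col = col, nucleus_id = nucleus_id,
             response = 1, ref_intensity = 1)
}

test_that("uniform target images measure as zero adjusted intensity", {
  nuc <- disk_label_map(64, c(32, 32), 25)
  f <- make_focus(32, 32)
  m0 <- measure_foci(matrix(0, 64, 64), f, nuc)
  expect_equal(m0$target_adjusted, 0)
  mB <- measure_foci(matrix(137.5, 64, 64), f, nuc)
  expect_equal(mB$target_adjusted, 0)
  expect_equal(mB$local_background, 137.5)
})

test_that("adjusted intensity matches a quadrature oracle on the model", {
  A <- 500; sigma <- 1.5; B <- 100
  img <- matrix(B, 64, 64)
  img <- centroquant:::render_spots(img, 32, 32, A, sigma)
  nuc <- disk_label_map(64, c(32, 32), 25)
  m <- measure_foci(img, make_focus(32, 32), nuc, disk_radius = 3,
                    annulus_inner = 4, annulus_outer = 7)
  # oracle: evaluate the generative formula over disk and annulus pixels
  disk_vals <- c(); ann_vals <- c()
  for (i in 0:63) for (j in 0:63) {
    d <- sqrt((i - 32)^2 + (j - 32)^2)
    v <- B + A * exp(-d^2 / (2 * sigma^2))
    if (d <= 3) disk_vals <- c(disk_vals, v)
    if (d >= 4 & d <= 7) ann_vals <- c(ann_vals, v)
  }
  expect_equal(m$target_adjusted, mean(disk_vals) - median(ann_vals),
               tolerance = 1e-10)
})

test_that("background invariance: constant offsets cancel exactly", {
  cfg <- field_config(image_height = 256, image_width = 256, n_cells = 3,
                      nucleus_radius_range = c(21, 24),
                      foci_per_nucleus = 30, n_z = 1, seed = 31)
  sim <- generate_field(cfg)
  nuc <- segment_nuclei(get_channel(sim$field, "dna"))
  foci <- detect_foci(get_channel(sim$field, "reference"), nuc)
  tgt <- get_channel(sim$field, "target")
  for (mode in c("annulus", "nucleus")) {
    m1 <- measure_foci(tgt, foci, nuc, background = mode)
    m2 <- measure_foci(tgt + 500, foci, nuc, background = mode)
    expect_lt(max(abs(m2$target_adjusted - m1$target_adjusted) /
                    (abs(m1$target_adjusted) + 1)), 1e-9)
  }
})

test_that("adjusted intensities scale linearly with the target channel", {
  cfg <- small_clean_cfg(n_cells = 2, foci = 10, seed = 37)
  sim <- generate_field(cfg)
  nuc <- segment_nuclei(get_channel(sim$field, "dna"))
  foci <- detect_foci(get_channel(sim$field, "reference"), nuc)
  tgt <- get_channel(sim$field, "target")
  m1 <- measure_foci(tgt, foci, nuc)
  m3 <- measure_foci(tgt * 3, foci, nuc)
  expect_equal(m3$target_adjusted, 3 * m1$target_adjusted,
               tolerance = 1e-9)
  c1 <- measure_cells(m1, nuc)
  c3 <- measure_cells(m3, nuc)
  expect_equal(c3$mean_target_adjusted, 3 * c1$mean_target_adjusted,
               tolerance = 1e-9)
})

test_that("per-cell records average foci and handle empty cells", {
  nuc <- disk_label_map(64, c(32, 32), 25)
  nuc$labels[nuc$labels == 1 & row(nuc$labels) > 52] <- 0L  # unchanged id
  f <- make_focus(c(30, 32, 34), c(30, 32, 34))
  f <- measure_foci(matrix(0, 64, 64), f, nuc)
  f$target_adjusted <- c(10, 20, 30)
  cells <- measure_cells(f, nuc)
  expect_equal(cells$mean_target_adjusted, 20)
  expect_equal(cells$n_foci, 3L)
  # a cell with no usable foci keeps its record with a missing mean
  f2 <- f; f2$flagged <- TRUE
  cells2 <- measure_cells(f2, nuc)
  expect_equal(nrow(cells2), 1)
  expect_true(is.na(cells2$mean_target_adjusted))
})

test_that("per-focus adjusted intensity increases with true amplitude", {
  # same field rendered at increasing target multipliers
  cfg <- small_clean_cfg(n_cells = 1, foci = 8, seed = 41)
  means <- sapply(c(0.1, 0.5, 1, 2), function(mult) {
    sim <- generate_field(cfg, target_multiplier = mult)
    q <- quantify_field(sim$field)
    mean(q$cells$mean_target_adjusted)
  })
  expect_true(all(diff(means) > 0))
})

test_that("condition ratios are recovered from noisy fields", {
  cfg <- field_config(n_cells = 8, n_z = 1, seed = 43)
  vals <- sapply(c(1, 0.25), function(mult) {
    sim <- generate_field(cfg, target_multiplier = mult)
    q <- quantify_field(sim$field)
    mean(q$cells$mean_target_adjusted, na.rm = TRUE)
  })
  expect_lt(abs(vals[2] / vals[1] - 0.25), 0.025)  # within 10% of 0.25
})
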