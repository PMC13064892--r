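test_that("empty field is pure background and truth has zero cells", {
  cfg <- field_config(image_height = 64, image_width = 64, n_cells = 0,
                      background_gradient = 0, seed = 3, n_z = 1)
  sim <- generate_field(cfg)
  expect_equal(nrow(sim$truth$cells), 0)
  expect_equal(nrow(sim$truth$foci), 0)
  # mean near the background level under Poisson + read noise
  expect_lt(abs(mean(sim$field$pixels) - 100), 1)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- field_config(image_height = 160, image_width = 160, n_cells = 2,
                      nucleus_radius_range = c(16, 19),
                      foci_per_nucleus = 8, seed = 7, n_z = 2)
  a <- generate_field(cfg)
  b <- generate_field(cfg)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$truth$foci, b$truth$foci)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("noise-free pixels match the generative spot formula", {
  cfg <- small_clean_cfg(n_cells = 1, foci = 1, seed = 11)
  sim <- generate_field(cfg, target_multiplier = 0.5)
  ref <- get_channel(sim$field, "reference")
  tgt <- get_channel(sim$field, "target")
  sp <- sim$truth$foci
  ci <- round(sp$row); cj <- round(sp$col)
  # pixel nearest the spot centre: background + amplitude * Gaussian falloff
  expect_equal(ref[ci + 1, cj + 1],
               spot_model_value(ci, cj, sp, sp$amp_reference, 1.0, 100),
               tolerance = 1e-12)
  expect_equal(tgt[ci + 1, cj + 1],
               spot_model_value(ci, cj, sp, sp$amp_target, 1.0, 100),
               tolerance = 1e-12)
  expect_equal(sp$amp_target, 300)  # 600 * 0.5
})

test_that("foci counts are conserved and all foci lie inside their nucleus", {
  cfg <- field_config(image_height = 320, image_width = 320, n_cells = 4,
                      nucleus_radius_range = c(21, 24),
                      foci_per_nucleus = 46, seed = 13, n_z = 1)
  sim <- generate_field(cfg)
  expect_equal(nrow(sim$truth$foci), 4 * 46)
  m <- merge(sim$truth$foci, sim$truth$cells,
             by.x = "cell_id", by.y = "cell_id")
  d <- sqrt((m$row - m$center_row)^2 + (m$col - m$center_col)^2)
  expect_true(all(d <= m$radius))
  # minimum pairwise separation within each nucleus
  for (k in unique(sim$truth$foci$cell_id)) {
    f <- sim$truth$foci[sim$truth$foci$cell_id == k, ]
    dm <- as.matrix(dist(f[, c("row", "col")]))
    expect_gte(min(dm[upper.tri(dm)]), 4 * cfg$spot_sigma)
  }
})

test_that("pixel noise follows the Poisson plus read-noise model", {
  cfg <- field_config(image_height = 512, image_width = 512, n_cells = 0,
                      background_level = 100, background_gradient = 0,
                      read_noise_sd = 3, seed = 17, n_z = 1)
  sim <- generate_field(cfg, edu = FALSE)
  px <- as.vector(sim$field$pixels)
  expect_equal(mean(px), 100, tolerance = 0.01)
  # variance = Poisson (lambda) + read noise variance
  expect_equal(var(px), 100 + 9, tolerance = 0.02)
})

test_that("nucleus placement fails loudly when the field is too crowded", {
  cfg <- field_config(image_height = 64, image_width = 64, n_cells = 20,
                      nucleus_radius_range = c(16, 19), seed = 1)
  expect_error(generate_field(cfg), "could not place")
})

test_that("condition multipliers set true amplitudes exactly", {
  cfg <- small_clean_cfg(n_cells = 2, foci = 8)
  set0 <- generate_condition_set(cfg, c(cycling = 1, quiescent = 0),
                                 n_fields_per_condition = 1,
                                 n_replicates = 1,
                                 replicate_effect_sd = 0, seed = 2)
  for (s in set0)
    if (s$field$condition == "quiescent")
      expect_true(all(s$truth$foci$amp_target == 0))
  set25 <- generate_condition_set(cfg, c(cycling = 1, quiescent = 0.25),
                                  n_fields_per_condition = 1,
                                  n_replicates = 1,
                                  replicate_effect_sd = 0, seed = 2)
  amps <- sapply(set25, function(s) mean(s$truth$foci$amp_target))
  conds <- sapply(set25, function(s) s$field$condition)
  expect_equal(mean(amps[conds == "quiescent"]) /
                 mean(amps[conds == "cycling"]), 0.25)
})

test_that("replicate effects are recoverable from the emitted truth", {
  cfg <- small_clean_cfg(n_cells = 2, foci = 8)
  eff_sd <- 0.05
  sims <- generate_condition_set(cfg, c(cycling = 1),
                                 n_fields_per_condition = 1,
                                 n_replicates = 3,
                                 replicate_effect_sd = eff_sd, seed = 9)
  drawn <- attr(sims, "replicate_factors")
  recovered <- sapply(sims, function(s)
    mean(s$truth$foci$amp_target) / 600)
  expect_equal(unname(recovered), drawn, tolerance = 1e-12)
  expect_true(all(abs(drawn - 1) <= 3 * eff_sd))
})

test_that("an empty condition map is rejected", {
  cfg <- small_clean_cfg()
  expect_error(generate_condition_set(cfg, conditions = numeric(0)),
               "non-empty")
})

test_that("EdU class fractions converge to the configured probability", {
  pop <- generate_edu_population(2000, edu_positive_fraction = 0.6,
                                 seed = 21)
  p_hat <- mean(pop$edu_class == "positive")
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))
  # classes are consistent with the component the mean was drawn from:
  # positives stochastically dominate negatives by construction
  expect_gt(min(tapply(pop$edu_mean, pop$edu_class, mean)[["positive"]],
                na.rm = TRUE),
            tapply(pop$edu_mean, pop$edu_class, mean)[["negative"]])
})
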