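manual_trace <- function(times, values, entry = NA, exit = NA,
                         cell_id = "c1", parent_id = NA_character_) {
  data.frame(cell_id = cell_id, parent_id = parent_id, time_h = times,
             value = values, mitosis_entry_h = entry,
             mitosis_exit_h = exit, replicate = 1,
             stringsAsFactors = FALSE)
}

test_that("timebase snapping follows the nearest-mark rule", {
  tr <- manual_trace(c(0, 20, 40) / 60, c(1, 2, 3))
  out <- resample_timebase(tr, 5)
  expect_equal(out$time_h * 60, c(0, 20, 40))
  # 12 min snaps to 10 (nearest 5-min mark)
  out2 <- resample_timebase(manual_trace(12 / 60, 1), 5)
  expect_equal(out2$time_h * 60, 10)
  expect_error(resample_timebase(manual_trace(c(1, 1), c(1, 2)), 5),
               "duplicate")
})

test_that("mixed 15- and 20-min series merge like a brute-force snapper", {
  t1 <- seq(0, 2, by = 15 / 60)
  t2 <- seq(0.05, 2, by = 20 / 60)
  tr <- rbind(manual_trace(t1, seq_along(t1), cell_id = "a"),
              manual_trace(t2, seq_along(t2) + 100, cell_id = "b"))
  out <- resample_timebase(tr, 5)
  # oracle: exhaustive nearest-mark assignment per observation
  for (k in seq_len(nrow(tr))) {
    mark <- round(tr$time_h[k] * 12) / 12
    hit <- out[out$cell_id == tr$cell_id[k] &
                 abs(out$time_h - mark) < 1e-9, ]
    expect_equal(nrow(hit), 1)
  }
  expect_true(all(out$time_h * 12 %% 1 < 1e-9))
})

test_that("alignment centres traces on mitotic entry", {
  tr <- manual_trace(seq(0, 10, by = 0.25), 1, entry = 5, exit = 5.5)
  ens <- align_to_mitosis(tr, grid_interval = 15)
  expect_true(all(ens$mean == 1))
  expect_true(all(ens$n == 1))
  expect_true(all(ens$rel_time_h >= -12 & ens$rel_time_h <= 12))
  expect_equal(min(ens$rel_time_h), -5)
  # translation invariance
  tr2 <- tr
  tr2$time_h <- tr2$time_h + 7
  tr2$mitosis_entry_h <- tr2$mitosis_entry_h + 7
  tr2$mitosis_exit_h <- tr2$mitosis_exit_h + 7
  expect_equal(align_to_mitosis(tr2, grid_interval = 15), ens)
})

test_that("ensemble mean and SD follow from the contributing traces", {
  ta <- manual_trace(0:4, 0, entry = 2, exit = 2.25, cell_id = "a")
  tb <- manual_trace(0:4, 2, entry = 2, exit = 2.25, cell_id = "b")
  ens <- align_to_mitosis(rbind(ta, tb), grid_interval = 60)
  expect_true(all(ens$mean == 1))
  expect_true(all(ens$sd == sqrt(2)))
  expect_true(all(ens$n == 2))
  # a trace without annotation is excluded with a warning
  tc <- manual_trace(0:4, 9, cell_id = "c")
  expect_warning(ens2 <- align_to_mitosis(rbind(ta, tb, tc),
                                          grid_interval = 60),
                 "without a mitosis annotation")
  expect_equal(ens2, ens)
})

test_that("pre/post windows respect their stated boundaries", {
  # parent observed before mitosis; one daughter afterwards
  par <- manual_trace(c(0, 1, 2), c(0.4, 0.4, 0.4), entry = 3, exit = 3.5)
  kid <- manual_trace(c(4.4, 4.4833333, 4.5, 5), c(9, 9, 1.0, 1.0),
                      entry = 3, exit = 3.5, cell_id = "c1.1",
                      parent_id = "c1")
  pp <- pre_post_mitosis_means(rbind(par, kid))
  expect_equal(pp$pre_mean, 0.4)
  # window opens at exit + 1 h = 4.5: the 4.4 and 4.48 observations
  # (value 9) are excluded, 4.5 and later included
  expect_equal(pp$post_mean, 1.0)
  # observations only before mitosis: post flagged missing
  pp2 <- pre_post_mitosis_means(par)
  expect_true(is.na(pp2$post_mean))
})

test_that("noise-free simulated traces give exact window means", {
  cfg <- trace_config(noise_sd = 0, seed = 2)
  tr <- generate_timelapse(cfg, n_cells = 10)
  pp <- pre_post_mitosis_means(tr)
  expect_true(all(pp$pre_mean == 0.4))
  expect_true(all(pp$post_mean == 1.0))
})

test_that("aligned ensemble recovers generative levels under noise", {
  cfg <- trace_config(noise_sd = 0.05, seed = 6)
  tr <- generate_timelapse(cfg, n_cells = 30)
  ens <- align_to_mitosis(tr)
  pre <- ens[ens$rel_time_h < 0, ]
  post <- ens[ens$rel_time_h > cfg$mitosis_duration / 60 +
                cfg$recovery_delay, ]
  se <- function(d) 0.05 / sqrt(min(d$n))
  expect_lt(max(abs(pre$mean - 0.4)), 3 * se(pre) + 1e-9)
  expect_lt(max(abs(post$mean - 1.0)), 3 * se(post) + 1e-9)
  # post/pre ratio across cells within 5% of the generative 2.5
  pp <- pre_post_mitosis_means(tr)
  ratio <- mean(pp$post_mean) / mean(pp$pre_mean)
  expect_lt(abs(ratio - 2.5) / 2.5, 0.05)
})
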