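# synthetic-data generator: pair tables, lineage trees, rendered image pairs

test_that("degenerate noiseless config gives identical symmetric pairs", {
  cfg <- lineage_sim_config(D_old = 0, D_new = 0, V_E_old = 0, V_E_new = 0,
                            seed = 42)
  pt <- simulate_pair_table(cfg)
  expect_equal(pt$new_value / pt$old_value, rep(1, nrow(pt)))
  dr <- daughter_ratio(pt$old_value, pt$new_value)
  expect_equal(dr$mean, 1)
})

test_that("generator mean ratio matches second-order expansion and MC oracle", {
  D <- 0.2; V_E <- 0.01
  closed_form <- (1 + D / 2) / (1 - D / 2) + 2 * V_E / (1 - D / 2)^3
  set.seed(1)
  d_mc <- rnorm(1e6, D, 2 * sqrt(V_E))
  d_mc <- d_mc[abs(d_mc) < 2]
  mc <- mean((1 + d_mc / 2) / (1 - d_mc / 2))
  # the expansion truncates at second order; MC is the exact oracle
  expect_lt(abs(mc - closed_form), 3e-3)
  cfg <- lineage_sim_config(n_mothers_old = 1e4, n_mothers_new = 2,
                            D_old = D, V_E_old = V_E, seed = 7)
  pt <- simulate_pair_table(cfg)
  got <- mean(pt$new_value[pt$mother_type == "old"] /
                pt$old_value[pt$mother_type == "old"])
  se <- sd((1 + d_mc / 2) / (1 - d_mc / 2)) / sqrt(1e4)
  expect_lt(abs(got - mc), 4 * se)
})

test_that("decomposition recovery: 3-SE coverage across 100 seeded runs", {
  n <- 200; D <- 0.101; V_E <- 0.00381
  se_D <- 2 * sqrt(V_E) / sqrt(n)          # sd(d)/sqrt(n), d ~ N(D, 4 V_E)
  se_VE <- V_E * sqrt(2 / (n - 1))         # large-sample SE of a variance
  hits <- 0L
  for (s in 1:100) {
    cfg <- lineage_sim_config(n_mothers_old = n, n_mothers_new = 2,
                              D_old = D, V_E_old = V_E, seed = s)
    dec <- variance_decomposition(simulate_pair_table(cfg), "old")
    if (abs(dec$D - D) <= 3 * se_D && abs(dec$V_E - V_E) <= 3 * se_VE)
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("implausible configs are rejected", {
  expect_error(lineage_sim_config(D_old = 2.5), "\\(-2, 2\\)")
  expect_error(lineage_sim_config(V_E_old = -1), "variances")
  expect_error(lineage_sim_config(n_mothers_old = 1), "at least 2")
  # bounded redraws: huge stochastic variance makes positive densities
  # essentially unreachable (deterministic given the seed)
  cfg <- lineage_sim_config(V_E_old = 2500, seed = 1)
  expect_error(simulate_pair_table(cfg), "redraws")
})

test_that("pair table round-trips through CSV with schema validation", {
  pt <- simulate_pair_table(lineage_sim_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pair_table(pt, path)
  back <- read_pair_table(path)
  expect_equal(back$old_value, pt$old_value)
  expect_equal(back$mother_type, pt$mother_type)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_pair_table(bad), "missing column")
})

test_that("lineage trees have the right shape and balanced polarity", {
  tr2 <- simulate_lineage(2, lineage_sim_config(seed = 5))
  leaves <- tr2[!tr2$cell_id %in% tr2$parent_id, ]
  expect_equal(nrow(leaves), 4L)
  expect_equal(sum(leaves$daughter_class == "old"), 2L)
  expect_equal(sum(leaves$daughter_class == "new"), 2L)
  # generation-1 cells remain unknown (root polarity unknown)
  expect_true(all(tr2$daughter_class[tr2$generation == 1L] == "unknown"))
  expect_error(simulate_lineage(1), "before two divisions")
  tr7 <- simulate_lineage(7, lineage_sim_config(seed = 5))
  expect_equal(sum(!tr7$cell_id %in% tr7$parent_id), 128L)
  # equinumerous old/new among cells whose parent polarity is known
  for (g in 2:7) {
    gen <- tr7[tr7$generation == g, ]
    expect_equal(sum(gen$daughter_class == "old"),
                 sum(gen$daughter_class == "new"))
    expect_equal(sum(gen$daughter_class == "unknown"), 0L)
  }
})

test_that("polarity assignment is invariant to pole A/B relabeling", {
  tr <- simulate_lineage(3, lineage_sim_config(seed = 9))
  flipped <- tr
  flipped$pole_A_age <- tr$pole_B_age
  flipped$pole_B_age <- tr$pole_A_age
  expect_equal(assign_polarity(flipped)$daughter_class, tr$daughter_class)
})

test_that("assign_polarity rejects malformed trees", {
  tr <- simulate_lineage(2, lineage_sim_config(seed = 5))
  broken <- tr[-nrow(tr), ]   # drop one child
  expect_error(assign_polarity(broken), "!= 2 children")
})

test_that("near-delta PSF, zero noise: fluorescence equals truth in mask", {
  cfg <- image_sim_config(psf_sigma_px = 0.1, background_level = 0,
                          shot_noise_scale = 0, outlier_fraction = 0,
                          seed = 1)
  sc <- render_image_pair(cfg)
  expect_lt(max(abs(sc$fluorescence - sc$truth)), 1e-8)
})

test_that("symmetric cell gives pole-half ratio exactly 1 on noiseless image", {
  cfg <- image_sim_config(pole_bias = 1, polar_enrichment = 1,
                          background_level = 0, shot_noise_scale = 0,
                          outlier_fraction = 0, seed = 1)
  sc <- render_image_pair(cfg)
  halves <- split_cell(sc$masks == 1,
                       c(sc$cells$centerline_row, sc$cells$new_pole_col), 2)
  expect_equal(measure_density(sc$fluorescence, halves$new_half) /
                 measure_density(sc$fluorescence, halves$old_half), 1)
})

test_that("rendered flux is conserved for interior-supported scenes", {
  cfg <- image_sim_config(background_level = 0, shot_noise_scale = 0,
                          outlier_fraction = 0, seed = 2)
  sc <- render_image_pair(cfg)
  expect_lt(abs(sum(sc$fluorescence) - sum(sc$truth)) / sum(sc$truth), 1e-6)
})

test_that("overlapping silhouettes violate the monolayer assumption", {
  cfg <- image_sim_config(seed = 1)
  cells <- data.frame(row0 = c(20, 22), col0 = c(20, 25))
  expect_error(render_image_pair(cfg, cells), "monolayer")
})

test_that("ground-truth quartile densities follow the stated profile", {
  cfg <- image_sim_config(seed = 1, background_level = 0,
                          shot_noise_scale = 0, outlier_fraction = 0)
  sc <- render_image_pair(cfg)
  b <- cfg$pole_bias; e <- cfg$polar_enrichment
  parts <- split_cell(sc$masks == 1,
                      c(sc$cells$centerline_row, sc$cells$new_pole_col), 4)
  got <- vapply(parts, function(m) measure_density(sc$truth, m), 0)
  expect_equal(unname(got), cfg$base_density * c(b * e, b, 1, e))
})

test_that("quartile trajectory generator keeps the sum-to-one invariant", {
  qt <- simulate_quartile_table(n_mothers = 20, seed = 4)
  expect_equal(rowSums(qt[, c("NP", "L2", "L3", "OP")]),
               rep(1, nrow(qt)))
  expect_equal(levels(qt$time_quartile), c("B", "T2", "T3", "D"))
})
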