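# normalizations, variance decomposition, randomization inference,
# slope comparison, Bartlett's test

test_that("pair normalization is antisymmetric and exact", {
  expect_equal(pair_normalize(2, 2), list(old = 0, new = 0))
  expect_equal(pair_normalize(0.9, 1.1), list(old = -0.1, new = 0.1))
  set.seed(1)
  z <- rand_norm_pairs(50)
  expect_equal(z$old + z$new, rep(0, 50))
  expect_error(pair_normalize(-2, 1), "> 0")
})

test_that("quartile normalization sums to exactly 1", {
  expect_equal(quartile_normalize(c(5, 5, 5, 5)), rep(0.25, 4))
  expect_equal(quartile_normalize(c(2, 1, 1, 0)), c(0.5, 0.25, 0.25, 0))
  set.seed(2)
  m <- matrix(runif(40, 0.1, 5), 10, 4)
  expect_equal(rowSums(quartile_normalize(m)), rep(1, 10))
  expect_error(quartile_normalize(c(0, 0, 0, 0)), "> 0")
  expect_error(quartile_normalize(1:3), "4 quartile")
})

test_that("decomposition identity holds to machine precision (brute force)", {
  set.seed(3)
  for (n in c(2, 5, 37, 1000)) {
    old <- runif(n, 50, 150); new <- runif(n, 50, 150)
    dec <- variance_decomposition(data.frame(old_value = old,
                                             new_value = new))
    bf <- brute_decomposition(old, new)
    expect_equal(dec$D, bf$D)
    expect_equal(dec$V_T, bf$V_T)
    expect_equal(dec$V_T, (bf$V_old + bf$V_new) / 2 + bf$D^2 / 4,
                 tolerance = 1e-14)
    expect_equal(dec$V_E, dec$V_T * (1 - dec$h2))
  }
})

test_that("decomposition arithmetic reproduces published-style summaries", {
  # elongation rows recompute from printed V_T and D
  old_el <- decomposition_from_summary(V_T = 0.00913, D = 0.0821)
  expect_equal(round(old_el$h2, 3), 0.185)
  expect_equal(round(old_el$V_E, 5), 0.00744)
  new_el <- decomposition_from_summary(V_T = 0.00581, D = 0.0533)
  expect_equal(round(new_el$h2, 3), 0.122)
  expect_equal(round(new_el$V_E, 5), 0.00510)
})

test_that("symmetric noise-only pairs give h2 = 0", {
  pairs <- data.frame(old_value = c(0.9, 1.1, 0.95, 1.05),
                      new_value = c(1.1, 0.9, 1.05, 0.95))
  dec <- variance_decomposition(pairs)
  expect_equal(dec$D, 0)
  expect_equal(dec$h2, 0)
  expect_equal(dec$V_E, dec$V_T)
})

test_that("h2 is invariant to uniform rescaling of raw values", {
  set.seed(4)
  old <- runif(30, 100, 300); new <- runif(30, 100, 300)
  d1 <- variance_decomposition(data.frame(old_value = old, new_value = new))
  d2 <- variance_decomposition(data.frame(old_value = 13 * old,
                                          new_value = 13 * new))
  expect_equal(d1$h2, d2$h2)
  expect_equal(d1$D, d2$D)
})

test_that("sample-variance convention is available and documented-different", {
  set.seed(5)
  pairs <- data.frame(old_value = runif(10, 1, 2), new_value = runif(10, 1, 2))
  dp <- variance_decomposition(pairs, convention = "population")
  ds <- variance_decomposition(pairs, convention = "sample")
  expect_equal(ds$V_T * (2 * 10 - 1) / (2 * 10), dp$V_T)
})

test_that("randomization test: perfect association hits the p floor", {
  set.seed(6)
  z <- rand_norm_pairs(60)
  rc <- randomization_correlation(z$old, z$new, z$old, z$new,
                                  n_perm = 999, seed = 1)
  expect_equal(rc$r, 1)
  expect_equal(rc$p, 1 / 1000)
  expect_error(randomization_correlation(z$old, z$new, z$old, z$new,
                                         n_perm = 0), ">= 1")
})

test_that("randomization p is bounded below and r matches pooled Pearson", {
  set.seed(7)
  x <- rand_norm_pairs(25); y <- rand_norm_pairs(25)
  rc <- randomization_correlation(x$old, x$new, y$old, y$new,
                                  n_perm = 199, seed = 2)
  expect_gte(rc$p, 1 / 200)
  expect_equal(rc$r, cor(c(x$old, x$new), c(y$old, y$new)))
  expect_equal(rc$slope,
               cov(c(x$old, x$new), c(y$old, y$new)) / var(c(x$old, x$new)))
})

test_that("pooled r of published-parameter pairs recovers the printed 0.387", {
  # the pooled-point correlation includes the deterministic alignment
  # D_x * D_y; the latent correlation rho is chosen in closed form so the
  # expected pooled r equals the printed value
  Dx <- 0.101; Vx <- 4 * 0.00381; Dy <- 0.0821; Vy <- 4 * 0.00744
  r_target <- 0.387
  rho <- (r_target * sqrt((Vx + Dx^2) * (Vy + Dy^2)) - Dx * Dy) /
    sqrt(Vx * Vy)
  set.seed(8)
  rs <- replicate(30, {
    n <- 216
    dx <- rnorm(n, Dx, sqrt(Vx))
    dy <- Dy + sqrt(Vy) * (rho * (dx - Dx) / sqrt(Vx) +
                             sqrt(1 - rho^2) * rnorm(n))
    randomization_correlation(-dx / 2, dx / 2, -dy / 2, dy / 2,
                              n_perm = 1)$r
  })
  expect_lt(abs(mean(rs) - r_target), 0.02)
})

test_that("slope comparison follows the SEM-based t formula", {
  eq <- compare_slopes(0.5, 0.1, 50, 0.5, 0.2, 60)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_equal(eq$df, 106)
  s <- 0.3; sem <- 0.05
  pm <- compare_slopes(s, sem, 40, -s, sem, 40)
  expect_equal(pm$t, 2 * s / (sem * sqrt(2)))
  # published trajectory-comparison inputs: the formula's own arithmetic
  f6 <- compare_slopes(-0.00390, 0.00313, 81, -0.00803, 0.00347, 81)
  expect_equal(f6$t, (-0.00390 + 0.00803) / sqrt(0.00313^2 + 0.00347^2))
  expect_equal(f6$p, 2 * pt(-abs(f6$t), 158))
  expect_error(compare_slopes(1, 0, 10, 2, 1, 10), "> 0")
})

test_that("Bartlett's closed form matches stats::bartlett.test", {
  set.seed(9)
  gs <- list(rnorm(20, sd = 1), rnorm(25, sd = 1.3), rnorm(30, sd = 0.8))
  ours <- variance_homogeneity(gs)
  ref <- stats::bartlett.test(gs)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$df, 2L)
})

test_that("Bartlett: identical groups give statistic 0, p 1; power case", {
  g <- c(1.2, 3.4, 2.2, 5.1)
  out <- variance_homogeneity(list(g, g))
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  set.seed(10)
  strong <- variance_homogeneity(list(rnorm(50, sd = 1), rnorm(50, sd = 2)))
  expect_lt(strong$p, 0.01)
  expect_error(variance_homogeneity(list(rep(1, 5), rnorm(5))),
               "zero variance")
  expect_error(variance_homogeneity(list(rnorm(5))), "2 groups")
})

test_that("Bartlett type-I error is calibrated near 0.05", {
  set.seed(11)
  rej <- mean(replicate(2000, {
    variance_homogeneity(list(rnorm(20), rnorm(20)))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("analyze_pair_table assembles consistent A/B/C blocks", {
  cfg <- lineage_sim_config(seed = 12)
  pt <- simulate_pair_table(cfg)
  rep <- analyze_pair_table(pt)
  expect_equal(rep$value$mother_class, c("old", "new"))
  old_row <- rep$value[rep$value$mother_class == "old", ]
  direct <- variance_decomposition(pt, "old")
  expect_equal(old_row$V_T, direct$V_T)
  expect_equal(old_row$h2, direct$h2)
  expect_true(all(c("value_across_mothers", "rate_across_mothers",
                    "rate_vs_value_old", "rate_vs_value_new") %in%
                    names(rep$V_E_comparison)))
  expect_true(all(unlist(rep$V_E_comparison) >= 0 &
                    unlist(rep$V_E_comparison) <= 1))
})
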