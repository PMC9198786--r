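test_that("identical groups give Wilks' lambda of one and F near zero", {
  set.seed(81)
  block <- matrix(rnorm(8 * 4), 8, 4)
  d <- data.frame(treatment = rep(c("control", "drug"), each = 8),
                  rbind(block, block))
  names(d)[-1] <- sprintf("b%.1f", seq(0.1, 0.7, by = 0.2))
  fit <- manova_two_group(d)
  expect_equal(fit$wilks_lambda, 1, tolerance = 1e-12)
  expect_equal(fit$f_approx, 0, tolerance = 1e-10)
})

test_that("with one band the MANOVA p equals the one-way ANOVA p", {
  set.seed(82)
  d <- data.frame(treatment = rep(c("control", "drug"), each = 10),
                  b0.1 = rnorm(20, 10))
  fit <- manova_two_group(d)
  oracle <- anova(lm(b0.1 ~ treatment, data = d))
  expect_equal(fit$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(fit$univariate$p[1], oracle$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("Wilks' lambda, F and p match the reference MANOVA implementation", {
  for (s in 1:5) {
    d <- simulate_band_power_study(n_per_group = 13, effect_size = 0.4,
                                   seed = 820 + s)
    fit <- manova_two_group(d)
    x <- as.matrix(d[grep("^b", names(d))])
    ref <- summary(stats::manova(x ~ d$treatment), test = "Wilks")$stats
    expect_equal(fit$wilks_lambda, unname(ref[1, "Wilks"]), tolerance = 1e-10)
    expect_equal(fit$f_approx, unname(ref[1, "approx F"]), tolerance = 1e-8)
    expect_equal(fit$p_value, unname(ref[1, "Pr(>F)"]), tolerance = 1e-10)
  }
})

test_that("Wilks' lambda is invariant under invertible linear transforms", {
  d <- simulate_band_power_study(n_per_group = 14, effect_size = 0.6,
                                 seed = 83)
  fit0 <- manova_two_group(d)
  bands <- grep("^b", names(d))
  set.seed(84)
  for (i in 1:3) {
    a <- matrix(rnorm(100), 10, 10)
    while (abs(det(a)) < 1e-3) a <- matrix(rnorm(100), 10, 10)
    d2 <- d
    d2[bands] <- as.matrix(d[bands]) %*% a
    expect_equal(manova_two_group(d2)$wilks_lambda, fit0$wilks_lambda,
                 tolerance = 1e-8)
  }
})

test_that("degenerate designs are rejected with informative errors", {
  d <- simulate_band_power_study(n_per_group = 4, seed = 85)
  expect_error(manova_two_group(d), "rank deficiency")
  d1 <- simulate_band_power_study(n_per_group = 15, seed = 86)
  d1$treatment <- "control"
  expect_error(manova_two_group(d1), "two groups")
  d2 <- simulate_band_power_study(n_per_group = 15, seed = 87)
  d2$b0.5 <- 1  # zero within-group variance
  expect_error(manova_two_group(d2), "b0.5")
})

test_that("the factorial grid yields all unordered cell-mean contrasts", {
  set.seed(88)
  d <- expand.grid(temp_c = 31:36, treatment = c("control", "drug"),
                   rep = 1:4)
  d$value <- rnorm(nrow(d))
  tab <- pairwise_cell_comparisons(d)
  expect_equal(nrow(tab), choose(12, 2))  # 66
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))
  expect_true(all(tab$p_adj <= 1))
  # two cells: one row, difference of cell means
  d2 <- data.frame(temp_c = 31, treatment = rep(c("a", "b"), each = 3),
                   value = c(1, 2, 3, 7, 8, 9))
  tab2 <- pairwise_cell_comparisons(d2)
  expect_equal(nrow(tab2), 1L)
  expect_equal(abs(tab2$diff), 6)
})

test_that("underpopulated cells are dropped with a warning", {
  d <- data.frame(temp_c = c(31, 31, 31, 32, 32, 33),
                  treatment = "control",
                  value = c(1, 2, 3, 4, 5, 6))
  expect_warning(tab <- pairwise_cell_comparisons(d), "fewer than two")
  expect_equal(nrow(tab), 1L)  # only cells 31 and 32 survive
  d_all_small <- data.frame(temp_c = c(31, 32), treatment = "control",
                            value = c(1, 2))
  expect_warning(expect_error(pairwise_cell_comparisons(d_all_small),
                              "at least two"))
})

test_that("BH adjustment follows the hand-executed step-up procedure", {
  expect_equal(bh_adjust(0.37), 0.37)                   # m = 1
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))     # common value
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # order preserved, matches reference implementation on random input
  set.seed(89)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in p
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("BH-adjusted contrasts control the false discovery rate under the null", {
  set.seed(90)
  hits <- replicate(400, {
    d <- expand.grid(temp_c = 31:33, treatment = c("control", "drug"),
                     rep = 1:4)
    d$value <- rnorm(nrow(d))
    any(pairwise_cell_comparisons(d)$p_adj < 0.05)
  })
  # family-wise hit rate under the global null is itself FDR-bounded at 5%
  expect_lte(mean(hits), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 400))
})

test_that("the drug-effect fixture is detected multivariately but spares its band", {
  set.seed(91)
  res <- t(replicate(100, {
    d <- simulate_band_power_study(n_per_group = 15, effect_size = 0.8,
                                   spared_band = 0.5)
    fit <- manova_two_group(d)
    c(fit$p_value < 0.05,
      fit$univariate$p[fit$univariate$band == "b0.5"] < 0.05)
  }))
  expect_gte(mean(res[, 1]), 0.8)   # multivariate power
  expect_lte(mean(res[, 2]), 0.12)  # spared band stays near alpha
})
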