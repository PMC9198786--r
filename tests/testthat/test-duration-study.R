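test_that("a single simulation at the reference duration is the identity", {
  cfg <- duration_study_config(n_sims = 1, durations = 64,
                               reference_duration = 64, seed = 71)
  surf <- run_duration_study(cfg)
  set.seed(71)
  rr <- simulate_rr(cfg$model, 64)
  p <- normalize_periodogram(lomb_scargle(truncate_rr(rr, 64), cfg$freqs))
  expect_equal(as.vector(surf$mean_power[1, ]), p$power)
})

test_that("valid surface rows are unit-sum and dispersion is finite", {
  cfg <- duration_study_config(n_sims = 10, durations = c(4, 16, 64),
                               seed = 72)
  surf <- run_duration_study(cfg)
  expect_true(all(surf$row_valid))
  expect_equal(rowSums(surf$mean_power), rep(1, 3), tolerance = 1e-9)
  expect_true(all(is.finite(surf$dispersion)))
  expect_true(all(surf$mean_power >= 0))
})

test_that("a zero-variance model yields degenerate all-zero rows", {
  m0 <- spectral_model(0.8, 2, 0.08, 0.08, 5e-4, 1e-3,
                       mean_rr = 0.1, sd_rr = 0)
  cfg <- duration_study_config(n_sims = 3, durations = c(4, 8),
                               model = m0, reference_duration = 8, seed = 73)
  surf <- run_duration_study(cfg)
  expect_true(all(surf$row_degenerate))
  expect_equal(as.vector(surf$mean_power), rep(0, length(surf$mean_power)))
})

test_that("the study is reproducible from its seed", {
  cfg <- duration_study_config(n_sims = 5, durations = c(4, 16, 64),
                               seed = 74)
  a <- run_duration_study(cfg)
  b <- run_duration_study(cfg)
  expect_identical(a$mean_power, b$mean_power)
  expect_identical(a$median_l1, b$median_l1)
})

test_that("convergence curve ends at zero and is zero for identical rows", {
  cfg <- duration_study_config(n_sims = 5, durations = c(8, 32, 64),
                               seed = 75)
  surf <- run_duration_study(cfg)
  div <- convergence_curve(surf)
  expect_equal(unname(div[length(div)]), 0)
  flat <- surf
  flat$mean_power <- matrix(rep(surf$mean_power[3, ], each = 3), nrow = 3)
  expect_equal(unname(convergence_curve(flat)), rep(0, 3))
})

test_that("periodogram divergence shrinks as records lengthen", {
  cfg <- duration_study_config(n_sims = 100, seed = 76)
  surf <- run_duration_study(cfg)
  div <- convergence_curve(surf)
  rho <- suppressWarnings(
    stats::cor(surf$durations, div, method = "spearman")
  )
  expect_lte(rho, -0.9)
  expect_lt(div[surf$durations == 8], div[surf$durations == 2])
})
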