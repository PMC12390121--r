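test_that("truncated sampling respects its bounds and degenerate cases", {
  expect_identical(sample_truncated(5, 10, 0), rep(10, 5))
  set.seed(1)
  r <- sample_truncated(1e4, 108.9, 40.5)
  q <- qnorm(c(0.05, 0.95), 108.9, 40.5)  # [42.28, 175.52]
  expect_true(all(r >= q[1] & r <= q[2]))
  # symmetric truncation keeps the mean
  expect_equal(mean(r), 108.9, tolerance = 0.01)
  expect_error(sample_truncated(10, 0, -1), "sd")
  expect_error(sample_truncated(10, 0, 1, lo = 0.9, hi = 0.1), "lo < hi")
})

test_that("identical seeds give bit-identical Monte Carlo summaries", {
  sc <- build_generic(0.27, 300)
  a <- run_monte_carlo(sc, n = 100, seed = 7, forage_cv = 0.4)
  b <- run_monte_carlo(sc, n = 100, seed = 7, forage_cv = 0.4)
  expect_identical(a$final_muscle_conc, b$final_muscle_conc)
  expect_identical(a$p95, b$p95)
  expect_identical(a$draws, b$draws)
  c <- run_monte_carlo(sc, n = 100, seed = 8, forage_cv = 0.4)
  expect_false(identical(a$p95, c$p95))
})

test_that("with distributions off and no forage CV every iteration is deterministic", {
  sc <- build_generic(0.27, 540)
  det <- simulate_dam(sc)
  mc <- run_monte_carlo(sc, n = 10, seed = 1, forage_cv = 0,
                        param_distributions = FALSE)
  expect_equal(mc$final_muscle_conc,
               rep(det$final_muscle_conc, 10), tolerance = 1e-12)
  expect_equal(mc$sd, 0)
  expect_equal(mc$final_serum_conc,
               rep(det$final_serum_conc, 10), tolerance = 1e-12)
})

test_that("shrinking all SDs collapses the probabilistic mean to the deterministic value", {
  sc <- build_generic(0.27, 300)
  det <- simulate_dam(sc)$final_muscle_conc
  p <- default_profile()
  for (f in grep("_sd$", names(p), value = TRUE)) p[[f]] <- p[[f]] * 1e-6
  p$gain_cv <- 1e-6; p$cow_dmi_cv <- 1e-6; p$milk_prod_cv <- 1e-6
  p$dmi_sd_per_bw <- p$dmi_sd_per_bw * 1e-6
  mc <- run_monte_carlo(sc, validate_profile(p), n = 50, seed = 2)
  expect_equal(mc$mean, det, tolerance = 1e-4)
})

test_that("recorded animal-level draws respect the truncation bounds", {
  mc <- run_monte_carlo(build_generic(0.27, 120), n = 500, seed = 3)
  p <- default_profile()
  z <- qnorm(0.95)
  expect_true(all(abs(mc$draws$muscle_body_ratio - p$muscle_body_ratio) <=
                    z * p$muscle_body_ratio_sd + 1e-12))
  expect_true(all(abs(mc$draws$birth_weight - p$birth_weight) <=
                    z * p$birth_weight_sd + 1e-12))
  # fixed-scope parameter is held at its mean
  expect_true(all(mc$draws$muscle_bw_fraction == p$muscle_bw_fraction))
})

test_that("sampling scopes are honoured", {
  sc <- build_generic(0.27, 120)
  scopes <- default_sampling_scopes()
  scopes["muscle_bw_fraction"] <- "per_iteration"
  mc <- run_monte_carlo(sc, n = 200, seed = 4, scopes = scopes)
  expect_gt(sd(mc$draws$muscle_bw_fraction), 0)
  scopes["muscle_body_ratio"] <- "fixed"
  mc2 <- run_monte_carlo(sc, n = 200, seed = 4, scopes = scopes)
  expect_equal(sd(mc2$draws$muscle_body_ratio), 0)
  expect_error(run_monte_carlo(sc, n = 10, seed = 1,
                               scopes = c(half_life = "sometimes")),
               "scopes")
})

test_that("the Monte Carlo output distribution is stable across seeds", {
  sc <- build_generic(0.27, 540)
  means <- vapply(1:4, function(s) {
    run_monte_carlo(sc, n = 250, seed = s, forage_cv = 0.4)$mean
  }, numeric(1))
  grand <- mean(means)
  mcse <- sd(means) / sqrt(length(means))
  expect_true(all(abs(means - grand) < 3 * sd(means) + 1e-9))
  # spread of seed-level means is small relative to the mean itself
  expect_lt(mcse / grand, 0.05)
})

test_that("summary quantiles are internally consistent", {
  mc <- run_monte_carlo(build_generic(0.27, 300), n = 400, seed = 5,
                        forage_cv = 0.4)
  expect_lte(mc$ci90[1], mc$mean)
  expect_gte(mc$ci90[2], mc$mean)
  expect_equal(mc$p95, unname(quantile(mc$final_muscle_conc, 0.95)))
  expect_equal(mc$mean, mean(mc$final_muscle_conc))
  bands <- run_monte_carlo(build_generic(0.27, 120), n = 100, seed = 5,
                           day_quantiles = TRUE)$day_bands
  expect_identical(dim(bands), c(120L, 3L))
  expect_true(all(bands[, "q05"] <= bands[, "q95"]))
})

test_that("a parameter the output does not depend on gets correlation ~0", {
  # serum ratio does not enter the muscle path
  mc <- run_monte_carlo(build_generic(0.27, 300), n = 400, seed = 6)
  r <- sensitivity_ranking(mc, "muscle")
  rho_ms <- r$rho[r$parameter == "muscle_serum_ratio"]
  expect_lt(abs(rho_ms), 0.15)
  # fixed parameters report exactly 0
  rho_mbw <- r$rho[r$parameter == "muscle_bw_fraction"]
  expect_identical(rho_mbw, 0)
  expect_error(sensitivity_ranking(
    run_monte_carlo(build_generic(0.27, 50), n = 50, seed = 1)), ">= 100")
})
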