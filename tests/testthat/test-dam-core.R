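test_that("daily elimination follows the half-life equation", {
  expect_equal(daily_elimination(10, 1), 5)
  expect_equal(daily_elimination(0, 50), 0)
  expect_equal(daily_elimination(1000, 108.9), 6.3452, tolerance = 1e-4)
  expect_equal(daily_elimination(1000, 108.9), 1000 * (1 - 2^(-1 / 108.9)))
  b <- c(0, 1, 10, 1e6)
  el <- daily_elimination(b, 75)
  expect_true(all(el >= 0 & el <= b))
  expect_error(daily_elimination(10, 0), "half_life")
  expect_error(daily_elimination(-1, 10), "body_burden")
})

test_that("tissue partitioning follows the ratio chain", {
  p <- default_profile()
  expect_equal(muscle_mass_of_pfos(100, p), 23.1)
  expect_equal(muscle_mass_of_pfos(0, p), 0)
  p1 <- default_profile(muscle_body_ratio = 0.9999)
  expect_equal(muscle_mass_of_pfos(50, p1), 50 * 0.9999)

  expect_equal(muscle_concentration(100, 500, p), 23.1 / (0.361 * 500))
  expect_equal(muscle_concentration(100, 500, p), 0.12798, tolerance = 1e-4)
  expect_equal(muscle_concentration(100, 1000, p),
               muscle_concentration(100, 500, p) / 2)
  expect_error(muscle_concentration(100, 0, p), "body_weight")

  expect_equal(serum_concentration(0, p), 0)
  expect_equal(serum_concentration(0.5, p), 6.25)
  expect_equal(serum_concentration(0.4, default_profile(muscle_serum_ratio = 0.9999)),
               0.4 / 0.9999)
})

test_that("a zero-exposure scenario stays at zero everywhere", {
  res <- simulate_dam(exposure_scenario(200))
  expect_true(all(res$trajectory$body_burden == 0))
  expect_true(all(res$trajectory$muscle_conc == 0))
  expect_identical(nrow(res$trajectory), 200L)
})

test_that("zero-intake depletion matches the closed-form half-life decay", {
  p <- default_profile(half_life = 30)
  sc <- exposure_scenario(150, initial_body_burden = 1000)
  res <- simulate_dam(sc, p)
  n <- res$trajectory$day
  expect_equal(res$trajectory$body_burden, 1000 * 2^(-n / 30),
               tolerance = 1e-12)
  # strictly decreasing while positive
  expect_true(all(diff(res$trajectory$body_burden) < 0))
})

test_that("burden trajectory conserves mass day by day", {
  sc <- build_synthetic_history(duration = 400, n_segments = 3,
                                segment_conc_range = c(0.5, 3),
                                depuration_days = 60, seed = 11)
  for (ord in c("intake_first", "eliminate_first")) {
    res <- simulate_dam(sc, default_profile(update_order = ord))
    tr <- res$trajectory
    recon <- attr(sc, "initial_body_burden") +
      cumsum(tr$intake_total) - cumsum(tr$eliminated)
    expect_equal(tr$body_burden, recon, tolerance = 1e-12)
    expect_true(all(tr$body_burden >= 0))
  }
})

test_that("the daily elimination fraction is constant along the trajectory", {
  p <- default_profile(half_life = 60)
  sc <- build_generic(1, 300)
  tr <- simulate_dam(sc, p)$trajectory
  # intake-first: elimination acts on the post-intake burden
  frac <- tr$eliminated / (tr$body_burden + tr$eliminated)
  expect_equal(frac, rep(1 - 2^(-1 / 60), 300), tolerance = 1e-12)
})

test_that("outputs are linear in the exposure concentrations", {
  base <- build_generic(0.27, 400)
  ref <- simulate_dam(base)
  for (alpha in c(0.5, 2, 10)) {
    scaled <- simulate_dam(build_generic(0.27 * alpha, 400))
    expect_equal(scaled$trajectory$body_burden,
                 alpha * ref$trajectory$body_burden, tolerance = 1e-10)
    expect_equal(scaled$final_muscle_conc, alpha * ref$final_muscle_conc,
                 tolerance = 1e-10)
  }
})

test_that("constant intake converges to the closed-form steady state", {
  # 10 half-lives of constant forage intake; fixed body weight is not
  # needed because only the burden is compared
  for (ord in c("intake_first", "eliminate_first")) {
    p <- constant_intake_profile(dmi = 5, half_life = 20, update_order = ord)
    sc <- exposure_scenario(300, forage_conc = 1, cow_forage_conc = 0)
    res <- simulate_dam(sc, p)
    f <- 2^(-1 / 20)
    ss <- if (ord == "intake_first") 5 * f / (1 - f) else 5 / (1 - f)
    expect_equal(res$final_body_burden, ss, tolerance = 0.002)
    # oracle recursion agrees exactly
    expect_equal(res$final_body_burden,
                 burden_recursion(0, 5, f, 300, ord == "intake_first"),
                 tolerance = 1e-12)
  }
})

test_that("update order changes the result by one day of elimination", {
  sc <- build_generic(0.27, 540)
  a <- simulate_dam(sc, default_profile(update_order = "intake_first"))
  b <- simulate_dam(sc, default_profile(update_order = "eliminate_first"))
  expect_gt(b$final_muscle_conc, a$final_muscle_conc)
  expect_lt((b$final_muscle_conc - a$final_muscle_conc) /
              a$final_muscle_conc, 0.01)
})

test_that("initial body burden is carried and depleted", {
  sc <- exposure_scenario(100, initial_body_burden = 500)
  res <- simulate_dam(sc)
  expect_equal(res$trajectory$body_burden[1],
               500 * 2^(-1 / 108.9), tolerance = 1e-12)
})

test_that("the bioaccumulation factor is the muscle:ration quotient", {
  expect_equal(bioaccumulation_factor(0.501, 0.270), 0.501 / 0.270)
  expect_equal(bioaccumulation_factor(0.501, 0.270), 1.8556, tolerance = 1e-4)
  expect_equal(bioaccumulation_factor(2, 2), 1)
  expect_equal(bioaccumulation_factor(0, 1), 0)
  expect_error(bioaccumulation_factor(1, 0), "ration_conc")
})

test_that("the inverse ration solver exploits linearity and verifies", {
  unit <- simulate_dam(build_generic(1, 540))$final_muscle_conc
  expect_equal(solve_ration_for_target(unit, 540), 1)
  r1 <- solve_ration_for_target(0.25, 540)
  r2 <- solve_ration_for_target(0.50, 540)
  expect_equal(r2, 2 * r1, tolerance = 1e-9)
  back <- simulate_dam(build_generic(r2, 540))$final_muscle_conc
  expect_equal(back, 0.50, tolerance = 1e-6)
  expect_error(solve_ration_for_target(0), "target")
})
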