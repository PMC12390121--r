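test_that("body weight starts at birth weight and matches the closed-form curve", {
  p <- default_profile()
  expect_identical(body_weight(0, p), p$birth_weight)
  expect_equal(body_weight(0, p), 35.45)

  # daily-gain summation vs the closed-form quartic: within 0.5% everywhere
  ages <- 1:540
  rel <- abs(body_weight(ages, p) - bw_closed_form(ages)) /
    bw_closed_form(ages)
  expect_lt(max(rel), 0.005)
  expect_equal(body_weight(100, p), 107.4778, tolerance = 0.005)

  # constant late gain beyond day 540
  expect_equal(body_weight(541, p) - body_weight(540, p), 0.32)
  expect_equal(body_weight(600, p) - body_weight(540, p), 60 * 0.32)

  # non-decreasing over the first two years
  expect_true(all(diff(body_weight(0:720, p)) >= 0))
  expect_error(body_weight(-1, p), "age")
})

test_that("daily gain follows the rate polynomial then the late constant", {
  p <- default_profile()
  expect_equal(daily_gain(0, p), 0.5584)
  expect_equal(daily_gain(600, p), 0.32)
  d <- 540
  expect_equal(daily_gain(540, p),
               0.5584 + 2 * 0.001787 * d - 3 * 1.549e-6 * d^2 -
                 4 * 1.332e-9 * d^3)
})

test_that("forage DMI is zero before day 66 then logarithmic, floored at 0", {
  p <- default_profile()
  expect_identical(forage_dmi(30, p), 0)
  expect_identical(forage_dmi(65, p), 0)
  expect_equal(forage_dmi(100, p), 5.4702 * log(100) - 22.889)
  expect_equal(forage_dmi(100, p), 2.3022, tolerance = 1e-4)
  expect_equal(forage_dmi(540, p), 11.527, tolerance = 1e-3)
  expect_true(all(forage_dmi(0:720, p) >= 0))
  # near-continuity at the intake threshold: the log curve crosses zero
  # close to day 66
  expect_lt(abs(forage_dmi(66, p) - 0), 0.1)
})

test_that("milk production follows the lactation quartic and stops at weaning", {
  p <- default_profile()
  expect_equal(milk_production(0, p), 1.445)
  expect_equal(milk_production(120, p), 7.4917, tolerance = 1e-4)
  expect_identical(milk_production(240, p), 0)
  expect_identical(milk_production(300, p), 0)
  expect_true(all(milk_production(0:720, p) >= 0))
})

test_that("milk DMI is the fluid production times the dry-matter fraction", {
  p <- default_profile()
  expect_equal(milk_dmi(0, p), 1.445 * 0.13)
  expect_identical(milk_dmi(250, p), 0)
  p1 <- default_profile(milk_dm_fraction = 0.9999)
  expect_equal(milk_dmi(100, p1), milk_production(100, p1) * 0.9999)
})

test_that("energy-balance calf forage intake reacts to forage quality", {
  p <- default_profile()
  # exact energy balance: milk supplies all the energy demand
  bw <- body_weight(100, p)
  dmi_m <- milk_dmi(100, p)
  expect_equal(calf_forage_dmi(100, p, dei = 4.87 * dmi_m / bw), 0)
  # direct substitution of the printed energy constants
  expect_equal(calf_forage_dmi(180, p),
               (0.0783 * body_weight(180, p) - 4.87 * milk_dmi(180, p)) / 2.27)
  # higher-quality forage (larger DE_F) means less forage needed
  expect_lt(calf_forage_dmi(180, p, de_forage = 3.18),
            calf_forage_dmi(180, p, de_forage = 2.27))
  expect_error(calf_forage_dmi(180, p, de_forage = 0), "de_forage")
})

test_that("water intake switches by animal class", {
  p <- default_profile()
  expect_equal(water_intake("nursing_calf", 2, p), 8)
  expect_equal(water_intake("finisher", 99, p), 40.84)
  expect_equal(water_intake("lactating_cow", 0, p), 56.47)
  expect_error(water_intake("goat", 1, p))
  expect_identical(animal_class(c(100, 239, 240, 500), p),
                   c("nursing_calf", "nursing_calf", "finisher", "finisher"))
})

test_that("soil ingestion is a fixed fraction of forage DMI", {
  p <- default_profile()
  expect_equal(soil_intake(10, p), 0.243)
  expect_identical(soil_intake(0, p), 0)
  expect_identical(soil_intake(10, default_profile(soil_fraction = 0)), 0)
})

test_that("profile validation rejects broken profiles and fills missing SDs", {
  expect_error(default_profile(half_life = -1), "half_life")
  expect_error(default_profile(muscle_body_ratio = 1.5), "muscle_body_ratio")
  expect_error(default_profile(nonsense = 1), "unknown")
  expect_error(default_profile(update_order = "midday"), "update_order")

  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(muscle_serum_ratio = 0.080), f)
  p <- load_profile(f)
  expect_equal(p$muscle_serum_ratio_sd, 0.016)   # 20% default
  expect_equal(p$half_life, 108.9)               # untouched default

  yaml::write_yaml(list(not_a_parameter = 1), f)
  expect_error(load_profile(f), "not_a_parameter")
})

test_that("profiles round-trip through YAML and JSON", {
  p <- default_profile(half_life = 99.5, update_order = "eliminate_first")
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_profile(p, f)
    q <- load_profile(f)
    expect_equal(unclass(q)[names(p)], unclass(p))
  }
})

test_that("the bundled default profile reproduces the reference parameters", {
  f <- system.file("extdata", "pfos_default_profile.yaml",
                   package = "dampfos")
  p <- load_profile(f)
  expect_equal(p$half_life, 108.9)
  expect_equal(p$half_life_sd, 40.5)
  expect_equal(p$muscle_body_ratio, 0.231)
  expect_equal(p$milk_transfer_factor, 0.0213)
})
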