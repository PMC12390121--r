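# Deterministic growth and intake submodels. All curves are evaluated at
# integer ages (day 0 = birth) and floor at zero outside their fitted
# ranges; body weight is integrated by one daily-gain step per day, matching
# the model's row-per-day structure.

#' Body weight at a given age
#'
#' Birth weight plus the cumulative sum of daily gains ([daily_gain()]) up
#' to the requested age: the discrete integral of the growth-rate
#' polynomial, which agrees with the closed-form quartic growth curve for
#' Holstein steers to within 0.5% over days 1-540. Beyond
#' `late_gain_start` (540 days) a constant gain (default 0.32 kg/day) is
#' added per day.
#'
#' @param age Age in integer days (vectorised); day 0 = birth.
#' @param profile A [default_profile()] parameter profile.
#' @return Body weight in kg.
#' @examples
#' body_weight(0)    # 35.45 kg at birth
#' body_weight(540)  # ~501 kg at typical slaughter age
#' @export
body_weight <- function(age, profile = default_profile()) {
  if (any(age < 0)) stop("age must be >= 0")
  age <- as.integer(age)
  ls <- profile$late_gain_start
  # cumulative gains over the polynomial phase, shared across the vector
  top <- min(max(age), ls)
  cum <- if (top >= 1) cumsum(daily_gain(seq_len(top), profile)) else numeric(0)
  poly_part <- ifelse(age >= 1, cum[pmin(pmax(age, 1), length(cum))], 0)
  poly_part[age == 0] <- 0
  profile$birth_weight + poly_part + pmax(age - ls, 0) * profile$late_gain
}

#' Daily body-weight gain at a given age
#'
#' The growth-rate cubic (the derivative of the quartic growth curve) for
#' ages up to `late_gain_start`; the constant `late_gain` afterwards.
#'
#' @inheritParams body_weight
#' @return Daily gain in kg/day.
#' @examples
#' daily_gain(0)    # 0.5584 kg/day at birth
#' daily_gain(600)  # 0.32 kg/day past day 540
#' @export
daily_gain <- function(age, profile = default_profile()) {
  if (any(age < 0)) stop("age must be >= 0")
  co <- profile$gain_coeffs
  g <- co[1] + co[2] * age + co[3] * age^2 + co[4] * age^3
  ifelse(age > profile$late_gain_start, profile$late_gain, g)
}

#' Forage dry-matter intake from birth to slaughter
#'
#' The single logarithmic intake curve covering calves and finishers:
#' zero before `dmi_start_day` (66 days, when meaningful forage intake
#' begins), then `slope * ln(age) + intercept`, floored at zero.
#'
#' @inheritParams body_weight
#' @return Forage dry-matter intake in kg DM/day.
#' @examples
#' forage_dmi(30)   # 0: nursing calf below the intake threshold
#' forage_dmi(540)  # ~11.5 kg DM/day at slaughter age
#' @export
forage_dmi <- function(age, profile = default_profile()) {
  if (any(age < 0)) stop("age must be >= 0")
  v <- profile$dmi_log_slope * log(pmax(age, 1)) + profile$dmi_log_intercept
  ifelse(age < profile$dmi_start_day, 0, pmax(v, 0))
}

#' Fluid milk production of the dam, indexed by calf age
#'
#' The quartic lactation curve (average of four NRC lactation curves),
#' floored at zero and zero from `weaning_day` (240 days) onwards. The
#' nursing calf is assumed to consume all of it.
#'
#' @param age_of_calf Calf age in days (vectorised).
#' @inheritParams body_weight
#' @return Fluid milk production in kg/day.
#' @export
milk_production <- function(age_of_calf, profile = default_profile()) {
  if (any(age_of_calf < 0)) stop("age_of_calf must be >= 0")
  co <- profile$milk_prod_coeffs
  d <- age_of_calf
  v <- co[1] + co[2] * d + co[3] * d^2 + co[4] * d^3 + co[5] * d^4
  ifelse(d >= profile$weaning_day, 0, pmax(v, 0))
}

#' Milk dry-matter intake of the nursing calf
#'
#' Fluid milk production times the dry-matter fraction of fluid milk
#' (default 13%).
#'
#' @inheritParams body_weight
#' @return Milk dry-matter intake in kg DM/day.
#' @export
milk_dmi <- function(age, profile = default_profile()) {
  milk_production(age, profile) * profile$milk_dm_fraction
}

#' Energy-balance derivation of nursing-calf forage intake
#'
#' The digestible-energy budget behind the pre-weaning portion of the
#' combined forage-intake curve: forage DMI = (DEI x BW - DE_M x DMI_M) /
#' DE_F, floored at zero, where DEI is the daily digestible-energy intake
#' per kg body weight, DMI_M the milk dry-matter intake, and DE_M / DE_F
#' the digestible energy of milk and forage. This documents how the default
#' intake curve was derived; the simulator itself uses [forage_dmi()].
#'
#' @inheritParams body_weight
#' @param dei Daily digestible-energy intake, Mcal per kg BW per day.
#' @param de_milk Digestible energy of milk dry matter, Mcal/kg.
#' @param de_forage Digestible energy of forage dry matter, Mcal/kg. The
#'   default of 2.27 (a 50-forage average) is conservative: a high-quality
#'   forage such as alfalfa (3.18) yields a smaller forage DMI for the same
#'   energy deficit.
#' @return Forage dry-matter intake in kg DM/day.
#' @export
calf_forage_dmi <- function(age, profile = default_profile(),
                            dei = profile$dei, de_milk = profile$de_milk,
                            de_forage = profile$de_forage) {
  if (any(age < 0) || any(age > profile$weaning_day)) {
    stop("age must be in [0, weaning_day]")
  }
  if (de_forage <= 0) stop("de_forage must be > 0")
  bw <- body_weight(age, profile)
  pmax((dei * bw - de_milk * milk_dmi(age, profile)) / de_forage, 0)
}

#' Drinking-water intake by animal class
#'
#' Nursing calves drink 4 L per kg of forage dry matter ingested (milk
#' water excluded); finishers and lactating cows use NRC
#' temperature-averaged constants (40.84 and 56.47 L/day).
#'
#' @param animal_class One of `"nursing_calf"`, `"finisher"`,
#'   `"lactating_cow"`.
#' @param forage_dmi Forage dry-matter intake in kg DM/day (used only for
#'   nursing calves).
#' @inheritParams body_weight
#' @return Water intake in L/day.
#' @export
water_intake <- function(animal_class, forage_dmi = 0,
                         profile = default_profile()) {
  if (any(forage_dmi < 0)) stop("forage_dmi must be >= 0")
  animal_class <- match.arg(animal_class,
                            c("nursing_calf", "finisher", "lactating_cow"))
  switch(animal_class,
    nursing_calf  = profile$water_rate_calf * forage_dmi,
    finisher      = rep_len(profile$water_finisher, max(1, length(forage_dmi))),
    lactating_cow = rep_len(profile$water_lactating_cow,
                            max(1, length(forage_dmi)))
  )
}

#' Incidental soil ingestion while grazing
#'
#' A fixed fraction (default 2.43%) of forage dry-matter intake.
#'
#' @inheritParams water_intake
#' @return Soil ingestion in kg/day.
#' @export
soil_intake <- function(forage_dmi, profile = default_profile()) {
  if (any(forage_dmi < 0)) stop("forage_dmi must be >= 0")
  profile$soil_fraction * forage_dmi
}

#' Dam (cow) forage dry-matter intake, indexed by calf age
#'
#' The quadratic lactating-cow intake curve used for the milk-transfer
#' pathway, floored at zero.
#'
#' @inheritParams milk_production
#' @return Cow forage dry-matter intake in kg DM/day.
#' @export
cow_dmi <- function(age_of_calf, profile = default_profile()) {
  if (any(age_of_calf < 0)) stop("age_of_calf must be >= 0")
  co <- profile$cow_dmi_coeffs
  pmax(co[1] + co[2] * age_of_calf + co[3] * age_of_calf^2, 0)
}

#' Animal class at a given age
#'
#' Nursing calf before `weaning_day`, finisher afterwards. (The
#' `lactating_cow` class applies to the dam, not the simulated animal.)
#'
#' @inheritParams body_weight
#' @return Character vector of class labels.
#' @export
animal_class <- function(age, profile = default_profile()) {
  ifelse(age < profile$weaning_day, "nursing_calf", "finisher")
}
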