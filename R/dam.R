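# The daily accumulation loop: a one-compartment mass balance kept as a
# running log, adding the day's dietary PFOS mass and removing a
# first-order (half-life) elimination each day, with static tissue
# partitioning into muscle and serum.

#' Daily first-order elimination
#'
#' The mass eliminated in one day from a body burden under a first-order
#' half-life: `burden * (1 - 0.5^(1/half_life))`. Always between 0 and the
#' burden.
#'
#' @param body_burden PFOS mass in the body, ug (vectorised).
#' @param half_life Elimination half-life in days (> 0).
#' @return Mass eliminated in ug/day.
#' @examples
#' daily_elimination(10, 1)        # a one-day half-life removes half
#' daily_elimination(1000, 108.9)  # ~6.35 ug/day
#' @export
daily_elimination <- function(body_burden, half_life) {
  if (any(half_life <= 0)) stop("half_life must be > 0")
  if (any(body_burden < 0)) stop("body_burden must be >= 0")
  body_burden * (1 - 0.5^(1 / half_life))
}

#' PFOS mass in muscle
#'
#' The muscle:body partition ratio times the whole-body burden.
#'
#' @inheritParams daily_elimination
#' @param profile A [default_profile()].
#' @return PFOS mass in muscle, ug.
#' @export
muscle_mass_of_pfos <- function(body_burden, profile = default_profile()) {
  if (any(body_burden < 0)) stop("body_burden must be >= 0")
  profile$muscle_body_ratio * body_burden
}

#' PFOS concentration in muscle
#'
#' Muscle PFOS mass divided by muscle mass, where muscle mass is the
#' muscle fraction of body weight times body weight.
#'
#' @inheritParams muscle_mass_of_pfos
#' @param body_weight Body weight in kg (> 0).
#' @return Muscle concentration in ug/kg.
#' @export
muscle_concentration <- function(body_burden, body_weight,
                                 profile = default_profile()) {
  if (any(body_weight <= 0)) stop("body_weight must be > 0")
  muscle_mass_of_pfos(body_burden, profile) /
    (profile$muscle_bw_fraction * body_weight)
}

#' PFOS concentration in serum
#'
#' The muscle:serum ratio is the muscle concentration expressed as a
#' fraction of the serum concentration (PFOS partitions strongly into
#' serum), so serum = muscle / ratio.
#'
#' @param muscle_conc Muscle concentration, ug/kg.
#' @inheritParams muscle_mass_of_pfos
#' @return Serum concentration in ug/kg.
#' @export
serum_concentration <- function(muscle_conc, profile = default_profile()) {
  if (profile$muscle_serum_ratio <= 0) stop("muscle_serum_ratio must be > 0")
  if (any(muscle_conc < 0)) stop("muscle_conc must be >= 0")
  muscle_conc / profile$muscle_serum_ratio
}

#' Simulate the daily accumulation model
#'
#' Runs the day-per-row mass balance over an exposure scenario. Day `d`
#' (age `d` days) adds the day's dietary intake ([daily_intake()]) to the
#' burden and removes one day's first-order elimination; with the default
#' `update_order = "intake_first"` the elimination acts on the post-intake
#' burden, with `"eliminate_first"` on the carried-over burden. States
#' (body weight, per-route intakes, burden, muscle and serum
#' concentrations) are recorded end-of-day, after elimination.
#'
#' @param scenario An [exposure_scenario()].
#' @param profile A [default_profile()].
#' @return An object of class `dam_result`: a list with `trajectory` (a
#'   data.frame, one row per day, columns `day`, `age`, `body_weight`,
#'   `intake_forage`, `intake_water`, `intake_soil`, `intake_milk`,
#'   `intake_total`, `eliminated`, `body_burden`, `muscle_conc`,
#'   `serum_conc`), `slaughter_day`, `final_muscle_conc`,
#'   `final_serum_conc`, `final_body_burden`, `final_body_weight`.
#' @examples
#' res <- simulate_dam(build_generic(0.270, 540))
#' res$final_muscle_conc  # ~0.5 ug/kg at slaughter
#' @export
simulate_dam <- function(scenario, profile = default_profile()) {
  duration <- attr(scenario, "duration")
  days <- seq_len(duration)
  intakes <- daily_intake(days, scenario, profile)
  bw <- body_weight(days, profile)
  frac_retained <- 0.5^(1 / profile$half_life)
  intake_first <- identical(profile$update_order, "intake_first")

  burden <- numeric(duration)
  eliminated <- numeric(duration)
  b <- attr(scenario, "initial_body_burden")
  for (d in days) {
    if (intake_first) {
      pre <- b + intakes$total[d]
      eliminated[d] <- pre * (1 - frac_retained)
      b <- pre - eliminated[d]
    } else {
      eliminated[d] <- b * (1 - frac_retained)
      b <- b - eliminated[d] + intakes$total[d]
    }
    burden[d] <- b
  }

  muscle <- muscle_concentration(burden, bw, profile)
  serum <- serum_concentration(muscle, profile)
  traj <- data.frame(
    day = days, age = days, body_weight = bw,
    intake_forage = intakes$forage, intake_water = intakes$water,
    intake_soil = intakes$soil, intake_milk = intakes$milk,
    intake_total = intakes$total, eliminated = eliminated,
    body_burden = burden, muscle_conc = muscle, serum_conc = serum
  )
  structure(list(
    trajectory = traj,
    slaughter_day = duration,
    final_muscle_conc = muscle[duration],
    final_serum_conc = serum[duration],
    final_body_burden = burden[duration],
    final_body_weight = bw[duration]
  ), class = "dam_result")
}

#' @export
print.dam_result <- function(x, ...) {
  cat("<dam_result> daily accumulation model trajectory\n")
  cat(sprintf("  %d days simulated; final body weight %.1f kg\n",
              x$slaughter_day, x$final_body_weight))
  cat(sprintf("  final body burden %.3g ug; muscle %.4g ug/kg; serum %.4g ug/kg\n",
              x$final_body_burden, x$final_muscle_conc, x$final_serum_conc))
  invisible(x)
}

#' Bioaccumulation factor
#'
#' Muscle concentration at slaughter divided by the concentration of the
#' total ration the animal was raised on (both ug/kg), the feed-to-tissue
#' transfer summary used for screening.
#'
#' @param final_muscle_conc Muscle concentration at slaughter, ug/kg.
#' @param ration_conc Ration concentration, ug/kg (> 0).
#' @return Unitless BAF.
#' @examples
#' bioaccumulation_factor(0.501, 0.270)  # ~1.86
#' @export
bioaccumulation_factor <- function(final_muscle_conc, ration_conc) {
  if (any(ration_conc <= 0)) stop("ration_conc must be > 0")
  if (any(final_muscle_conc < 0)) stop("final_muscle_conc must be >= 0")
  final_muscle_conc / ration_conc
}

#' Solve the ration concentration giving a target muscle residue
#'
#' With zero initial burden the model is linear in the exposure
#' concentrations, so the deterministic inverse problem is solved exactly
#' by one simulation at unit ration concentration: the answer is
#' `target / unit_response`. The result is verified by re-simulation to
#' within `1e-6` relative error.
#'
#' @param target_muscle_conc Target muscle concentration at slaughter,
#'   ug/kg (> 0).
#' @param slaughter_day Slaughter age in days (default 540).
#' @param profile A [default_profile()].
#' @return Ration concentration in ug/kg.
#' @examples
#' solve_ration_for_target(0.5, 540)  # ~0.27 ug/kg
#' @export
solve_ration_for_target <- function(target_muscle_conc, slaughter_day = 540,
                                    profile = default_profile()) {
  if (target_muscle_conc <= 0) stop("target_muscle_conc must be > 0")
  unit <- simulate_dam(build_generic(1, slaughter_day), profile)
  if (unit$final_muscle_conc <= 0) {
    stop("unit ration produces no muscle residue; cannot invert")
  }
  ration <- target_muscle_conc / unit$final_muscle_conc
  check <- simulate_dam(build_generic(ration, slaughter_day), profile)
  rel <- abs(check$final_muscle_conc - target_muscle_conc) /
    target_muscle_conc
  if (rel > 1e-6) {
    stop("inverse solution failed verification (relative error ",
         format(rel), ")")
  }
  ration
}
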