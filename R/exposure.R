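# Exposure scenarios (day-indexed media concentrations) and their
# conversion, through the physiology submodels, into daily PFOS mass
# intake with a per-route breakdown. The nursing-calf milk pathway runs
# through the dam: her daily intake times the milk transfer factor gives
# the fluid-milk concentration the calf drinks.

#' Construct an exposure scenario
#'
#' A scenario is a day-indexed table of PFOS concentrations in the media
#' the animal (and, pre-weaning, its dam) is exposed to. Day `d` of the
#' table (1..duration) holds the concentrations in effect during the
#' animal's `d`-th day of life; piecewise-constant feeding histories are
#' the canonical representation (see [scenario_from_segments()]).
#'
#' @param duration Scenario length in days (>= 1).
#' @param forage_conc PFOS in the animal's forage, ug/kg DM. Scalar or
#'   vector of length `duration`.
#' @param water_conc PFOS in drinking water, ug/L.
#' @param soil_conc PFOS in ingested soil, ug/kg.
#' @param cow_forage_conc PFOS in the dam's feed, ug/kg DM (drives the
#'   milk pathway). Defaults to `forage_conc` (herd shares the ration).
#' @param cow_water_conc PFOS in the dam's drinking water, ug/L.
#' @param initial_body_burden PFOS mass in the calf at birth, ug
#'   (default 0; fetal transfer can be expressed by setting it).
#' @return An object of class `exposure_scenario`: a data.frame with
#'   columns `day`, `forage_conc`, `water_conc`, `soil_conc`,
#'   `cow_forage_conc`, `cow_water_conc` and attributes `duration` and
#'   `initial_body_burden`.
#' @examples
#' sc <- exposure_scenario(540, forage_conc = 0.27)
#' attr(sc, "duration")
#' @export
exposure_scenario <- function(duration, forage_conc = 0, water_conc = 0,
                              soil_conc = 0, cow_forage_conc = forage_conc,
                              cow_water_conc = water_conc,
                              initial_body_burden = 0) {
  duration <- as.integer(duration)
  if (duration < 1) stop("duration must be >= 1 day")
  if (initial_body_burden < 0) stop("initial_body_burden must be >= 0")
  expand <- function(x, nm) {
    if (length(x) == 1) x <- rep(x, duration)
    if (length(x) != duration) {
      stop(nm, " must have length 1 or duration (", duration, ")")
    }
    if (any(is.na(x)) || any(x < 0)) stop(nm, " must be >= 0 for every day")
    as.numeric(x)
  }
  df <- data.frame(
    day = seq_len(duration),
    forage_conc = expand(forage_conc, "forage_conc"),
    water_conc = expand(water_conc, "water_conc"),
    soil_conc = expand(soil_conc, "soil_conc"),
    cow_forage_conc = expand(cow_forage_conc, "cow_forage_conc"),
    cow_water_conc = expand(cow_water_conc, "cow_water_conc")
  )
  structure(df, duration = duration,
            initial_body_burden = as.numeric(initial_body_burden),
            class = c("exposure_scenario", "data.frame"))
}

#' Build an exposure scenario from piecewise-constant segments
#'
#' Feeding histories are naturally piecewise constant (seasonal feed
#' changes, depuration on clean feed). Each segment row gives the
#' concentrations in force from `start_day` to `end_day` inclusive
#' (1-based days of life).
#'
#' @param segments A data.frame with columns `start_day`, `end_day`, and
#'   any of `forage_conc`, `water_conc`, `soil_conc`, `cow_forage_conc`,
#'   `cow_water_conc` (missing media default to 0; a missing
#'   `cow_forage_conc` defaults to the segment's `forage_conc`). Segments
#'   must tile `1..duration` without gaps or overlaps.
#' @param duration Total days; defaults to `max(segments$end_day)`.
#' @inheritParams exposure_scenario
#' @return An `exposure_scenario`.
#' @export
scenario_from_segments <- function(segments, duration = max(segments$end_day),
                                   initial_body_burden = 0) {
  if (!all(c("start_day", "end_day") %in% names(segments))) {
    stop("segments need start_day and end_day columns")
  }
  segments <- segments[order(segments$start_day), , drop = FALSE]
  if (segments$start_day[1] != 1 ||
      any(segments$start_day[-1] != utils::head(segments$end_day, -1) + 1) ||
      max(segments$end_day) < duration) {
    stop("segments must tile days 1..duration without gaps or overlaps")
  }
  col <- function(nm, default) {
    if (nm %in% names(segments)) segments[[nm]] else
      rep(default, length.out = nrow(segments))
  }
  fc <- col("forage_conc", 0)
  vals <- list(forage_conc = fc,
               water_conc = col("water_conc", 0),
               soil_conc = col("soil_conc", 0),
               cow_forage_conc = col("cow_forage_conc", fc),
               cow_water_conc = col("cow_water_conc", 0))
  len <- pmin(segments$end_day, duration) - segments$start_day + 1
  keep <- len > 0
  daily <- lapply(vals, function(v) rep(v[keep], times = len[keep]))
  exposure_scenario(duration,
                    forage_conc = daily$forage_conc,
                    water_conc = daily$water_conc,
                    soil_conc = daily$soil_conc,
                    cow_forage_conc = daily$cow_forage_conc,
                    cow_water_conc = daily$cow_water_conc,
                    initial_body_burden = initial_body_burden)
}

#' Daily PFOS intake of the dam
#'
#' The lactating cow's PFOS intake from her forage, drinking water and
#' incidental soil ingestion, evaluated at the calf's age (her intake
#' curve is indexed by days since calving). Used only for the milk
#' pathway; the dam's own kinetics are not modelled.
#'
#' @param age_of_calf Calf age in days (< weaning day).
#' @param scenario An [exposure_scenario()].
#' @param profile A [default_profile()].
#' @return PFOS intake in ug/day.
#' @export
cow_daily_intake <- function(age_of_calf, scenario,
                             profile = default_profile()) {
  row <- scenario_row(scenario, age_of_calf)
  dmi <- cow_dmi(age_of_calf, profile)
  dmi * row$cow_forage_conc +
    profile$water_lactating_cow * row$cow_water_conc +
    profile$soil_fraction * dmi * row$soil_conc
}

#' Fluid-milk PFOS concentration from the dam's intake
#'
#' The milk transfer factor (d/kg) maps the dam's current daily PFOS
#' intake (ug/day) to her fluid-milk concentration (ug/kg); her milk
#' responds instantaneously to her intake.
#'
#' @param cow_intake Dam's PFOS intake, ug/day.
#' @param profile A [default_profile()].
#' @return Milk concentration in ug/kg fluid milk.
#' @export
milk_concentration <- function(cow_intake, profile = default_profile()) {
  if (any(cow_intake < 0)) stop("cow_intake must be >= 0")
  profile$milk_transfer_factor * cow_intake
}

# internal: scenario row for a 1-based day of life
scenario_row <- function(scenario, age) {
  duration <- attr(scenario, "duration")
  if (any(age < 1) || any(age > duration)) {
    stop("age ", paste(age[age < 1 | age > duration], collapse = ","),
         " outside scenario duration ", duration)
  }
  scenario[age, , drop = FALSE]
}

#' Daily PFOS mass intake with per-route breakdown
#'
#' Combines the physiological intake rates with the scenario
#' concentrations on a given day of life: forage, drinking water,
#' incidental soil, and (before weaning) milk via the dam. Routes sum
#' exactly to the total, and the total is scaled by the gut absorption
#' fraction.
#'
#' @param age Day of life, 1..duration (vectorised).
#' @inheritParams cow_daily_intake
#' @return A data.frame with columns `age`, `forage`, `water`, `soil`,
#'   `milk`, `total` (all ug/day).
#' @examples
#' sc <- build_generic(ration_conc = 0.27, slaughter_day = 540)
#' daily_intake(300, sc)  # post-weaning: all intake via forage
#' @export
daily_intake <- function(age, scenario, profile = default_profile()) {
  row <- scenario_row(scenario, age)
  dmi <- forage_dmi(age, profile)
  cls <- animal_class(age, profile)
  wi <- ifelse(cls == "nursing_calf",
               profile$water_rate_calf * dmi, profile$water_finisher)
  nursing <- age < profile$weaning_day
  milk_rate <- milk_production(age, profile)
  mc <- ifelse(nursing,
               milk_concentration(cow_daily_intake(age, scenario, profile),
                                  profile),
               0)
  af <- profile$absorption_fraction
  out <- data.frame(
    age = age,
    forage = af * dmi * row$forage_conc,
    water = af * wi * row$water_conc,
    soil = af * soil_intake(dmi, profile) * row$soil_conc,
    milk = af * milk_rate * mc
  )
  out$total <- out$forage + out$water + out$soil + out$milk
  rownames(out) <- NULL
  out
}

#' Read / write exposure scenarios
#'
#' Scenarios are stored as a piecewise-segment CSV (columns `start_day`,
#' `end_day`, `forage_conc`, `water_conc`, `soil_conc`, `cow_forage_conc`,
#' `cow_water_conc`) plus a YAML header file carrying `duration` and
#' `initial_body_burden`. `write_scenario()` compresses the day-indexed
#' table back into maximal constant segments.
#'
#' @param path CSV path; the YAML header is `<path>.yaml`.
#' @return `read_scenario()` returns an `exposure_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  seg <- utils::read.csv(path)
  hdr_path <- paste0(path, ".yaml")
  hdr <- if (file.exists(hdr_path)) yaml::read_yaml(hdr_path) else list()
  duration <- if (!is.null(hdr$duration)) hdr$duration else max(seg$end_day)
  ibb <- if (!is.null(hdr$initial_body_burden)) hdr$initial_body_burden else 0
  scenario_from_segments(seg, duration = duration,
                         initial_body_burden = ibb)
}

#' @rdname read_scenario
#' @param scenario An `exposure_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  media <- c("forage_conc", "water_conc", "soil_conc", "cow_forage_conc",
             "cow_water_conc")
  m <- as.matrix(scenario[media])
  change <- c(TRUE, rowSums(abs(m[-1, , drop = FALSE] -
                                m[-nrow(m), , drop = FALSE])) > 0)
  starts <- which(change)
  ends <- c(starts[-1] - 1, nrow(m))
  seg <- data.frame(start_day = starts, end_day = ends,
                    m[starts, , drop = FALSE], row.names = NULL)
  utils::write.csv(seg, path, row.names = FALSE)
  yaml::write_yaml(list(duration = attr(scenario, "duration"),
                        initial_body_burden =
                          attr(scenario, "initial_body_burden")),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("<exposure_scenario> %d days, initial burden %.3g ug\n",
              attr(x, "duration"), attr(x, "initial_body_burden")))
  rng <- function(nm) sprintf("%s %.3g-%.3g", nm, min(x[[nm]]), max(x[[nm]]))
  cat("  ", paste(vapply(c("forage_conc", "water_conc", "soil_conc",
                           "cow_forage_conc"), rng, ""), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
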