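#' Default DAM parameter profile for PFOS in beef cattle
#'
#' Builds the bundled parameter profile: the single source of truth for a
#' simulation run. Every constant and distribution used by the physiology,
#' exposure, core-loop and Monte Carlo layers lives here, so a run is fully
#' described by a profile plus an exposure scenario (plus a seed for
#' probabilistic runs).
#'
#' The defaults are the literature-derived values for PFOS in beef cattle:
#' a weight-of-evidence elimination half-life of 108.9 +/- 40.5 days, a
#' muscle:body PFOS partition ratio of 0.231 +/- 0.090, a muscle mass
#' fraction of 0.361 +/- 0.117 kg muscle per kg body weight, a muscle:serum
#' concentration ratio of 0.080 +/- 0.016, NRC-derived growth and intake
#' curves, and a milk transfer factor of 0.0213 d/kg from the dam's daily
#' PFOS intake to her fluid-milk concentration.
#'
#' @param ... Named overrides for any profile field, e.g.
#'   `default_profile(half_life = 120, update_order = "eliminate_first")`.
#'
#' @return An object of class `dam_profile`: a named list of parameters.
#'   Fields are grouped by role:
#' \describe{
#'   \item{Growth}{`birth_weight` (kg), `birth_weight_sd`, `gain_coeffs`
#'     (cubic polynomial in age, kg/day), `gain_cv` (relative SD of the
#'     daily gain), `late_gain` and `late_gain_sd` (kg/day beyond
#'     `late_gain_start` = 540 days).}
#'   \item{Intake}{`dmi_log_slope`/`dmi_log_intercept` (forage dry-matter
#'     intake, kg = slope * ln(age) + intercept, zero before
#'     `dmi_start_day`), `dmi_sd_per_bw` (absolute SD as a fraction of body
#'     weight), `cow_dmi_coeffs` (quadratic in calf age, kg) and
#'     `cow_dmi_cv`, `milk_prod_coeffs` (quartic in calf age, kg fluid
#'     milk) and `milk_prod_cv`, `milk_dm_fraction`, `weaning_day`,
#'     `soil_fraction` (soil ingested as a fraction of forage DMI) and
#'     `soil_sd_per_dmi`, `water_rate_calf` (L per kg forage DMI),
#'     `water_finisher` and `water_lactating_cow` (L/day) with their SDs.}
#'   \item{Transfer}{`milk_transfer_factor` (d/kg), `absorption_fraction`
#'     (gut absorption, default 1).}
#'   \item{Partitioning}{`half_life` (days), `muscle_body_ratio`,
#'     `muscle_bw_fraction`, `muscle_serum_ratio`, each with `_sd`.}
#'   \item{Energy-balance documentation path}{`dei` (Mcal/kg BW/day),
#'     `de_milk`, `de_forage` (Mcal/kg), used by [calf_forage_dmi()].}
#'   \item{Simulation}{`update_order` (`"intake_first"` or
#'     `"eliminate_first"`), `trunc_lo`/`trunc_hi` (Monte Carlo truncation
#'     quantiles, default 5th/95th).}
#' }
#'
#' @examples
#' p <- default_profile()
#' p$half_life
#' body_weight(540, p)
#' @seealso [load_profile()], [write_profile()], [simulate_dam()]
#' @export
default_profile <- function(...) {
  p <- list(
    # growth
    birth_weight = 35.45, birth_weight_sd = 3.27,
    gain_coeffs = c(0.5584, 2 * 0.001787, -3 * 1.549e-6, -4 * 1.332e-9),
    gain_cv = 0.35,
    late_gain = 0.32, late_gain_sd = 0.112, late_gain_start = 540,
    # intake
    dmi_log_slope = 5.4702, dmi_log_intercept = -22.889,
    dmi_start_day = 66, dmi_sd_per_bw = 0.0013,
    cow_dmi_coeffs = c(11.697, 0.0196, -1e-4), cow_dmi_cv = 0.062,
    milk_prod_coeffs = c(1.445, 0.3024, -0.003686, 0.0000163, -0.0000000257),
    milk_prod_cv = 0.355,
    milk_dm_fraction = 0.13, weaning_day = 240,
    soil_fraction = 0.0243, soil_sd_per_dmi = 0.005,
    water_rate_calf = 4,
    water_finisher = 40.84, water_finisher_sd = 12.87,
    water_lactating_cow = 56.47, water_lactating_cow_sd = 8.16,
    # transfer
    milk_transfer_factor = 0.0213, absorption_fraction = 1,
    # partitioning / kinetics
    half_life = 108.9, half_life_sd = 40.5,
    muscle_body_ratio = 0.231, muscle_body_ratio_sd = 0.090,
    muscle_bw_fraction = 0.361, muscle_bw_fraction_sd = 0.117,
    muscle_serum_ratio = 0.080, muscle_serum_ratio_sd = 0.016,
    # digestible-energy constants behind the calf forage DMI derivation
    dei = 0.0783, de_milk = 4.87, de_forage = 2.27,
    # simulation configuration
    update_order = "intake_first",
    trunc_lo = 0.05, trunc_hi = 0.95
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown profile field(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_profile(structure(p, class = "dam_profile"))
}

# Required fields and the predicate each must satisfy; *_sd fields are
# optional on disk (filled by the 20%-of-value default in load_profile).
profile_required <- function() {
  c(
    "birth_weight", "gain_coeffs", "gain_cv", "late_gain", "late_gain_start",
    "dmi_log_slope", "dmi_log_intercept", "dmi_start_day",
    "cow_dmi_coeffs", "milk_prod_coeffs", "milk_dm_fraction", "weaning_day",
    "soil_fraction", "water_rate_calf", "water_finisher",
    "water_lactating_cow", "milk_transfer_factor", "absorption_fraction",
    "half_life", "muscle_body_ratio", "muscle_bw_fraction",
    "muscle_serum_ratio", "update_order", "trunc_lo", "trunc_hi"
  )
}

#' Validate a DAM parameter profile
#'
#' Checks presence of every required field and the physical invariants
#' (positive half-life and weights, ratios in their valid ranges, truncation
#' quantiles ordered within (0, 1)). Called by [default_profile()] and
#' [load_profile()]; exported so hand-built profiles can be checked too.
#'
#' @param profile A `dam_profile` or plain named list.
#' @return The validated profile (invisibly classed as `dam_profile`).
#' @export
validate_profile <- function(profile) {
  miss <- setdiff(profile_required(), names(profile))
  if (length(miss)) {
    stop("profile is missing required field(s): ", paste(miss, collapse = ", "))
  }
  chk <- function(cond, field, what) {
    if (!isTRUE(all(cond))) stop("invalid profile field '", field, "': ", what)
  }
  chk(profile$birth_weight > 0, "birth_weight", "must be > 0")
  chk(profile$late_gain > 0, "late_gain", "must be > 0")
  chk(profile$half_life > 0, "half_life", "must be > 0")
  chk(profile$muscle_body_ratio > 0 && profile$muscle_body_ratio < 1,
      "muscle_body_ratio", "must be in (0, 1)")
  chk(profile$muscle_bw_fraction > 0 && profile$muscle_bw_fraction < 1,
      "muscle_bw_fraction", "must be in (0, 1)")
  chk(profile$muscle_serum_ratio > 0, "muscle_serum_ratio", "must be > 0")
  chk(profile$milk_dm_fraction > 0 && profile$milk_dm_fraction < 1,
      "milk_dm_fraction", "must be in (0, 1)")
  chk(profile$soil_fraction >= 0 && profile$soil_fraction < 0.1,
      "soil_fraction", "must be in [0, 0.1)")
  chk(profile$dmi_start_day < profile$weaning_day,
      "dmi_start_day", "must be < weaning_day")
  chk(profile$absorption_fraction > 0 && profile$absorption_fraction <= 1,
      "absorption_fraction", "must be in (0, 1]")
  chk(profile$milk_transfer_factor >= 0, "milk_transfer_factor", "must be >= 0")
  chk(length(profile$gain_coeffs) == 4, "gain_coeffs", "must have 4 coefficients")
  chk(length(profile$cow_dmi_coeffs) == 3, "cow_dmi_coeffs",
      "must have 3 coefficients")
  chk(length(profile$milk_prod_coeffs) == 5, "milk_prod_coeffs",
      "must have 5 coefficients")
  chk(profile$update_order %in% c("intake_first", "eliminate_first"),
      "update_order", "must be 'intake_first' or 'eliminate_first'")
  chk(profile$trunc_lo > 0 && profile$trunc_hi < 1 &&
        profile$trunc_lo < profile$trunc_hi,
      "trunc_lo/trunc_hi", "must satisfy 0 < lo < hi < 1")
  sds <- grep("_sd$", names(profile), value = TRUE)
  for (f in sds) chk(profile[[f]] >= 0, f, "must be >= 0")
  invisible(structure(profile, class = "dam_profile"))
}

#' Read a parameter profile from a flat YAML or JSON document
#'
#' The on-disk format is a flat key-value document whose keys are the
#' profile field names (vectors such as the polynomial coefficient sets are
#' YAML/JSON sequences). Any missing `<field>_sd` whose base field is
#' present is filled with the default of 20 percent of the field value, the
#' convention used when a literature SD is unavailable. Missing required
#' fields are a hard error naming the field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` profile document.
#' @return A validated `dam_profile`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_profile(default_profile(), f)
#' p <- load_profile(f)
#' stopifnot(p$half_life == 108.9)
#' @export
load_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || is.null(names(raw))) {
    stop("malformed profile document (expected a flat key-value mapping): ",
         path)
  }
  known <- names(default_profile())
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown profile key(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  p <- default_profile()
  p[names(raw)] <- lapply(raw, function(x) unlist(x, use.names = FALSE))
  p$update_order <- as.character(p$update_order)
  # fill missing SDs at 20% of the value for scalar-valued fields
  for (f in grep("_sd$", names(p), value = TRUE)) {
    base <- sub("_sd$", "", f)
    if (is.null(raw[[f]]) && !is.null(raw[[base]]) && length(p[[base]]) == 1L) {
      p[[f]] <- 0.2 * abs(p[[base]])
    }
  }
  validate_profile(p)
}

#' Write a parameter profile as a flat YAML or JSON document
#'
#' @param profile A `dam_profile`.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   anything else YAML).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  profile <- validate_profile(profile)
  x <- unclass(profile)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' @export
print.dam_profile <- function(x, ...) {
  cat("<dam_profile> PFOS daily accumulation model parameters\n")
  cat(sprintf("  half-life           : %.1f +/- %.1f d\n",
              x$half_life, x$half_life_sd))
  cat(sprintf("  muscle:body ratio   : %.3f +/- %.3f\n",
              x$muscle_body_ratio, x$muscle_body_ratio_sd))
  cat(sprintf("  muscle BW fraction  : %.3f +/- %.3f kg/kg\n",
              x$muscle_bw_fraction, x$muscle_bw_fraction_sd))
  cat(sprintf("  muscle:serum ratio  : %.3f +/- %.3f\n",
              x$muscle_serum_ratio, x$muscle_serum_ratio_sd))
  cat(sprintf("  birth weight        : %.2f +/- %.2f kg\n",
              x$birth_weight, x$birth_weight_sd))
  cat(sprintf("  milk transfer factor: %.4f d/kg\n", x$milk_transfer_factor))
  cat(sprintf("  weaning day %d | forage DMI from day %d | update order %s\n",
              x$weaning_day, x$dmi_start_day, x$update_order))
  invisible(x)
}
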