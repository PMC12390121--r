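# Canonical scenario builders: the constant-ration lifetime ("generic")
# scenario used to derive bioaccumulation factors, a synthetic
# feeding-history generator emulating seasonal piecewise exposures with a
# terminal depuration period, and the inverse problem of finding the
# ration concentration that meets a regulatory tissue level.

#' Generic constant-ration lifetime scenario
#'
#' The whole herd (the animal and its dam) eats a ration with a constant
#' PFOS concentration from birth to slaughter; water and soil
#' concentrations are zero, so the entire exposure is dietary. The nursing
#' phase is exposed through the dam's milk (she eats the same ration).
#'
#' @param ration_conc PFOS concentration of the total ration, ug/kg DM
#'   (>= 0).
#' @param slaughter_day Slaughter age in days (default 540, an 18-month
#'   lifespan).
#' @return An [exposure_scenario()].
#' @examples
#' sc <- build_generic(0.270, 540)
#' simulate_dam(sc)$final_muscle_conc  # ~0.5 ug/kg
#' @export
build_generic <- function(ration_conc, slaughter_day = 540) {
  if (ration_conc < 0) stop("ration_conc must be >= 0")
  if (slaughter_day < 1) stop("slaughter_day must be >= 1")
  exposure_scenario(slaughter_day, forage_conc = ration_conc,
                    cow_forage_conc = ration_conc)
}

#' Synthetic piecewise feeding history
#'
#' Generates an exposure scenario emulating a real farm feeding history:
#' the lifetime is split into equal segments (seasonal feed sources) whose
#' base concentrations are drawn uniformly from `segment_conc_range`;
#' day-to-day within-field variability is added as truncated multiplicative
#' noise at CV `within_field_cv`; an optional terminal depuration period
#' runs on PFOS-free feed. The dam shares the animal's feed. Reproducible
#' under `seed`.
#'
#' @param duration Total days (default 540).
#' @param n_segments Number of constant-feed segments before depuration
#'   (>= 1).
#' @param segment_conc_range Length-2 range (ug/kg) for the uniform
#'   segment concentrations.
#' @param within_field_cv Relative day-to-day SD of the realised feed
#'   concentration (default 0.40, the observed within-field variation).
#' @param depuration_days Days of zero-PFOS feed before slaughter
#'   (default 0).
#' @param seed Integer seed (required).
#' @return An [exposure_scenario()].
#' @examples
#' sc <- build_synthetic_history(n_segments = 4,
#'                               segment_conc_range = c(0.5, 3),
#'                               depuration_days = 120, seed = 7)
#' @export
build_synthetic_history <- function(duration = 540, n_segments = 3,
                                    segment_conc_range = c(0.1, 2),
                                    within_field_cv = 0.40,
                                    depuration_days = 0, seed) {
  if (missing(seed)) stop("a seed is required for a reproducible history")
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (within_field_cv < 0) stop("within_field_cv must be >= 0")
  if (depuration_days < 0 || depuration_days > duration) {
    stop("depuration_days must be in [0, duration]")
  }
  set.seed(as.integer(seed))
  exposed <- duration - depuration_days
  conc <- numeric(duration)
  if (exposed > 0) {
    bounds <- floor(seq(0, exposed, length.out = n_segments + 1))
    base <- stats::runif(n_segments, segment_conc_range[1],
                         segment_conc_range[2])
    daily <- rep(base, times = diff(bounds))
    if (within_field_cv > 0) {
      noise <- 1 + within_field_cv *
        stats::qnorm(stats::runif(exposed, 0.05, 0.95))
      daily <- pmax(daily * noise, 0)
    }
    conc[seq_len(exposed)] <- daily
  }
  exposure_scenario(duration, forage_conc = conc, cow_forage_conc = conc)
}

#' Ration concentration meeting a target muscle residue
#'
#' Finds the constant total-ration PFOS concentration for which the muscle
#' concentration at slaughter equals `target`, either for the average
#' animal (`confidence = "deterministic"`, delegating to
#' [solve_ration_for_target()]) or so that 95% of the simulated herd stays
#' at or below the target (`confidence = "p95"`): the latter bisects on
#' the ration concentration until the Monte Carlo 95th percentile at
#' slaughter matches the target, holding the random-number stream fixed
#' across bisection steps (common random numbers) so the bracketing is
#' stable.
#'
#' @param target Target muscle concentration, ug/kg (> 0), e.g. the
#'   0.5 ug/kg regulatory screening level.
#' @param confidence `"deterministic"` or `"p95"`.
#' @param profile A [default_profile()].
#' @param slaughter_day Slaughter age in days (default 540).
#' @param n Monte Carlo iterations per bisection step (default 1000).
#' @param seed Integer seed (required for `"p95"`).
#' @param forage_cv Within-field forage variability for the probabilistic
#'   mode (default 0.40).
#' @param tol Relative tolerance on the achieved percentile
#'   (default 1e-3).
#' @param bounds Initial bisection bracket on the ration concentration,
#'   ug/kg.
#' @param max_iter Bisection iteration cap; exceeding it is an error.
#' @param ... Passed on to [run_monte_carlo()] (e.g. `scopes`,
#'   `param_distributions`).
#' @return Ration concentration in ug/kg.
#' @examples
#' regulatory_ration_limit(0.5)                      # ~0.27 ug/kg
#' \donttest{
#' regulatory_ration_limit(0.5, "p95", seed = 1)     # ~0.19 ug/kg
#' }
#' @export
regulatory_ration_limit <- function(target,
                                    confidence = c("deterministic", "p95"),
                                    profile = default_profile(),
                                    slaughter_day = 540, n = 1000, seed,
                                    forage_cv = 0.40, tol = 1e-3,
                                    bounds = c(1e-4, 10), max_iter = 60,
                                    ...) {
  confidence <- match.arg(confidence)
  if (target <= 0) stop("target must be > 0")
  if (confidence == "deterministic") {
    return(solve_ration_for_target(target, slaughter_day, profile))
  }
  if (missing(seed)) stop("a seed is required for the p95 mode")
  p95_at <- function(conc) {
    run_monte_carlo(build_generic(conc, slaughter_day), profile, n = n,
                    seed = seed, forage_cv = forage_cv, ...)$p95
  }
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- p95_at(lo) - target
  f_hi <- p95_at(hi) - target
  if (f_lo > 0 || f_hi < 0) {
    stop("target not bracketed by bounds [", lo, ", ", hi, "]")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- p95_at(mid) - target
    if (abs(f_mid) <= tol * target) return(mid)
    if (f_mid > 0) hi <- mid else lo <- mid
  }
  stop("bisection did not converge within ", max_iter, " iterations")
}
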