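# Readers/writers for trajectories, Monte Carlo dumps and run summaries,
# plus the reproducibility manifest written by every CLI run.

#' Write / read a simulated trajectory as CSV
#'
#' One row per day with all daily-state columns (body weight, per-route
#' intakes, eliminated mass, body burden, muscle and serum
#' concentrations). The round trip preserves every field to full double
#' precision (values are written with 15 significant digits).
#'
#' @param result A `dam_result` from [simulate_dam()].
#' @param path CSV path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory data.frame.
#' @export
write_trajectory <- function(result, path) {
  traj <- if (inherits(result, "dam_result")) result$trajectory else result
  out <- traj
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}

#' Dump per-iteration Monte Carlo draws and outputs as CSV
#'
#' One row per iteration: the sampled animal-level parameters, per-day
#' parameters summarised by their mean draw, and the final muscle and
#' serum concentrations - the audit trail for external sensitivity
#' re-analysis.
#'
#' @param mc A `dam_mc` from [run_monte_carlo()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_mc_draws <- function(mc, path) {
  df <- cbind(iteration = seq_len(mc$n), mc$draws,
              final_muscle_conc = mc$final_muscle_conc,
              final_serum_conc = mc$final_serum_conc)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' @param x A `dam_result` or `dam_mc` object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  s <- if (inherits(x, "dam_result")) {
    list(kind = "deterministic", slaughter_day = x$slaughter_day,
         final_muscle_conc = x$final_muscle_conc,
         final_serum_conc = x$final_serum_conc,
         final_body_burden = x$final_body_burden,
         final_body_weight = x$final_body_weight)
  } else if (inherits(x, "dam_mc")) {
    list(kind = "montecarlo", n = x$n, seed = x$seed,
         forage_cv = x$forage_cv, mean = x$mean, sd = x$sd,
         ci90 = x$ci90, p95 = x$p95,
         mean_serum = x$mean_serum, p95_serum = x$p95_serum)
  } else {
    stop("cannot summarise object of class ", paste(class(x), collapse = "/"))
  }
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed and package version of a run so it can
#' be reproduced bit-exactly.
#'
#' @param config Named list echoing the run configuration.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  m <- c(list(package = "dampfos",
              version = as.character(utils::packageVersion("dampfos")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         config)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
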