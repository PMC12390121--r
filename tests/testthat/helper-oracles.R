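# Independent oracles used across the suite.

# Closed-form quartic growth curve (the curve whose derivative the daily
# gain integrates); the simulator never calls this.
bw_closed_form <- function(d) {
  35.45 + 0.5584 * d + 0.001787 * d^2 - 1.549e-6 * d^3 - 1.332e-9 * d^4
}

# Weighted moments of an evidence table computed directly from the mixture
# definition: each row is normal(half_life, sd) with mixture weight
# proportional to total_weight.
mixture_moments <- function(ev) {
  w <- total_weight(ev)
  m <- sum(w * ev$half_life) / sum(w)
  v <- sum(w * (ev$sd^2 + ev$half_life^2)) / sum(w) - m^2
  list(mean = m, sd = sqrt(v))
}

# Closed-form burden after n days of constant intake I under retained
# daily fraction f = 2^(-1/T), starting from burden b0.
burden_recursion <- function(b0, I, f, n, intake_first = TRUE) {
  b <- b0
  for (i in seq_len(n)) b <- if (intake_first) (b + I) * f else b * f + I
  b
}

# A profile rigged for constant forage DMI from day 1 (no milk phase),
# handy for steady-state and depletion checks.
constant_intake_profile <- function(dmi = 5, half_life = 20,
                                    update_order = "intake_first") {
  default_profile(dmi_log_slope = 0, dmi_log_intercept = dmi,
                  dmi_start_day = 0, weaning_day = 1,
                  half_life = half_life, update_order = update_order)
}
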