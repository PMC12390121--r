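# dampfos

A daily accumulation model (DAM) for predicting perfluorooctane sulfonate
(PFOS) residues in beef cattle muscle and serum after oral exposure.

PFOS reaches grazing cattle through forage grown on biosolid-amended
fields, drinking water, incidental soil ingestion and — for nursing
calves — the dam's milk. Because its elimination half-life in cattle is
on the order of months, residues rarely reach steady state under
real-world seasonal feeding, so steady-state toxicokinetics mispredict
tissue concentrations. `dampfos` is written for food-safety risk
assessors who need a transparent, parameterisable alternative: a
one-compartment mass balance with one row per day of the animal's life.

## The model

Each day the dietary PFOS mass enters the body burden *A* (µg) and a
first-order elimination leaves it:

    E = A · (1 − 0.5^(1/T))          daily elimination, half-life T (days)
    A_d = (A_{d−1} + I_d) · 0.5^(1/T)

Muscle and serum concentrations follow from static partitioning:

    C_muscle = R_mb · A / (F_mbw · BW)      R_mb  = 0.231 (muscle:body)
    C_serum  = C_muscle / R_ms              F_mbw = 0.361 kg muscle/kg BW
                                            R_ms  = 0.080 (muscle:serum)

Daily intake I combines NRC-derived physiology (growth curve, logarithmic
forage dry-matter intake, lactation curve, water and soil intake) with a
day-indexed exposure scenario. The half-life T = 108.9 ± 40.5 days is a
weight-of-evidence pool of six literature estimates. A Monte Carlo layer
propagates the parameter distributions (truncated at their 5th/95th
percentiles) plus within-field forage variability, and ranks parameter
sensitivity by Spearman correlation. The feed-to-tissue summary is the
bioaccumulation factor BAF = C_muscle(slaughter) / C_ration.

## Worked example

```r
library(dampfos)

# deterministic: constant 0.270 ug/kg ration from birth to day 540
res <- simulate_dam(build_generic(ration_conc = 0.270, slaughter_day = 540))
res
#> <dam_result> daily accumulation model trajectory
#>   540 days simulated; final body weight 500.8 kg
#>   final body burden 397 ug; muscle 0.5069 ug/kg; serum 6.337 ug/kg
bioaccumulation_factor(res$final_muscle_conc, 0.270)
#> [1] 1.877536

# probabilistic: 1000 iterations, 40% within-field forage variation
mc <- run_monte_carlo(build_generic(0.190, 540), n = 1000, seed = 1,
                      forage_cv = 0.40)
mc
#> <dam_mc> 1000 Monte Carlo iterations (seed 1, forage CV 0.40)
#>   muscle at slaughter: mean 0.3265 +/- 0.1045 ug/kg
#>   90% CI [0.1562, 0.4967]; 95th percentile 0.4967 ug/kg

head(sensitivity_ranking(mc), 2)
#>           parameter        rho    abs_rho
#> 1 muscle_body_ratio 0.99531606 0.99531606
#> 2         half_life 0.06001541 0.06001541
```

A 0.270 µg/kg ration drives the average animal to ≈0.5 µg/kg PFOS in
muscle at slaughter (the USDA screening level for bovine muscle), a
deterministic BAF of ≈1.88; at a 0.190 µg/kg ration, 95% of the simulated
herd stays at or below 0.5 µg/kg. The muscle:body partition ratio
dominates the output uncertainty.

The inverse problems are solved directly:

```r
solve_ration_for_target(0.5, slaughter_day = 540)   # 0.2663 ug/kg
regulatory_ration_limit(0.5, "p95", seed = 1)       # ~0.19  ug/kg
```

Piecewise feeding histories (seasonal feed changes, terminal depuration
on clean feed) are first-class scenarios:

```r
sc <- build_synthetic_history(duration = 735, n_segments = 5,
                              segment_conc_range = c(0.5, 4),
                              depuration_days = 150, seed = 21)
simulate_dam(sc)$final_muscle_conc
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/dam.R generic-baf --ration 0.27 --out out/
Rscript inst/cli/dam.R make-fixture --out fix/ --days 540 --depuration 120 --seed 5
Rscript inst/cli/dam.R simulate --scenario fix/scenario.csv --out out/
Rscript inst/cli/dam.R montecarlo --scenario fix/scenario.csv --n 1000 --seed 1 --forage-cv 0.4 --out out/
Rscript inst/cli/dam.R combine-halflife --seed 1 --out out/
```

Every run writes its outputs plus a `manifest.json` (configuration echo,
seed, package version) sufficient to reproduce it bit-exactly.

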