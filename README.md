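# moultphen

Individual-level moult phenology from longitudinal resighting data.

Colony studies of seals (and other molting vertebrates) score the visible
moult of marked individuals repeatedly through a season: each sighting is
an integer 0–100 "per cent moulted". **moultphen** turns such sighting
tables into per-individual event dates and population-level synchrony
statistics, for analysts who have longitudinal mark–resight data and want
individual — not just population — phenology:

* a **hierarchical Bayesian logistic model** of moult progression. Each
  animal-year cycle follows `p(t) = logistic((t − t50)/s)`; moult start,
  end and the 5–95% duration derive as `t50 ∓ s·ln 19` and `2·s·ln 19`.
  Cycles are fitted jointly with crossed animal and year effects on `t50`
  and `log s` (`fit_hierarchical`, adaptive Metropolis-within-Gibbs in
  Rcpp; split-Rhat/ESS convergence gates), and event dates are derived
  draw-wise with credible intervals (`derive_events`).
* **detection-corrected arrival and departure**: the first sighting lags
  true arrival by the surveyed days the animal was missed; with per
  survey-day detection `p`, the gap likelihood is `(1−p)^k`. Detection is
  hierarchical across years and separate for arrival vs departure
  (`fit_arrival_departure`, exact Gibbs).
* **population synchrony**: daily cumulative arrived/departed and moult
  started/ended curves, fractions present and moulting, peak synchrony
  and quantile-based population event windows (`build_schedule`,
  `peak_synchrony`, `population_window`).
* **comparisons**: gamma log-link mixed models across age-sex categories
  with Tukey grouping letters, variance partitioning between category ×
  year structure and individual, the arrival–duration compensation
  regression, and the annual-cycle variance chain (`compare_categories`,
  `partition_variance`, `compensation_regression`, `annual_cycle_chain`).
* a **seeded synthetic-colony generator** (`generator_config`,
  `generate_truth`, `observe`) emulating the whole observation process —
  logistic trajectories, category timing offsets, individual/year random
  effects, 75% survey coverage, imperfect detection, integer scoring,
  rare 0↔100 misclassification — so every stage is testable without
  field data.

## Worked example

```r
library(moultphen)

cfg <- generator_config(categories = default_categories(
  c(adult_reproductive = 30, adult_skip = 8,
    juvenile_female = 12, juvenile_male = 8)), n_years = 3, seed = 2024)
truth     <- generate_truth(cfg)          # latent cycles
sightings <- observe(truth, cfg)          # 3839 sighting rows

filt <- filter_cycles(sightings)          # >=6 obs, one <10%, one >90%
sum(filt$cycles$eligible)                 # 167 of 174 cycles

fit <- fit_hierarchical(filt$eligible[category == "adult_reproductive"],
                        chains = 2, iter = 2000, warmup = 1000, seed = 1)
#> Hierarchical logistic moult fit
#>   cycles: 87  animals: 30  years: 3
#>   draws: 2000 over 2 chains; converged: FALSE
#>   population mean t50: 142.58  mean 5-95% duration: 5.88 d

ev <- derive_events(fit)
ev[1:2, .(animal_id, year, start_mean, mid_mean, duration_mean)]
#>    animal_id  year start_mean mid_mean duration_mean
#> 1:    AR0001     1   143.2465 146.1237      5.754377
#> 2:    AR0001     2   142.6475 145.5823      5.869552

sub <- sightings[select_subset(ev)[, .(animal_id, year)],
                 on = c("animal_id", "year")]
ho <- fit_arrival_departure(sub, survey_calendar(sightings), seed = 2)
summarize_categories(ho, ev)
#>              category  n arrival departure duration  pre_gap post_gap
#> 1: adult_reproductive 87 120.931   161.991 41.06002 18.22672 17.05498

pk <- peak_synchrony(build_schedule(truth))
#> peak presence: 0.93 on day 136; peak moulting: 0.28 on day 141
```

Reading the numbers: the fitted mean 5–95% moult duration for
reproductive adult females is 5.88 d against a generating mean of
5.95 d; the detection-corrected haul-out lasts ≈41 d, with the ≈6-day
moult centred in it (pre/post gaps ≈18 d); and although 93% of this small
colony is ashore on the peak day, only 28% is moulting simultaneously —
individual moults are brief but staggered. (`converged: FALSE` here only
flags a handful of sparse-cycle parameters below the ESS ≥ 200 gate at
these reduced draw counts; increase `iter` for production runs.)

An end-to-end, file-based run (generation → fit → haul-out → synchrony →
comparisons, with a provenance manifest):

```r
run_pipeline(pipeline_config(seed = 1), "runs/demo")
```

or from the shell: `inst/cli/moultphen pipeline --config cfg.yaml --out
runs/demo` (a `synthdata` subcommand writes sighting CSVs).

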