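# shared fixtures: all synthetic, generated at test time

one_cat_config <- function(name = "adult_reproductive", n = 20, years = 2,
                           seed = 1, ...) {
  cats <- default_categories(stats::setNames(n, name))[name]
  generator_config(categories = cats, n_years = years, seed = seed, ...)
}

small_colony <- function(name = "adult_reproductive", n = 20, years = 2,
                         seed = 1, ...) {
  cfg <- one_cat_config(name, n, years, seed, ...)
  truth <- generate_truth(cfg)
  obs <- observe(truth, cfg)
  list(cfg = cfg, truth = truth, obs = obs, filt = filter_cycles(obs))
}

# fit with the convergence-gate warning muffled (small test fits keep the
# gate but are run at reduced draws)
quiet_fit <- function(...) suppressWarnings(fit_hierarchical(...))

# hand-built sighting table: one row per (animal, date, score)
toy_sightings <- function(animal_id, dates, scores, year = 1,
                          category = "adult_reproductive") {
  data.table::data.table(animal_id = animal_id, year = year,
                         category = category, date = as.integer(dates),
                         percent_moulted = as.integer(scores))
}

# noiseless logistic sightings for a given truth
logistic_scores <- function(dates, t50, scale) {
  as.integer(round(100 * plogis((dates - t50) / scale)))
}

# realized mean true duration of the eligible cycles of a colony
eligible_truth_mean <- function(colony) {
  keep <- paste(colony$truth$animal_id, colony$truth$year) %in%
    colony$filt$cycles[eligible == TRUE, paste(animal_id, year)]
  mean(colony$truth$duration[keep])
}
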