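test_that("filter_cycles applies the three inclusion criteria", {
  ok <- toy_sightings("A", c(120, 122, 125, 128, 131, 134),
                      c(0, 0, 20, 60, 95, 100))
  few <- toy_sightings("B", c(120, 124, 128, 130, 133), c(0, 10, 60, 95, 100))
  no_early <- toy_sightings("C", c(120, 123, 126, 129, 132, 135),
                            c(15, 30, 50, 70, 92, 100))
  no_late <- toy_sightings("D", c(120, 123, 126, 129, 132, 135),
                           c(0, 5, 30, 50, 70, 88))
  f <- filter_cycles(rbind(ok, few, no_early, no_late))
  expect_equal(sort(unique(f$eligible$animal_id)), "A")
  rep <- setNames(f$report$n_cycles, f$report$reason)
  expect_equal(rep[["min_observations"]], 1L)
  expect_equal(rep[["no_early_observation"]], 1L)
  expect_equal(rep[["no_late_observation"]], 1L)
  # boundary: exactly 10% / 90% do not satisfy the strict criteria
  edge <- toy_sightings("E", c(120, 123, 126, 129, 132, 135),
                        c(10, 20, 40, 60, 80, 90))
  fe <- filter_cycles(edge)
  expect_equal(sum(fe$cycles$eligible), 0L)
  # empty input: empty output, zero-count report
  f0 <- filter_cycles(NULL)
  expect_equal(nrow(f0$eligible), 0L)
  expect_equal(sum(f0$report$n_cycles), 0L)
})

test_that("logistic closed forms hold to machine precision", {
  set.seed(1)
  sc <- exp(runif(50, -2, 2))
  expect_equal(moult_duration(sc) / sc, rep(2 * log(19), 50),
               tolerance = 1e-14)
  expect_equal(moult_end(135, sc) - moult_start(135, sc), moult_duration(sc),
               tolerance = 1e-12)
  expect_equal(moult_start(135, 1), 132.0556, tolerance = 1e-4)
  expect_equal(moult_end(135, 1), 137.9444, tolerance = 1e-4)
  expect_equal(moult_duration(1), 5.8889, tolerance = 1e-4)
  # linearity in scale
  expect_equal(moult_duration(c(1, 2)), c(5.8889, 11.7778), tolerance = 1e-4)
  expect_equal(scale_from_duration(moult_duration(1.37)), 1.37)
})

test_that("noiseless cycles recover truth and shrink individual effects", {
  t50 <- 135; scale <- 5.95 / (2 * log(19))
  dates <- 128:142
  obs <- data.table::rbindlist(lapply(c("A", "B", "C"), function(id)
    toy_sightings(id, dates, logistic_scores(dates, t50, scale))))
  fit <- quiet_fit(obs, chains = 2, iter = 1500, warmup = 700, seed = 4)
  ev <- derive_events(fit)
  expect_true(all(abs(ev$mid_mean - 135) < 0.2))
  expect_true(all(abs(ev$duration_mean - 5.95) < 0.3))
  # draw-wise identity: start + duration = end, preserved in summaries
  expect_equal(ev$start_mean + ev$duration_mean, ev$end_mean,
               tolerance = 1e-9)
  expect_true(all(ev$start_q2.5 <= ev$start_q50 &
                    ev$start_q50 <= ev$start_q97.5))
  # exchangeable duplicates: individual effects concentrate near zero
  a_cols <- grep("^a\\[", colnames(fit$draws))
  expect_true(all(abs(colMeans(fit$draws[, a_cols])) < 0.3))
})

test_that("sparse cycles have wider posteriors than dense ones (shrinkage)", {
  t50 <- 135; scale <- 1.2
  dense_dates <- 126:144
  sparse_dates <- c(128, 132, 134, 136, 138, 142)
  mk <- function(id, dates) {
    set.seed(match(id, LETTERS))
    sc <- round(100 * plogis((dates - t50) / scale) + rnorm(length(dates), 0, 3))
    toy_sightings(id, dates, pmin(pmax(sc, 0), 100))
  }
  obs <- rbind(mk("A", sparse_dates), mk("B", dense_dates),
               mk("C", dense_dates), mk("D", dense_dates))
  fit <- quiet_fit(obs, chains = 2, iter = 1500, warmup = 700, seed = 5)
  ev <- derive_events(fit)
  sd_sparse <- ev[animal_id == "A", mid_sd]
  sd_dense <- min(ev[animal_id != "A", mid_sd])
  expect_gt(sd_sparse, sd_dense)
})

test_that("degenerate and undersized inputs fail loudly", {
  flat <- toy_sightings("A", c(120, 125, 130, 135, 140, 145), rep(50, 6))
  other <- toy_sightings("B", 120:126, c(0, 2, 10, 50, 90, 98, 100))
  expect_error(fit_hierarchical(rbind(flat, other)), "degenerate_cycle")
  expect_error(fit_hierarchical(other), "at least 2 cycles")
})

test_that("fitted curve passes close to the observations of a dense cycle", {
  # one well-observed animal (29 sightings), default observer noise
  cats <- list(category_spec("adult_reproductive", 3, 132, 2, 6, 0.5))
  cfg <- generator_config(categories = cats, sd_year = 0, n_years = 1,
                          survey_coverage = 1, detection_prob = 0.75,
                          flip_prob = 0, seed = 9)
  tr <- generate_truth(cfg)
  obs <- observe(tr, cfg)
  counts <- obs[, .N, by = animal_id][order(-N)]
  fit <- quiet_fit(obs, chains = 2, iter = 1500, warmup = 700, seed = 6)
  ev <- derive_events(fit)
  best <- counts$animal_id[1]
  sub <- obs[animal_id == best]
  pars <- ev[animal_id == best]
  pred <- 100 * plogis((sub$date - pars$mid_mean) /
                         scale_from_duration(pars$duration_mean))
  # posterior-predictive check: >= 90% of observations within the ~95%
  # observational-noise band (2 * score_sd)
  frac_close <- mean(abs(pred - sub$percent_moulted) <= 2 * cfg$score_sd)
  expect_gte(frac_close, 0.9)
})

test_that("split-Rhat and ESS behave on white-noise and stuck chains", {
  set.seed(10)
  x <- matrix(rnorm(2000), ncol = 4)
  expect_lt(rhat_split(x), 1.02)
  expect_gt(ess_basic(x), 0.5 * length(x))
  # diverging chains are flagged
  y <- cbind(rnorm(500), rnorm(500) + 5)
  expect_gt(rhat_split(y), 1.5)
})

test_that("fit_by_category groups skip females into the adult run", {
  cats <- default_categories(c(adult_reproductive = 8, adult_skip = 4,
                               juvenile_female = 6, juvenile_male = 0))
  cats$juvenile_male <- NULL
  cfg <- generator_config(categories = cats, n_years = 2, seed = 15)
  tr <- generate_truth(cfg)
  obs <- observe(tr, cfg)
  filt <- filter_cycles(obs)
  fits <- suppressWarnings(fit_by_category(filt$eligible, chains = 2,
                                           iter = 900, warmup = 450,
                                           seed = 7))
  expect_setequal(names(fits), c("adult", "juvenile_female"))
  expect_setequal(unique(fits$adult$cycles$category),
                  c("adult_reproductive", "adult_skip"))
  # post-hoc skip summary comes from the shared adult posterior
  ps_skip <- population_summary(fits$adult, categories = "adult_skip")
  expect_true(ps_skip[metric == "cycle_mean_duration", mean] > 0)
})
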