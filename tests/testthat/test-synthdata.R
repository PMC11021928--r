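test_that("degenerate variance collapses every cycle to category means", {
  cats <- list(category_spec("adult_reproductive", 5, 137, 0, 5.95, 0))
  cfg <- generator_config(categories = cats, sd_year = 0, n_years = 2,
                          sd_gap = 0, sd_log_haulout = 0,
                          arrival_duration_slope = 0, seed = 1)
  tr <- generate_truth(cfg)
  expect_equal(nrow(tr), 10L)
  expect_equal(tr$duration, rep(5.95, 10))
  expect_equal(tr$t50, rep(137 + 5.95 / 2, 10))
  # closed form: scale = duration / (2 ln 19)
  expect_equal(tr$scale, rep(5.95 / (2 * log(19)), 10), tolerance = 1e-12)
  expect_equal(unique(round(tr$scale, 4)), 1.0104)
  expect_equal(tr$arrival, tr$moult_start - 18)
  expect_equal(tr$departure, tr$moult_end + 18, tolerance = 1e-9)
  expect_equal(attr(tr, "redraws"), 0L)
})

test_that("noiseless observation limit gives one exact sighting per presence day", {
  cats <- list(category_spec("adult_reproductive", 3, 132, 0, 6, 0))
  cfg <- generator_config(categories = cats, sd_year = 0, n_years = 1,
                          sd_gap = 0, sd_log_haulout = 0,
                          arrival_duration_slope = 0, survey_coverage = 1,
                          detection_prob = 1, score_sd = 0, flip_prob = 0,
                          seed = 2)
  tr <- generate_truth(cfg)
  obs <- observe(tr, cfg)
  # presence: arrival 114 .. departure 156, one sighting per animal-day
  perday <- obs[, .N, by = .(animal_id, date)]
  expect_true(all(perday$N == 1L))
  expect_equal(obs[, .N, by = animal_id]$N, rep(43L, 3))
  # logistic midpoint: score 50 on the t50 day (t50 = 135, integer)
  expect_true(all(obs[date == 135, percent_moulted] == 50L))
  expect_true(all(obs$percent_moulted >= 0 & obs$percent_moulted <= 100))
})

test_that("survey calendar hits the configured coverage", {
  col <- small_colony(n = 30, years = 7, seed = 5)
  svy <- survey_calendar(col$obs)
  # season window per year mirrors the generator: floor(min arrival) - 3
  # to ceiling(max departure) + 3
  season <- col$truth[, .(n_days = ceiling(max(departure)) + 3 -
                            (floor(min(arrival)) - 3) + 1), by = year]
  n_total <- sum(season$n_days)
  frac <- nrow(svy) / n_total
  expect_lt(abs(frac - 0.75), 0.03)
})

test_that("score flips occur only at extremes and at the configured rate", {
  col <- small_colony(n = 40, years = 3, seed = 6, score_sd = 0,
                      flip_prob = 0.1)
  m <- merge(col$obs, col$truth[, .(animal_id, year, t50, scale)],
             by = c("animal_id", "year"))
  m[, expected := logistic_scores(date, t50, scale)]
  mid <- m[!(expected %in% c(0L, 100L))]
  expect_true(all(mid$percent_moulted == mid$expected))
  ext <- m[expected %in% c(0L, 100L)]
  flipped <- ext[percent_moulted != expected]
  expect_true(all(flipped$percent_moulted == 100L - flipped$expected))
  rate <- nrow(flipped) / nrow(ext)
  tol <- 4 * sqrt(0.1 * 0.9 / nrow(ext))
  expect_lt(abs(rate - 0.1), tol)
})

test_that("duplicate-observer simulation reproduces high scorer consistency", {
  res <- duplicate_observer_sim(generator_config(seed = 3), n_pairs = 1220)
  expect_gte(res$r_squared, 0.98)
  expect_equal(nrow(res$data), 1220L)
})

test_that("log haul-out duration declines with arrival at the configured slope", {
  cfg <- generator_config(seed = 11)
  tr <- generate_truth(cfg)
  sl <- coef(lm(log(departure - arrival) ~ arrival + category, tr))[["arrival"]]
  expect_lt(sl, 0)
  expect_lt(abs(sl - cfg$arrival_duration_slope),
            0.1 * abs(cfg$arrival_duration_slope))
  # halving calibration: latest decile spends about half the time ashore
  ar <- tr[category == "adult_reproductive"]
  qs <- quantile(ar$arrival, c(0.1, 0.9))
  ratio <- mean(ar[arrival <= qs[1], departure - arrival]) /
    mean(ar[arrival >= qs[2], departure - arrival])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.6)
})

test_that("category sample means match the configured (printed) means", {
  cfg <- one_cat_config(n = 500, years = 1, seed = 13)
  tr <- generate_truth(cfg)
  expect_lt(abs(mean(tr$duration) - 5.95), 2 * 1.6 / sqrt(500))
  full <- generate_truth(generator_config(seed = 14))
  md <- full[, mean(duration), by = category]
  expect_lt(md[category == "adult_reproductive", V1],
            md[category == "juvenile_female", V1])
  expect_lt(md[category == "juvenile_female", V1],
            md[category == "juvenile_male", V1])
  # printed start offsets: juvenile males first, adults 19 d later
  ms <- full[, mean(moult_start), by = category]
  gap <- ms[category == "adult_reproductive", V1] -
    ms[category == "juvenile_male", V1]
  expect_lt(abs(gap - 19), 6)
})

test_that("sighting tables round-trip through CSV with metadata sidecar", {
  col <- small_colony(n = 5, years = 1, seed = 8)
  path <- file.path(tempdir(), "sightings_test.csv")
  write_sightings(col$obs, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_sightings(path)
  expect_equal(nrow(back), nrow(col$obs))
  expect_equal(back$percent_moulted, col$obs$percent_moulted)
  expect_equal(survey_calendar(back), survey_calendar(col$obs))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 8L)
  unlink(c(path, paste0(path, c(".meta.json", ".surveys.csv"))))
})

test_that("generator rejects invalid configurations", {
  expect_error(generator_config(survey_coverage = 1.2))
  expect_error(generator_config(flip_prob = -0.1))
  expect_error(category_spec("adult_reproductive", 0, 137, 1, 6, 1))
  expect_error(category_spec("adult_male", 5, 137, 1, 6, 1))
})
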