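# gamma GLMM comparisons, variance partitioning and the annual-cycle chain.
# Metrics fed to the mixed models carry small observation noise, as the
# fitted per-cycle estimates would (the latent truth is deterministic given
# animal and year, which degenerates a residual-based model).

noisy <- function(x, sd = 0.4, seed = 1) {
  set.seed(seed)
  pmax(x + rnorm(length(x), 0, sd), 0.1)
}

test_that("variance shares sum to one and match an ANOVA oracle", {
  # balanced Gaussian identity-link instance: 4 categories x 3 years x
  # 12 animals each, animal crossed with year
  set.seed(2)
  A <- 12; Y <- 3; C <- 4
  cat_eff <- c(0, 1.5, 3, 4.5); yr_eff <- c(-1, 0, 1)
  dd <- data.table::CJ(animal = 1:(A * C), year = 1:Y)
  dd[, category := (animal - 1) %/% A + 1]
  u <- rnorm(A * C, 0, 1.2)
  dd[, y := cat_eff[category] + yr_eff[year] + u[animal] + rnorm(.N, 0, 0.8)]
  vp <- partition_variance(dd$y, dd$category, dd$year, dd$animal,
                           family = "gaussian")
  expect_equal(sum(vp$shares), 1, tolerance = 1e-9)
  # brute-force oracle: fixed variance from the saturated cell-mean lm,
  # animal variance from the expected-mean-squares identity on residuals
  fixed_lm <- lm(y ~ factor(category) * factor(year), dd)
  var_fixed_o <- var(fitted(fixed_lm))
  r <- residuals(fixed_lm)
  ms_within <- mean(tapply(r, dd$animal, var))
  ms_between <- Y * var(tapply(r, dd$animal, mean))
  var_ind_o <- max((ms_between - ms_within) / Y, 0)
  var_res_o <- ms_within
  tot_o <- var_fixed_o + var_ind_o + var_res_o
  expect_lt(abs(vp$shares[["fixed"]] - var_fixed_o / tot_o), 0.02)
  expect_lt(abs(vp$shares[["individual"]] - var_ind_o / tot_o), 0.02)
  expect_lt(abs(vp$shares[["residual"]] - var_res_o / tot_o), 0.02)
})

test_that("degenerate generators give degenerate shares", {
  # zero individual sd: individual share ~ 0
  set.seed(3)
  dd <- data.table::CJ(animal = 1:40, year = 1:3)
  dd[, category := (animal - 1) %/% 20 + 1]
  dd[, y := c(5, 8)[category] + 0.5 * year + rnorm(.N, 0, 0.5)]
  vp0 <- partition_variance(dd$y, dd$category, dd$year, dd$animal,
                            family = "gaussian")
  expect_lt(vp0$share_individual, 0.05)
  # zero category and year effects: individual + residual ~ 1
  u <- rnorm(40, 0, 1.5)
  dd[, y2 := 6 + u[animal] + rnorm(.N, 0, 0.5)]
  vp1 <- partition_variance(dd$y2, dd$category, dd$year, dd$animal,
                            family = "gaussian")
  expect_gt(vp1$shares[["individual"]] + vp1$shares[["residual"]], 0.9)
  # single category: interaction dropped and flagged
  one <- dd[category == 1]
  vp2 <- partition_variance(one$y, one$category, one$year, one$animal,
                            family = "gaussian")
  expect_true(vp2$dropped_interaction)
})

test_that("individual-dominated generator yields a dominant individual share", {
  # individual start sd >> category spread, mirroring the published
  # 75-80% individual shares
  cats <- default_categories()
  for (nm in names(cats)) cats[[nm]]$sd_individual_start <- 18
  cfg <- generator_config(categories = cats, n_years = 3, seed = 41)
  tr <- generate_truth(cfg)
  vp <- partition_variance(noisy(days_since_origin(tr$moult_start), 1, 5),
                           tr$category, tr$year, tr$animal_id,
                           family = "gamma")
  expect_gt(vp$share_individual, 0.7)
})

test_that("category comparison recovers the printed duration groups", {
  cfg <- generator_config(seed = 42, n_years = 3)
  cfg$categories <- lapply(cfg$categories, function(x) {
    x$n_individuals <- max(6L, x$n_individuals %/% 3L); x })
  tr <- generate_truth(cfg)
  cc <- compare_categories(noisy(tr$duration, 0.4, 6), tr$category,
                           tr$animal_id, tr$year)
  tab <- cc$table
  adults <- tab[category %in% c("adult_reproductive", "adult_skip"), letter]
  juvs <- tab[category %in% c("juvenile_female", "juvenile_male"), letter]
  # adults grouped apart from juveniles (no shared letter)
  expect_false(any(unlist(strsplit(adults, "")) %in%
                     unlist(strsplit(juvs, ""))))
  # skip vs reproductive start about 8 d apart (generator offsets 11 vs 19);
  # checked at a size where the between-animal se (~1.2 d) resolves 8 d
  big <- generate_truth(generator_config(categories = default_categories(
    c(adult_reproductive = 100, adult_skip = 100, juvenile_female = 5,
      juvenile_male = 5)), n_years = 1, seed = 47))
  ms <- big[, mean(moult_start), by = category]
  gap <- ms[category == "adult_reproductive", V1] -
    ms[category == "adult_skip", V1]
  expect_lt(abs(gap - 8), 4)
  expect_error(compare_categories(c(-1, rep(1, 9)), rep(c("a", "b"), 5),
                                  1:10, rep(1, 10)),
               "non-positive")
})

test_that("equal-mean categories usually share a letter (type-I control)", {
  hits <- 0L
  for (r in 1:8) {
    set.seed(50 + r)
    n <- 40
    dd <- data.table::data.table(
      animal = rep(1:(2 * n / 4), each = 2),
      category = rep(c("x", "y"), each = n / 2),
      year = rep(1:2, n / 2),
      v = pmax(rnorm(n, 8, 1.5), 0.5))
    cc <- compare_categories(dd$v, dd$category, dd$animal, dd$year)
    shared <- length(intersect(strsplit(cc$table$letter[1], "")[[1]],
                               strsplit(cc$table$letter[2], "")[[1]])) > 0
    hits <- hits + shared
  }
  expect_gte(hits, 7L)
})

test_that("compensation regression detects the built-in halving", {
  tr <- generate_truth(generator_config(seed = 43))
  cr <- compensation_regression(tr$departure - tr$arrival, tr$arrival,
                                tr$category, tr$animal_id)
  expect_equal(nrow(cr), 4L)
  expect_true(all(cr$slope < 0))
  expect_true(all(cr$p < 0.05))
  # adult females: earliest decile stays more than twice as long
  expect_gt(cr[category == "adult_reproductive", decile_ratio], 2)
  # small categories are refused
  expect_warning(
    cr2 <- compensation_regression(rep(10, 5), 1:5, rep("tiny", 5), 1:5),
    "fewer than 10")
  expect_equal(nrow(cr2), 0L)
})

test_that("null compensation slope is covered by the CI", {
  covered <- 0L
  for (r in 1:10) {
    cfg <- one_cat_config(n = 40, years = 2, seed = 60 + r,
                          arrival_duration_slope = 0)
    tr <- generate_truth(cfg)
    cr <- compensation_regression(tr$departure - tr$arrival, tr$arrival,
                                  tr$category, tr$animal_id)
    covered <- covered + (cr$ci_lo <= 0 && 0 <= cr$ci_hi)
  }
  expect_gte(covered, 8L)
})

test_that("annual-cycle chain shows the compensation-driven sd decline", {
  tr_on <- generate_truth(generator_config(seed = 44))
  ch_on <- annual_cycle_chain(
    tr_on[category == "adult_reproductive",
          .(arrival, moult_start, moult_end, departure)])
  expect_true(attr(ch_on, "sd_declines"))
  sds <- setNames(ch_on$sd, ch_on$event)
  expect_gt(sds[["moult_arrival"]], sds[["moult_start"]])
  expect_gt(sds[["moult_start"]], sds[["moult_departure"]])
  # events ordered in time
  moults <- ch_on[source == "this_pipeline"]
  expect_true(all(diff(moults$mean_day) > 0))
  # compensation off: departure variance is inflated, not shrunk
  tr_off <- generate_truth(generator_config(seed = 44,
                                            arrival_duration_slope = 0))
  ar <- tr_off[category == "adult_reproductive"]
  expect_gte(sd(ar$departure), sd(ar$arrival))
  ch_off <- annual_cycle_chain(ar[, .(arrival, moult_start, moult_end,
                                      departure)])
  expect_false(attr(ch_off, "sd_declines"))
  # missing event columns warn
  expect_warning(annual_cycle_chain(ar[, .(arrival, moult_start,
                                           departure)]),
                 "moult_end")
})
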