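#' Category specification for the synthetic colony
#'
#' One age-sex category of the colony: how many individuals it contains and
#' the category-level timing parameters of their moult. Defaults for the four
#' modelled categories are supplied by \code{\link{default_categories}}.
#'
#' @param name one of \code{"adult_reproductive"}, \code{"adult_skip"},
#'   \code{"juvenile_female"}, \code{"juvenile_male"}.
#' @param n_individuals number of marked individuals (>= 1).
#' @param mean_moult_start category mean moult start (5\% moulted),
#'   day-of-year.
#' @param sd_individual_start between-individual sd of moult start, days.
#' @param mean_duration category mean 5--95\% moult duration, days.
#' @param sd_individual_duration between-individual sd of duration, days.
#' @param mean_pre_moult_gap mean days from haul-out arrival to moult start.
#' @param mean_post_moult_gap mean days from moult end to departure.
#' @return a list of class \code{moult_category}.
#' @export
category_spec <- function(name, n_individuals, mean_moult_start,
                          sd_individual_start, mean_duration,
                          sd_individual_duration,
                          mean_pre_moult_gap = 18,
                          mean_post_moult_gap = 18) {
  name <- match.arg(name, c("adult_reproductive", "adult_skip",
                            "juvenile_female", "juvenile_male"))
  stopifnot(n_individuals >= 1, mean_duration > 0,
            sd_individual_start >= 0, sd_individual_duration >= 0,
            mean_pre_moult_gap > 0, mean_post_moult_gap > 0)
  structure(list(name = name, n_individuals = as.integer(n_individuals),
                 mean_moult_start = mean_moult_start,
                 sd_individual_start = sd_individual_start,
                 mean_duration = mean_duration,
                 sd_individual_duration = sd_individual_duration,
                 mean_pre_moult_gap = mean_pre_moult_gap,
                 mean_post_moult_gap = mean_post_moult_gap),
            class = "moult_category")
}

#' Default age-sex categories
#'
#' Encodes the published category means of a northern elephant seal colony:
#' juvenile males start moulting first (28 April, day-of-year 118), juvenile
#' females 5 days later, skip adult females 11 days after juvenile males and
#' reproductive adult females 19 days after; mean 5--95\% durations are
#' 5.95 d (reproductive adults), 6.01 d (skip adults), 9.67 d (juvenile
#' females) and 10.29 d (juvenile males); moult starts on average 18 days
#' after arrival and departure follows 18 days after moult end. Individual
#' counts give roughly the published per-year cycle counts (~168 cycles per
#' year, dominated by reproductive adult females). Duration sds are
#' back-computed from the published standard errors and sample sizes.
#'
#' @param n_individuals optional named vector overriding the per-category
#'   individual counts, e.g. \code{c(adult_reproductive = 50)}.
#' @return list of \code{\link{category_spec}} objects.
#' @export
default_categories <- function(n_individuals = NULL) {
  defs <- list(
    category_spec("juvenile_male",      23, 118, 11.5, 10.29, 2.8),
    category_spec("juvenile_female",    33, 123, 11.5,  9.67, 2.6),
    category_spec("adult_skip",         16, 129, 11.5,  6.01, 1.7),
    category_spec("adult_reproductive", 96, 137, 11.5,  5.95, 1.6))
  names(defs) <- vapply(defs, `[[`, "", "name")
  if (!is.null(n_individuals)) {
    for (nm in names(n_individuals))
      defs[[nm]]$n_individuals <- as.integer(n_individuals[[nm]])
  }
  defs
}

#' Generator configuration
#'
#' Full description of the synthetic colony and its observation process. The
#' defaults are the package's stated world: survey coverage 0.75 of season
#' days, per-survey-day detection probability 0.7, integer scoring with
#' observer noise sd 3 percentage points, 0/100 flip probability 0.02, year
#' effect sd 1 d (year-to-year variation in moult timing is small), and an
#' arrival--duration compensation slope of -0.017 per day calibrated once so
#' that the latest-arriving decile's mean haul-out duration is about half
#' the earliest decile's (and the earliest decile robustly stays more than
#' twice as long as the latest across seeds).
#'
#' @param categories list of \code{\link{category_spec}} objects.
#' @param sd_year sd of the shared year effect on moult start, days.
#' @param n_years number of seasons simulated.
#' @param arrival_duration_slope change in log haul-out duration per day of
#'   arrival delay (negative = later arrivals stay for less time).
#' @param survey_coverage probability a season day is surveyed.
#' @param detection_prob probability a hauled-out animal is sighted on a
#'   surveyed day.
#' @param flip_prob probability a clamped 0 or 100 score is recorded as the
#'   opposite extreme.
#' @param score_sd observer noise on the percentage score, percentage points.
#' @param sd_gap between-cycle sd of the pre-moult gap, days.
#' @param sd_log_haulout extra lognormal noise on haul-out duration beyond
#'   the arrival-compensation term.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(categories = default_categories(),
                             sd_year = 1.0, n_years = 7L,
                             arrival_duration_slope = -0.017,
                             survey_coverage = 0.75, detection_prob = 0.7,
                             flip_prob = 0.02, score_sd = 3,
                             sd_gap = 6.9, sd_log_haulout = 0.1,
                             seed = NULL) {
  stopifnot(survey_coverage >= 0, survey_coverage <= 1,
            detection_prob >= 0, detection_prob <= 1,
            flip_prob >= 0, flip_prob <= 1,
            sd_year >= 0, score_sd >= 0, sd_gap >= 0, sd_log_haulout >= 0,
            n_years >= 1)
  if (is.null(names(categories)))
    names(categories) <- vapply(categories, `[[`, "", "name")
  structure(list(categories = categories, sd_year = sd_year,
                 n_years = as.integer(n_years),
                 arrival_duration_slope = arrival_duration_slope,
                 survey_coverage = survey_coverage,
                 detection_prob = detection_prob, flip_prob = flip_prob,
                 score_sd = score_sd, sd_gap = sd_gap,
                 sd_log_haulout = sd_log_haulout, seed = seed),
            class = "generator_config")
}

cat_abbrev <- c(adult_reproductive = "AR", adult_skip = "AS",
                juvenile_female = "JF", juvenile_male = "JM")

#' Generate the latent truth of a synthetic colony
#'
#' Draws one moult cycle per individual per year. Individual effects (start
#' offset and duration) are drawn once per animal and shared across years;
#' a single year effect per season is shared across animals and categories.
#' Per cycle, \code{t50 = mean_moult_start + duration/2 + individual effect +
#' year effect} and \code{scale = duration/(2 ln 19)}. Arrival precedes moult
#' start by a truncated-Normal pre-moult gap; the haul-out duration is
#' \code{(duration + mean_pre_gap + mean_post_gap) * exp(slope * (arrival -
#' mean arrival) + eta)} (mean-centred lognormal noise \code{eta}), so that
#' log haul-out duration is, by construction, linear in realized arrival
#' date with the configured compensation slope. Departure is arrival plus
#' haul-out duration, floored at moult end + 0.5 d.
#'
#' @param config a \code{\link{generator_config}}.
#' @return \code{data.table} with one row per cycle: \code{animal_id, year,
#'   category, t50, scale, moult_start, moult_end, duration, arrival,
#'   departure, pre_gap, post_gap}. Attributes: \code{redraws} (rejected
#'   truncated-Normal draws), \code{clamped} (departures floored),
#'   \code{config}.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  year_eff <- rnorm(config$n_years, 0, config$sd_year)
  redraws <- 0L
  out <- vector("list", length(config$categories))
  for (ci in seq_along(config$categories)) {
    cs <- config$categories[[ci]]
    n <- cs$n_individuals
    ids <- sprintf("%s%04d", cat_abbrev[[cs$name]], seq_len(n))
    u_start <- rnorm(n, 0, cs$sd_individual_start)
    dur <- rnorm_trunc(n, cs$mean_duration, cs$sd_individual_duration, 0.5)
    redraws <- redraws + attr(dur, "redraws")
    dur <- as.vector(dur)
    dt <- data.table::CJ(animal = seq_len(n), year = seq_len(config$n_years))
    dt[, `:=`(animal_id = ids[animal],
              category = cs$name,
              duration = dur[animal],
              moult_start = cs$mean_moult_start + u_start[animal] +
                year_eff[year])]
    g_pre <- rnorm_trunc(nrow(dt), cs$mean_pre_moult_gap, config$sd_gap, 2)
    redraws <- redraws + attr(g_pre, "redraws")
    g_pre <- as.vector(g_pre)
    eta <- rnorm(nrow(dt), 0, config$sd_log_haulout)
    s <- config$arrival_duration_slope
    var_arr <- cs$sd_individual_start^2 + config$sd_year^2 + config$sd_gap^2
    mean_arrival <- cs$mean_moult_start - cs$mean_pre_moult_gap
    dt[, `:=`(moult_end = moult_start + duration,
              t50 = moult_start + duration / 2,
              scale = scale_from_duration(duration),
              pre_gap = g_pre,
              arrival = moult_start - g_pre)]
    # centring term keeps E[haul-out] = mean_duration + both mean gaps
    dt[, haulout := (duration + cs$mean_pre_moult_gap + cs$mean_post_moult_gap) *
         exp(s * (arrival - mean_arrival) + eta -
             (s^2 * var_arr + config$sd_log_haulout^2) / 2)]
    dt[, clamped := arrival + haulout < moult_end + 0.5]
    dt[, departure := pmax(arrival + haulout, moult_end + 0.5)]
    dt[, post_gap := departure - moult_end]
    out[[ci]] <- dt[, .(animal_id, year, category, t50, scale, moult_start,
                        moult_end, duration, arrival, departure, pre_gap,
                        post_gap, clamped)]
  }
  res <- data.table::rbindlist(out)
  clamped <- sum(res$clamped)
  res[, clamped := NULL]
  data.table::setattr(res, "redraws", redraws)
  data.table::setattr(res, "clamped", clamped)
  data.table::setattr(res, "config", config)
  res[]
}

#' Degrade latent truth into a sighting table
#'
#' Draws a survey calendar (each season day surveyed independently with
#' probability \code{survey_coverage}), sights each hauled-out animal on a
#' surveyed day with probability \code{detection_prob}, scores the sighting
#' as \code{round(100 * logistic((date - t50)/scale) + Normal(0, score_sd))}
#' clamped to [0, 100], and flips clamped 0/100 scores to the opposite
#' extreme with probability \code{flip_prob}.
#'
#' @param truth output of \code{\link{generate_truth}}.
#' @param config a \code{\link{generator_config}}; seeded with
#'   \code{config$seed + 1} so truth and observation draws differ.
#' @return \code{data.table} of sightings (\code{animal_id, year, category,
#'   date, percent_moulted}) with attributes \code{surveys} (a
#'   \code{data.table} of surveyed \code{year, day}) and \code{config}.
#' @export
observe <- function(truth, config) {
  stopifnot(nrow(truth) > 0, inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  season <- truth[, .(first = floor(min(arrival)) - 3L,
                      last = ceiling(max(departure)) + 3L), by = year]
  surveys <- season[, {
    days <- seq.int(first, last)
    .(day = days[runif(length(days)) < config$survey_coverage])
  }, by = year]
  svy <- split(surveys$day, surveys$year)
  recs <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i]
    present <- seq.int(ceiling(row$arrival), floor(row$departure))
    days <- intersect(present, svy[[as.character(row$year)]])
    if (length(days) == 0L) next
    days <- days[runif(length(days)) < config$detection_prob]
    if (length(days) == 0L) next
    p <- plogis((days - row$t50) / row$scale)
    val <- round(100 * p + rnorm(length(days), 0, config$score_sd))
    val <- pmin(pmax(val, 0), 100)
    ext <- which(val %in% c(0, 100))
    if (length(ext) > 0 && config$flip_prob > 0) {
      flip <- ext[runif(length(ext)) < config$flip_prob]
      val[flip] <- 100 - val[flip]
    }
    recs[[i]] <- data.table::data.table(
      animal_id = row$animal_id, year = row$year, category = row$category,
      date = as.integer(days), percent_moulted = as.integer(val))
  }
  res <- data.table::rbindlist(recs)
  data.table::setkey(res, animal_id, year, date)
  data.table::setattr(res, "surveys", surveys[])
  data.table::setattr(res, "config", config)
  res[]
}

#' Survey calendar of a sighting table
#' @param sightings output of \code{\link{observe}}.
#' @return \code{data.table} with columns \code{year, day}.
#' @export
survey_calendar <- function(sightings) attr(sightings, "surveys")

#' Duplicate-observer consistency simulation
#'
#' Re-creates the field protocol check in which two observers independently
#' score the same animal on the same day: samples hauled-out animal-days
#' from a synthetic colony and scores each twice with independent observer
#' noise. Reports the squared correlation between the two scores. Extreme
#' 0/100 flips are excluded by default (the flip process is checked
#' separately, as a rate at the extremes); set \code{include_flips = TRUE}
#' to include them.
#'
#' @param config a \code{\link{generator_config}}.
#' @param n_pairs number of double-scored animal-days.
#' @param include_flips also apply the 0/100 flip process to each score.
#' @return list with \code{r_squared} and the \code{data.table} of pairs.
#' @export
duplicate_observer_sim <- function(config = generator_config(seed = 1),
                                   n_pairs = 1220, include_flips = FALSE) {
  truth <- generate_truth(config)
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  idx <- sample.int(nrow(truth), n_pairs, replace = TRUE)
  first <- ceiling(truth$arrival[idx])
  day <- first + floor(runif(n_pairs) *
                         (floor(truth$departure[idx]) - first + 1))
  p <- plogis((day - truth$t50[idx]) / truth$scale[idx])
  score_once <- function() {
    val <- round(100 * p + rnorm(n_pairs, 0, config$score_sd))
    val <- pmin(pmax(val, 0), 100)
    if (include_flips) {
      ext <- which(val %in% c(0, 100))
      flip <- ext[runif(length(ext)) < config$flip_prob]
      val[flip] <- 100 - val[flip]
    }
    val
  }
  s1 <- score_once(); s2 <- score_once()
  list(r_squared = stats::cor(s1, s2)^2,
       data = data.table::data.table(true_pct = 100 * p, score1 = s1,
                                     score2 = s2))
}

#' Write / read a sighting table
#'
#' CSV with header \code{animal_id,year,category,date,percent_moulted}; the
#' generating configuration and seed are stored in a JSON sidecar
#' (\code{<path>.meta.json}) together with a survey-calendar CSV
#' (\code{<path>.surveys.csv}) when available.
#'
#' @param sightings sighting \code{data.table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_sightings <- function(sightings, path) {
  cols <- c("animal_id", "year", "category", "date", "percent_moulted")
  data.table::fwrite(sightings[, cols, with = FALSE], path)
  cfg <- attr(sightings, "config")
  if (!is.null(cfg)) {
    meta <- list(package = "moultphen",
                 version = as.character(packageVersion("moultphen")),
                 seed = cfg$seed, config = unclass_config(cfg))
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  svy <- attr(sightings, "surveys")
  if (!is.null(svy)) data.table::fwrite(svy, paste0(path, ".surveys.csv"))
  invisible(path)
}

#' @rdname write_sightings
#' @export
read_sightings <- function(path) {
  res <- data.table::fread(path)
  stopifnot(all(c("animal_id", "year", "category", "date",
                  "percent_moulted") %in% names(res)))
  svy_path <- paste0(path, ".surveys.csv")
  if (file.exists(svy_path))
    data.table::setattr(res, "surveys", data.table::fread(svy_path))
  res[]
}

unclass_config <- function(cfg) {
  x <- unclass(cfg)
  x$categories <- lapply(x$categories, unclass)
  x
}
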