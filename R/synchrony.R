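#' Population schedule from individual event dates
#'
#' Builds daily empirical cumulative fractions of the population that have
#' arrived, started moulting, finished moulting and departed, plus the
#' derived fractions present (\code{cum_arrived - cum_departed}) and
#' moulting (\code{cum_moult_started - cum_moult_ended}). Half-open day
#' semantics: an individual counts as present on day \code{t} iff
#' \code{arrival <= t < departure} (likewise for moulting), so cumulative
#' differencing never double-counts boundary days. Years are pooled;
#' filter the input beforehand for per-year schedules.
#'
#' @param events \code{data.frame}/\code{data.table} with per-individual
#'   columns \code{arrival, moult_start, moult_end, departure} (only
#'   \code{arrival}/\code{departure} are required; the moult columns may be
#'   omitted for presence-only schedules).
#' @return \code{data.table} of class \code{population_schedule}: one row
#'   per day with the six series. Rows of the input violating
#'   \code{arrival <= moult_start <= moult_end <= departure} are dropped;
#'   attribute \code{rejected} reports them.
#' @export
build_schedule <- function(events) {
  dt <- data.table::as.data.table(events)
  stopifnot(all(c("arrival", "departure") %in% names(dt)))
  has_moult <- all(c("moult_start", "moult_end") %in% names(dt))
  ok <- dt$arrival <= dt$departure
  if (has_moult)
    ok <- ok & dt$arrival <= dt$moult_start & dt$moult_start <= dt$moult_end &
      dt$moult_end <= dt$departure
  ok <- ok & stats::complete.cases(
    dt[, intersect(c("arrival", "moult_start", "moult_end", "departure"),
                   names(dt)), with = FALSE])
  rejected <- dt[!ok]
  dt <- dt[ok]
  if (nrow(dt) == 0) stop("no valid rows to build a schedule from")
  n <- nrow(dt)
  day <- seq.int(floor(min(dt$arrival)) - 1L, ceiling(max(dt$departure)) + 1L)
  cum <- function(x) findInterval(day, sort(x), left.open = FALSE) / n
  res <- data.table::data.table(
    day = day,
    cum_arrived = cum(dt$arrival),
    cum_departed = cum(dt$departure))
  if (has_moult) {
    res[, cum_moult_started := cum(dt$moult_start)]
    res[, cum_moult_ended := cum(dt$moult_end)]
    res[, frac_moulting := cum_moult_started - cum_moult_ended]
  }
  res[, frac_present := cum_arrived - cum_departed]
  data.table::setattr(res, "n_individuals", n)
  data.table::setattr(res, "rejected", rejected)
  data.table::setattr(res, "class",
                      c("population_schedule", class(res)))
  res[]
}

#' Peak synchrony of a population schedule
#'
#' The maximum single-day fraction of the population present and (if moult
#' columns exist) moulting, with the day of each maximum; ties broken by
#' the earliest day.
#'
#' @param schedule a \code{\link{build_schedule}} result.
#' @return list with \code{peak_present} and \code{peak_moulting}, each
#'   \code{list(fraction, day)} (\code{peak_moulting} is \code{NULL} for
#'   presence-only schedules).
#' @export
peak_synchrony <- function(schedule) {
  stopifnot(nrow(schedule) > 0)
  pk <- function(v) {
    i <- which.max(v)  # which.max returns the first (earliest) maximum
    list(fraction = v[i], day = schedule$day[i])
  }
  list(peak_present = pk(schedule$frac_present),
       peak_moulting = if ("frac_moulting" %in% names(schedule))
         pk(schedule$frac_moulting) else NULL)
}

#' Population event window
#'
#' Length of the central \code{coverage} population window: from the
#' \code{(1-coverage)/2} empirical quantile of the start dates to the
#' \code{1-(1-coverage)/2} quantile of the end dates. With all dates equal
#' the window collapses to the individual event duration.
#'
#' @param starts event start dates (e.g. pooled moult starts or arrivals).
#' @param ends matching end dates (defaults to \code{starts}: a window of
#'   instantaneous events).
#' @param coverage central coverage in (0, 1), default 0.95.
#' @return window length in days.
#' @export
population_window <- function(starts, ends = starts, coverage = 0.95) {
  stopifnot(length(starts) >= 2, length(ends) == length(starts),
            coverage > 0, coverage < 1)
  alpha <- (1 - coverage) / 2
  as.numeric(quantile(ends, 1 - alpha, names = FALSE) -
               quantile(starts, alpha, names = FALSE))
}

#' Simulate peak synchrony for a Normal-start population
#'
#' Draws \code{n} event start dates from a Normal distribution whose
#' population window (central \code{coverage} interval of starts through
#' ends) equals \code{window}, gives every individual the same fixed event
#' duration, and measures peak synchrony on the daily schedule. Used for
#' desk-scale checks of how individual duration and population spread set
#' the peak fraction: with starts \eqn{N(\mu, \sigma)} and fixed duration
#' \eqn{d}, the expected peak is \eqn{2\Phi(d/2\sigma) - 1}.
#'
#' @param n number of individuals.
#' @param window population window length in days (95\% by default).
#' @param duration fixed individual event duration in days.
#' @param seed integer seed.
#' @param coverage central coverage defining the window (default 0.95).
#' @return list with \code{peak} (fraction), \code{day}, \code{sigma} used,
#'   and the \code{schedule}.
#' @export
simulate_population_peak <- function(n, window, duration, seed = 1,
                                     coverage = 0.95) {
  stopifnot(window > duration)
  z <- qnorm(1 - (1 - coverage) / 2)
  sigma <- (window - duration) / (2 * z)
  set.seed(seed)
  starts <- rnorm(n, 0, sigma)
  sched <- build_schedule(data.table::data.table(
    arrival = starts, moult_start = starts, moult_end = starts + duration,
    departure = starts + duration))
  pk <- peak_synchrony(sched)
  list(peak = pk$peak_present$fraction, day = pk$peak_present$day,
       sigma = sigma, schedule = sched)
}
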