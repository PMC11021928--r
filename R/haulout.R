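#' Select well-determined cycles for the haul-out model
#'
#' Keeps cycles whose 95\% credible interval for moult start is strictly
#' narrower than \code{ci_width_max} days.
#'
#' @param events per-cycle event summaries from \code{\link{derive_events}}.
#' @param ci_width_max maximum CI width in days (default 6, strict).
#' @return the selected rows; attributes \code{n_kept} and \code{n_dropped}
#'   carry the counts.
#' @export
select_subset <- function(events, ci_width_max = 6) {
  dt <- data.table::as.data.table(events)
  keep <- (dt$start_q97.5 - dt$start_q2.5) < ci_width_max
  res <- dt[keep]
  data.table::setattr(res, "n_kept", sum(keep))
  data.table::setattr(res, "n_dropped", sum(!keep))
  res[]
}

# number of surveyed days < x (sv sorted ascending, x integer)
n_surv_before <- function(sv, x) findInterval(x - 0.5, sv)
# number of surveyed days <= x
n_surv_upto <- function(sv, x) findInterval(x + 0.5, sv)

# vectorized categorical sampling: one column index per row of weight
# matrix W (rows need not be normalized)
sample_rows <- function(W) {
  cum <- W
  for (j in seq_len(ncol(W))[-1]) cum[, j] <- cum[, j - 1L] + W[, j]
  u <- runif(nrow(W)) * cum[, ncol(W)]
  rowSums(cum < u) + 1L
}

#' Detection-corrected arrival and departure dates
#'
#' The first sighting of a cycle lags true arrival by the surveyed days on
#' which the animal was present but missed. With latent arrival day
#' \eqn{a \le f} (first sighting \eqn{f}), the gap likelihood is
#' \eqn{(1-p)^k} with \eqn{k} the number of surveyed days in \eqn{[a, f)},
#' under a uniform prior on a window before \eqn{f}; the construction is
#' mirrored after the last sighting for departure. Detection probabilities
#' are separate for the two boundaries, constant within a season, and
#' hierarchical across years (per-year Beta draws around a learned common
#' mean). Interior surveyed days between first and last sighting, when the
#' animal is known to be ashore, identify the detection probabilities
#' (arrival uses the first half of each haul-out, departure the second).
#' Sampling is Gibbs (conjugate Beta updates and categorical latent days)
#' with a Metropolis step for the hierarchical means.
#'
#' Day convention: the latent integer day \eqn{a} is the first day ashore;
#' the reported continuous arrival is \eqn{a - 0.5} (departure
#' \eqn{d + 0.5}), and duration is computed draw-wise as departure minus
#' arrival.
#'
#' @param sightings sightings of the selected cycles.
#' @param surveys survey calendar \code{data.table} with columns
#'   \code{year, day}.
#' @param window prior window length in days before the first sighting
#'   (after the last, for departure); doubled for single-sighting cycles.
#' @param draws,warmup,seed Gibbs sampler settings.
#' @param kappa concentration of the across-year Beta hierarchy.
#' @param fixed_p_arr,fixed_p_dep optionally pin the detection
#'   probabilities instead of estimating them (used in oracle checks).
#' @return list of class \code{haulout_fit}: \code{estimates} (one row per
#'   cycle with posterior summaries of arrival, departure, duration and the
#'   integer first-day-ashore \code{arrival_day}), \code{detection}
#'   (per-year posterior of the two detection probabilities),
#'   \code{arrival_draws} / \code{departure_draws} matrices.
#' @export
fit_arrival_departure <- function(sightings, surveys, window = 30L,
                                  draws = 1500L, warmup = 500L, seed = 1L,
                                  kappa = 10, fixed_p_arr = NULL,
                                  fixed_p_dep = NULL) {
  if (is.null(surveys) || nrow(surveys) == 0) stop("empty survey calendar")
  dt <- data.table::as.data.table(sightings)
  set.seed(seed)
  cyc <- dt[, .(first = min(date), last = max(date),
                category = category[1], n_sight = .N),
            by = .(animal_id, year)]
  cyc[, single_sighting := first == last]
  cyc[, win := ifelse(single_sighting, 2L * window, window)]
  maxwin <- max(cyc$win)
  years <- sort(unique(cyc$year))
  sv <- lapply(years, function(yy) sort(surveys[year == yy, day]))
  names(sv) <- as.character(years)
  cyc[, yidx := match(year, years)]
  n <- nrow(cyc)

  # K matrices: missed-survey counts per candidate latent day
  K_arr <- matrix(NA_real_, n, maxwin + 1L)
  K_dep <- matrix(NA_real_, n, maxwin + 1L)
  for (i in seq_len(n)) {
    s <- sv[[cyc$yidx[i]]]
    j <- 0:cyc$win[i]
    K_arr[i, j + 1L] <- n_surv_before(s, cyc$first[i]) -
      n_surv_before(s, cyc$first[i] - j)
    K_dep[i, j + 1L] <- n_surv_upto(s, cyc$last[i] + j) -
      n_surv_upto(s, cyc$last[i])
  }
  # interior detection trials (animal known present between first and last)
  sight_key <- paste(dt$animal_id, dt$year, dt$date)
  succ_arr <- succ_dep <- fail_arr <- fail_dep <- numeric(length(years))
  for (i in seq_len(n)) {
    s <- sv[[cyc$yidx[i]]]
    mid <- (cyc$first[i] + cyc$last[i]) / 2
    inter <- s[s > cyc$first[i] & s < cyc$last[i]]
    ia <- inter[inter <= mid]; id <- inter[inter > mid]
    hit <- function(dd) paste(cyc$animal_id[i], cyc$year[i], dd) %in% sight_key
    y <- cyc$yidx[i]
    succ_arr[y] <- succ_arr[y] + 1 + sum(hit(ia))    # day `first` is a detection
    fail_arr[y] <- fail_arr[y] + sum(!hit(ia))
    succ_dep[y] <- succ_dep[y] + 1 + sum(hit(id))    # day `last` is a detection
    fail_dep[y] <- fail_dep[y] + sum(!hit(id))
  }

  gibbs_side <- function(K, succ, fail, fixed_p) {
    p <- if (is.null(fixed_p)) rep(0.5, length(years)) else
      rep(fixed_p, length(years))
    mu <- 0.5
    lat <- integer(n)
    keep_lat <- matrix(0L, draws, n)
    keep_p <- matrix(0, draws, length(years))
    keep_mu <- numeric(draws)
    Kz <- K; Kz[is.na(Kz)] <- Inf   # outside each cycle's window
    for (it in seq_len(warmup + draws)) {
      W <- (1 - p[cyc$yidx])^Kz
      W[Kz == Inf] <- 0
      if (any(rowSums(W) == 0)) { # p == 1: all mass on k == 0 days
        z <- rowSums(W) == 0
        W[z, ] <- (Kz[z, , drop = FALSE] == 0) * 1
      }
      lat <- sample_rows(W) - 1L   # offset in days from the sighting
      if (is.null(fixed_p)) {
        gap_miss <- vapply(seq_along(years), function(y) {
          idx <- cyc$yidx == y
          sum(K[cbind(which(idx), lat[idx] + 1L)])
        }, 0)
        p <- rbeta(length(years), mu * kappa + succ,
                   (1 - mu) * kappa + fail + gap_miss)
        p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
        # MH on the hierarchy mean
        prop <- plogis(qlogis(mu) + rnorm(1, 0, 0.4))
        lr <- sum(dbeta(p, prop * kappa, (1 - prop) * kappa, log = TRUE)) -
          sum(dbeta(p, mu * kappa, (1 - mu) * kappa, log = TRUE))
        if (log(runif(1)) < lr) mu <- prop
      }
      if (it > warmup) {
        keep_lat[it - warmup, ] <- lat
        keep_p[it - warmup, ] <- p
        keep_mu[it - warmup] <- mu
      }
    }
    list(lat = keep_lat, p = keep_p, mu = keep_mu)
  }

  arr <- gibbs_side(K_arr, succ_arr, fail_arr, fixed_p_arr)
  dep <- gibbs_side(K_dep, succ_dep, fail_dep, fixed_p_dep)

  arrival_draws <- sweep(-arr$lat, 2, cyc$first, "+") - 0.5
  departure_draws <- sweep(dep$lat, 2, cyc$last, "+") + 0.5
  duration_draws <- departure_draws - arrival_draws
  summ <- function(M, prefix) {
    S <- t(apply(M, 2, posterior_summary))
    colnames(S) <- paste0(prefix, "_", c("mean", "sd", "q2.5", "q50", "q97.5"))
    S
  }
  est <- cbind(cyc[, .(animal_id, year, category, first_sighting = first,
                       last_sighting = last, n_sight, single_sighting)],
               data.table::as.data.table(summ(arrival_draws, "arrival")),
               data.table::as.data.table(summ(departure_draws, "departure")),
               data.table::as.data.table(summ(duration_draws, "duration")))
  est[, arrival_day_mean := arrival_mean + 0.5]
  est[, arrival_day_map := cyc$first - apply(arr$lat, 2, function(v)
    as.integer(names(which.max(table(v)))))]
  detection <- data.table::rbindlist(lapply(seq_along(years), function(y) {
    pa <- posterior_summary(arr$p[, y]); pd <- posterior_summary(dep$p[, y])
    data.table::data.table(year = years[y],
                           p_arr_mean = pa[["mean"]], p_arr_sd = pa[["sd"]],
                           p_dep_mean = pd[["mean"]], p_dep_sd = pd[["sd"]])
  }))
  structure(list(estimates = est[], detection = detection,
                 mu_arr = arr$mu, mu_dep = dep$mu,
                 arrival_draws = arrival_draws,
                 departure_draws = departure_draws,
                 settings = list(window = window, draws = draws,
                                 warmup = warmup, seed = seed,
                                 kappa = kappa)),
            class = "haulout_fit")
}

#' @export
#' @method print haulout_fit
print.haulout_fit <- function(x, ...) {
  cat("Detection-corrected haul-out fit:", nrow(x$estimates), "cycles,",
      nrow(x$detection), "year(s)\n")
  cat("  mean detection p (arrival):",
      round(mean(x$detection$p_arr_mean), 3),
      " (departure):", round(mean(x$detection$p_dep_mean), 3), "\n")
  invisible(x)
}

#' Category-level haul-out summaries
#'
#' Per-category means and standard errors of arrival, departure and
#' haul-out duration; when moult event summaries are supplied, also the
#' pre-moult gap (moult start minus arrival) and post-moult gap (departure
#' minus moult end).
#'
#' @param haulout a \code{haulout_fit} or its \code{estimates} table.
#' @param events optional \code{\link{derive_events}} table to merge on
#'   \code{animal_id, year}.
#' @param categories categories to report (default: all present); an empty
#'   requested category is omitted with a warning.
#' @return \code{data.table}, one row per category.
#' @export
summarize_categories <- function(haulout, events = NULL, categories = NULL) {
  est <- if (inherits(haulout, "haulout_fit")) haulout$estimates else
    data.table::as.data.table(haulout)
  est <- data.table::copy(est)
  if (!is.null(events)) {
    ev <- data.table::as.data.table(events)[, .(animal_id, year, start_mean,
                                                end_mean)]
    est <- ev[est, on = c("animal_id", "year")]
    est[, pre_gap := start_mean - arrival_mean]
    est[, post_gap := departure_mean - end_mean]
  }
  if (is.null(categories)) categories <- sort(unique(est$category))
  missing_cat <- setdiff(categories, unique(est$category))
  if (length(missing_cat) > 0)
    warning("no cycles for category: ", paste(missing_cat, collapse = ", "),
            "; omitted")
  categories <- setdiff(categories, missing_cat)
  se <- function(x) sd(x) / sqrt(length(x))
  res <- est[category %in% categories, {
    out <- list(n = .N,
                arrival = mean(arrival_mean), arrival_se = se(arrival_mean),
                departure = mean(departure_mean),
                departure_se = se(departure_mean),
                duration = mean(duration_mean),
                duration_se = se(duration_mean))
    if (!is.null(events)) {
      out <- c(out, list(pre_gap = mean(pre_gap), pre_gap_se = se(pre_gap),
                         post_gap = mean(post_gap),
                         post_gap_se = se(post_gap)))
    }
    out
  }, by = category]
  data.table::setorder(res, category)
  res[]
}
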