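#' Filter moult cycles by inclusion criteria
#'
#' A cycle (one animal in one year) enters the moult model only when its
#' sighting series can pin the logistic curve down: at least
#' \code{min_observations} sightings, at least one score below
#' \code{early_max} percent and at least one above \code{late_min} percent.
#'
#' @param sightings sighting \code{data.table} (columns \code{animal_id,
#'   year, category, date, percent_moulted}).
#' @param min_observations minimum sightings per cycle (default 6).
#' @param early_max a cycle needs one score strictly below this (default 10).
#' @param late_min a cycle needs one score strictly above this (default 90).
#' @return list with \code{eligible} (sightings of kept cycles),
#'   \code{cycles} (per-cycle summary with \code{eligible} flag) and
#'   \code{report} (a \code{data.table} of exclusion reasons and counts; a
#'   cycle failing several criteria is counted under each).
#' @export
filter_cycles <- function(sightings, min_observations = 6, early_max = 10,
                          late_min = 90) {
  empty_report <- data.table::data.table(
    reason = c("min_observations", "no_early_observation",
               "no_late_observation"), n_cycles = 0L)
  if (is.null(sightings) || nrow(sightings) == 0) {
    return(list(eligible = data.table::data.table(), cycles = data.table::data.table(),
                report = empty_report))
  }
  dt <- data.table::as.data.table(sightings)
  cyc <- dt[, .(n_obs = .N, min_pct = min(percent_moulted),
                max_pct = max(percent_moulted),
                category = category[1]),
            by = .(animal_id, year)]
  cyc[, `:=`(fail_n = n_obs < min_observations,
             fail_early = !(min_pct < early_max),
             fail_late = !(max_pct > late_min))]
  cyc[, eligible := !(fail_n | fail_early | fail_late)]
  report <- data.table::data.table(
    reason = c("min_observations", "no_early_observation",
               "no_late_observation"),
    n_cycles = c(sum(cyc$fail_n), sum(cyc$fail_early), sum(cyc$fail_late)))
  keep <- cyc[eligible == TRUE, .(animal_id, year)]
  eligible <- dt[keep, on = c("animal_id", "year")]
  list(eligible = eligible[], cycles = cyc[], report = report)
}

# crude per-cycle logistic estimates used to initialize the sampler:
# regress logit of the clipped fraction on date
init_cycle_params <- function(t, y) {
  yc <- pmin(pmax(y, 0.01), 0.99)
  z <- qlogis(yc)
  b <- tryCatch({
    fit <- stats::lm.fit(cbind(1, t), z)
    fit$coefficients
  }, error = function(e) c(0, NA))
  slope <- b[2]
  if (!is.finite(slope) || slope <= 1e-3) {
    w <- y * (1 - y) + 0.02
    return(c(t50 = sum(t * w) / sum(w), scale = 1.5))
  }
  c(t50 = -b[1] / slope, scale = min(max(1 / slope, 0.2), 20))
}

#' Fit the hierarchical Bayesian logistic moult model
#'
#' Fits all supplied cycles at once. The observed integer score is modelled
#' as a rounded, clamped Normal read-out (sd \code{sigma_obs}) of the latent
#' fraction \code{logistic((t - t50_i)/scale_i)} -- an interval-censored
#' Normal on 0..100, whose boundary cells absorb the tails so exact 0/100
#' scores are admissible without the boundary-attraction bias a truncated
#' Normal density would introduce -- with
#' \code{t50_i = mu_t50 + a[animal] + b[year]} and
#' \code{log scale_i = mu_logscale + c[animal] + d[year]}; the animal and
#' year effects have zero-mean Normal hyper-distributions whose sds carry
#' half-Normal priors. Sampling is adaptive Metropolis-within-Gibbs (Rcpp);
#' chains are seeded reproducibly from \code{seed}.
#'
#' Callers normally run one model per age-sex category (skip adult females
#' belong in the adult run and are summarized post hoc); see
#' \code{\link{fit_by_category}}.
#'
#' @param sightings eligible sightings (see \code{\link{filter_cycles}}).
#' @param chains number of chains (default 2).
#' @param iter iterations per chain including warmup.
#' @param warmup warmup (adaptation) iterations, discarded.
#' @param seed integer seed.
#' @param rhat_max,ess_min convergence gate for reported parameters; a
#'   violation raises a structured warning of class
#'   \code{moultphen_nonconvergence} listing offending parameters.
#' @param contamination fixed weight of a Uniform(0,1) contamination
#'   component mixed into the truncated-Normal likelihood (default 0.02).
#'   Rare gross scoring errors (a fully moulted animal recorded as 0\%, or
#'   vice versa) are otherwise impossible under the Normal tail and would
#'   inflate \code{sigma_obs} enough to bias durations; the contamination
#'   absorbs them without modelling the flip process. Set to 0 for the pure
#'   truncated-Normal likelihood.
#' @return object of class \code{moult_fit}: cycle table, per-cycle
#'   \code{t50_draws} and \code{scale_draws} matrices (draws x cycles),
#'   hyper-parameter draws, diagnostics table and variance components.
#' @export
fit_hierarchical <- function(sightings, chains = 2L, iter = 2500L,
                             warmup = 1000L, seed = 1L,
                             rhat_max = 1.05, ess_min = 200,
                             contamination = 0.02) {
  dt <- data.table::copy(data.table::as.data.table(sightings))
  stopifnot(nrow(dt) > 0)
  dt[, cycle_key := paste(animal_id, year, sep = "::")]
  cycles <- dt[, .(animal_id = animal_id[1], year = year[1],
                   category = category[1], n_obs = .N,
                   degenerate = length(unique(percent_moulted)) == 1L),
               by = cycle_key]
  if (nrow(cycles) < 2) stop("fit_hierarchical needs at least 2 cycles")
  if (any(cycles$degenerate))
    stop("degenerate_cycle: all scores identical for ",
         paste(cycles[degenerate == TRUE, cycle_key], collapse = ", "))
  cycles[, cycle := .I]
  cycles[, anim := as.integer(factor(animal_id))]
  cycles[, yr := as.integer(factor(year))]
  dt <- dt[cycles[, .(cycle_key, cycle, anim, yr)], on = "cycle_key"]
  n_anim <- max(cycles$anim); n_year <- max(cycles$yr)

  t <- as.numeric(dt$date); y <- dt$percent_moulted / 100
  # crude inits
  ini <- dt[, as.list(init_cycle_params(as.numeric(date),
                                        percent_moulted / 100)),
            by = cycle]
  data.table::setorder(ini, cycle)
  cycles[, `:=`(t50_init = ini$t50, ls_init = log(ini$scale))]
  mu0 <- mean(cycles$t50_init); nu0 <- mean(cycles$ls_init)
  a0 <- cycles[, mean(t50_init) - mu0, by = anim][order(anim), V1]
  c0 <- cycles[, mean(ls_init) - nu0, by = anim][order(anim), V1]
  b0 <- rep(0, n_year); d0 <- rep(0, n_year)
  w <- y * (1 - y) + 0.02
  prior <- list(m0 = sum(t * w) / sum(w), sd_mu_t50 = 30,
                nu0 = nu0, sd_mu_ls = 1.5,
                s_a = 10, s_b = 5, s_c = 1, s_d = 0.5, s_obs = 0.2,
                eps = contamination)
  base_init <- c(mu0, nu0,
                 log(max(sd(a0), 0.5)), log(0.5),
                 log(max(sd(c0), 0.1)), log(0.05), log(0.05),
                 a0, b0, c0, d0)
  npar <- length(base_init)
  chain_draws <- vector("list", chains)
  accept <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * ch)
    init <- base_init + rnorm(npar, 0, 0.02)
    res <- mcmc_moult_chain(t, y, dt$cycle - 1L, cycles$anim - 1L,
                            cycles$yr - 1L, n_anim, n_year,
                            as.integer(iter), as.integer(warmup), init, prior)
    chain_draws[[ch]] <- res$draws
    accept[[ch]] <- res$accept
  }
  par_names <- c("mu_t50", "mu_logscale", "lsig_anim_t50", "lsig_year_t50",
                 "lsig_anim_ls", "lsig_year_ls", "lsigma_obs",
                 paste0("a[", seq_len(n_anim), "]"),
                 paste0("b[", seq_len(n_year), "]"),
                 paste0("c[", seq_len(n_anim), "]"),
                 paste0("d[", seq_len(n_year), "]"))
  for (ch in seq_len(chains)) colnames(chain_draws[[ch]]) <- par_names

  # per-cycle draws, per chain, for diagnostics; then pooled
  iA <- 7L
  t50_by_chain <- lapply(chain_draws, function(D) {
    D[, "mu_t50"] + D[, iA + cycles$anim, drop = FALSE] +
      D[, iA + n_anim + cycles$yr, drop = FALSE]
  })
  ls_by_chain <- lapply(chain_draws, function(D) {
    D[, "mu_logscale"] + D[, iA + n_anim + n_year + cycles$anim, drop = FALSE] +
      D[, iA + 2L * n_anim + n_year + cycles$yr, drop = FALSE]
  })
  diag_of <- function(mats) {
    vapply(seq_len(ncol(mats[[1]])), function(j) {
      m <- vapply(mats, function(x) x[, j], numeric(nrow(mats[[1]])))
      c(rhat_split(m), ess_basic(m))
    }, numeric(2))
  }
  hyper_idx <- 1:7
  hyper_mats <- lapply(hyper_idx, function(k)
    vapply(chain_draws, function(D) D[, k], numeric(nrow(chain_draws[[1]]))))
  dg_hyper <- vapply(hyper_mats, function(m) c(rhat_split(m), ess_basic(m)),
                     numeric(2))
  dg_t50 <- diag_of(t50_by_chain)
  dg_ls <- diag_of(ls_by_chain)
  diagnostics <- data.table::data.table(
    param = c(par_names[hyper_idx],
              paste0("t50[", cycles$cycle_key, "]"),
              paste0("logscale[", cycles$cycle_key, "]")),
    rhat = c(dg_hyper[1, ], dg_t50[1, ], dg_ls[1, ]),
    ess = c(dg_hyper[2, ], dg_t50[2, ], dg_ls[2, ]))

  draws <- do.call(rbind, chain_draws)
  fit <- structure(list(
    cycles = cycles[, .(cycle, cycle_key, animal_id, year, category, n_obs)],
    draws = draws,
    chain = rep(seq_len(chains), each = nrow(chain_draws[[1]])),
    t50_draws = do.call(rbind, t50_by_chain),
    scale_draws = exp(do.call(rbind, ls_by_chain)),
    n_anim = n_anim, n_year = n_year,
    diagnostics = diagnostics,
    accept = accept, prior = prior,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    seed = seed)), class = "moult_fit")
  bad <- diagnostics[rhat > rhat_max | ess < ess_min]
  fit$converged <- nrow(bad) == 0
  if (!fit$converged) {
    w <- simpleWarning(paste0(
      "moult model convergence gate failed for ", nrow(bad), " parameter(s): ",
      paste(utils::head(bad$param, 5), collapse = ", "),
      if (nrow(bad) > 5) ", ..." else "",
      " (max rhat ", round(max(bad$rhat), 3), ", min ess ",
      round(min(bad$ess)), ")"))
    class(w) <- c("moultphen_nonconvergence", class(w))
    warning(w)
  }
  fit
}

#' @export
#' @method print moult_fit
print.moult_fit <- function(x, ...) {
  cat("Hierarchical logistic moult fit\n")
  cat("  cycles:", nrow(x$cycles), " animals:", x$n_anim,
      " years:", x$n_year, "\n")
  cat("  draws:", nrow(x$draws), "over", x$settings$chains, "chains;",
      "converged:", x$converged, "\n")
  ps <- population_summary(x)
  cat("  population mean t50:", round(ps[metric == "pop_mean_t50", mean], 2),
      " mean 5-95% duration:",
      round(ps[metric == "pop_mean_duration", mean], 2), "d\n")
  invisible(x)
}

#' Fit one model run per category group
#'
#' Runs the hierarchical model the way the field analysis is structured:
#' adult reproductive and skip females share one "adult" run (skip results
#' are summarized post hoc from the same posterior), while juvenile females
#' and juvenile males get their own runs. Unknown-status adults should be
#' labelled \code{adult_reproductive} upstream.
#'
#' @param sightings eligible sightings across all categories.
#' @param ... passed to \code{\link{fit_hierarchical}}.
#' @return named list of \code{moult_fit} objects
#'   (\code{adult}, \code{juvenile_female}, \code{juvenile_male}; only
#'   groups with >= 2 cycles are fitted).
#' @export
fit_by_category <- function(sightings, ...) {
  dt <- data.table::as.data.table(sightings)
  groups <- list(adult = c("adult_reproductive", "adult_skip"),
                 juvenile_female = "juvenile_female",
                 juvenile_male = "juvenile_male")
  out <- list()
  for (g in names(groups)) {
    sub <- dt[category %in% groups[[g]]]
    if (nrow(sub) == 0) next
    n_cyc <- nrow(unique(sub[, .(animal_id, year)]))
    if (n_cyc < 2) next
    out[[g]] <- fit_hierarchical(sub, ...)
  }
  out
}

#' Derive per-cycle event dates from a fit
#'
#' Start, midpoint, end and 5--95\% duration are computed draw-wise from the
#' per-cycle posterior (\code{start = t50 - scale ln 19}, \code{end = t50 +
#' scale ln 19}, \code{duration = 2 scale ln 19}), so \code{start + duration
#' = end} holds exactly within every draw, then summarized.
#'
#' @param fit a \code{moult_fit}.
#' @return \code{data.table}, one row per cycle, with posterior mean, sd and
#'   2.5/50/97.5\% quantiles of each event
#'   (\code{start_mean, start_sd, start_q2.5, ...}).
#' @export
derive_events <- function(fit) {
  stopifnot(inherits(fit, "moult_fit"))
  summ <- function(M) {
    out <- t(apply(M, 2, posterior_summary))
    colnames(out) <- c("mean", "sd", "q2.5", "q50", "q97.5")
    out
  }
  s_start <- summ(fit$t50_draws - fit$scale_draws * LN19)
  s_mid <- summ(fit$t50_draws)
  s_end <- summ(fit$t50_draws + fit$scale_draws * LN19)
  s_dur <- summ(2 * fit$scale_draws * LN19)
  res <- data.table::copy(fit$cycles)
  for (ev in c("start", "mid", "end", "duration")) {
    S <- switch(ev, start = s_start, mid = s_mid, end = s_end,
                duration = s_dur)
    for (cn in colnames(S)) res[, (paste0(ev, "_", cn)) := S[, cn]]
  }
  res[]
}

#' Population-level posterior summaries
#'
#' Reports, per draw and then summarized: the hyper-mean moult date
#' (\code{mu_t50}); the population mean 5--95\% duration across individuals
#' in an average year under the fitted lognormal hyper-distribution,
#' \code{2 ln 19 exp(mu_logscale + sd_anim^2 / 2)}, whose posterior sd
#' carries the between-individual uncertainty (a variant additionally
#' integrating the year effect, \code{pop_mean_duration_with_year}, is also
#' returned; with few years its year-sd term is prior-dominated); the
#' finite-sample cycle-average duration; and the variance-component sds.
#'
#' @param fit a \code{moult_fit}.
#' @param categories optional character vector restricting the cycle-average
#'   rows to given categories (e.g. post-hoc skip-female summaries).
#' @return \code{data.table} with one row per metric (mean, sd, quantiles).
#' @export
population_summary <- function(fit, categories = NULL) {
  D <- fit$draws
  sig_c <- exp(D[, "lsig_anim_ls"]); sig_d <- exp(D[, "lsig_year_ls"])
  pop_dur <- 2 * LN19 * exp(D[, "mu_logscale"] + 0.5 * sig_c^2)
  pop_dur_yr <- 2 * LN19 * exp(D[, "mu_logscale"] + 0.5 * (sig_c^2 + sig_d^2))
  keep <- if (is.null(categories)) seq_len(nrow(fit$cycles)) else
    which(fit$cycles$category %in% categories)
  cyc_dur <- rowMeans(2 * LN19 * fit$scale_draws[, keep, drop = FALSE])
  cyc_t50 <- rowMeans(fit$t50_draws[, keep, drop = FALSE])
  metrics <- list(pop_mean_t50 = D[, "mu_t50"],
                  pop_mean_duration = pop_dur,
                  pop_mean_duration_with_year = pop_dur_yr,
                  cycle_mean_duration = cyc_dur,
                  cycle_mean_t50 = cyc_t50,
                  sd_anim_t50 = exp(D[, "lsig_anim_t50"]),
                  sd_year_t50 = exp(D[, "lsig_year_t50"]),
                  sd_anim_logscale = sig_c,
                  sd_year_logscale = sig_d,
                  sigma_obs = exp(D[, "lsigma_obs"]))
  res <- data.table::rbindlist(lapply(names(metrics), function(nm) {
    s <- posterior_summary(metrics[[nm]])
    data.table::data.table(metric = nm, mean = s[["mean"]], sd = s[["sd"]],
                           q2.5 = s[["q2.5"]], q50 = s[["q50"]],
                           q97.5 = s[["q97.5"]])
  }))
  res[]
}
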