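# Category comparisons, variance partitioning and the annual-cycle variance
# chain. Gamma log-link mixed models are delegated to lme4::glmer; start
# dates must be re-expressed as positive values (days since 1 March,
# day-of-year 60) before gamma modelling.

#' Shift day-of-year dates to a positive season origin
#' @param dates day-of-year values.
#' @param origin season origin (default day 60, 1 March).
#' @return days since origin.
#' @export
days_since_origin <- function(dates, origin = 60) dates - origin

quiet_glmer <- function(...) {
  withCallingHandlers(
    suppressMessages(lme4::glmer(...)),
    warning = function(w) {
      if (grepl(paste0("failed to converge|Model is nearly unidentifiable|",
                       "singular|scaled gradient|Hessian|var-cov|",
                       "variance-covariance"),
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# all-pairs grouping letters by insert-and-absorb from a logical
# "not significantly different" matrix
grouping_letters <- function(nsd) {
  k <- nrow(nsd)
  groups <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(nsd[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i); placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  # absorb redundant groups
  keep <- rep(TRUE, length(groups))
  for (g in seq_along(groups))
    for (h in seq_along(groups))
      if (g != h && keep[h] && all(groups[[g]] %in% groups[[h]]) &&
          length(groups[[g]]) < length(groups[[h]])) keep[g] <- FALSE
  groups <- groups[keep]
  letters_out <- character(k)
  for (g in seq_along(groups))
    for (i in groups[[g]])
      letters_out[i] <- paste0(letters_out[i], letters[g])
  letters_out
}

#' Compare a moult metric across age-sex categories
#'
#' Gamma log-link mixed model of a positive per-cycle metric with category
#' as fixed effect and random intercepts for individual and year, followed
#' by all-pairs contrasts with a Tukey (studentized-range) multiplicity
#' adjustment at \code{alpha}, summarized as grouping letters (categories
#' sharing a letter are not significantly different).
#'
#' @param values positive metric values, one per cycle (durations, or start
#'   dates shifted with \code{\link{days_since_origin}}).
#' @param category,animal,year parallel vectors of labels.
#' @param alpha significance level for the letters (default 0.05).
#' @return list with \code{table} (category, n, response-scale mean, se,
#'   letter), \code{contrasts} (pairwise log-scale differences, z and
#'   Tukey-adjusted p) and the fitted \code{model}.
#' @export
compare_categories <- function(values, category, animal, year,
                               alpha = 0.05) {
  if (any(values <= 0))
    stop("non-positive metric values at rows: ",
         paste(utils::head(which(values <= 0), 10), collapse = ", "))
  dd <- data.frame(v = values, category = factor(category),
                   animal = factor(animal), year = factor(year))
  form <- if (nlevels(dd$year) > 1)
    v ~ 0 + category + (1 | animal) + (1 | year)
  else v ~ 0 + category + (1 | animal)
  m <- quiet_glmer(form, data = dd, family = stats::Gamma(link = "log"))
  beta <- lme4::fixef(m)
  V <- as.matrix(suppressWarnings(vcov(m)))
  k <- length(beta)
  lev <- sub("^category", "", names(beta))
  pairs <- utils::combn(k, 2)
  zstat <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    (beta[i] - beta[j]) / sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
  })
  pval <- ptukey(abs(zstat) * sqrt(2), nmeans = k, df = Inf,
                 lower.tail = FALSE)
  nsd <- diag(TRUE, k)
  for (c2 in seq_len(ncol(pairs))) {
    ns <- pval[c2] >= alpha
    nsd[pairs[1, c2], pairs[2, c2]] <- ns
    nsd[pairs[2, c2], pairs[1, c2]] <- ns
  }
  lets <- grouping_letters(nsd)
  tab <- data.table::data.table(
    category = lev,
    n = as.integer(table(dd$category)[lev]),
    mean = as.numeric(exp(beta)),
    se = as.numeric(exp(beta) * sqrt(diag(V))),
    letter = lets)
  contrasts <- data.table::data.table(
    pair = apply(pairs, 2, function(ij) paste(lev[ij], collapse = " - ")),
    log_diff = apply(pairs, 2, function(ij) beta[ij[1]] - beta[ij[2]]),
    z = zstat, p_tukey = pval)
  list(table = tab[], contrasts = contrasts[], model = m)
}

#' Partition variance between fixed structure and individual
#'
#' Fits \code{metric ~ category * year + (1 | animal)} and decomposes
#' variance on the link (log) scale into the fixed component (variance of
#' the fixed-effect linear predictor across observations), the individual
#' random-intercept variance, and the residual. For the gamma log link the
#' residual on the latent log scale is approximated by
#' \code{log(1 + dispersion)}. Because the published convention is
#' ambiguous, both shares are returned: with and without the residual in
#' the denominator.
#'
#' @param values metric values (positive for the gamma family).
#' @param category,year,animal parallel label vectors.
#' @param family \code{"gamma"} (log link, default) or \code{"gaussian"}
#'   (identity link, used by the ANOVA cross-check).
#' @return list of class \code{variance_partition} with components
#'   \code{var_fixed}, \code{var_individual}, \code{var_residual},
#'   \code{share_individual}, \code{share_individual_no_resid},
#'   \code{shares} (all three, summing to 1), \code{dropped_interaction}
#'   and \code{model}.
#' @export
partition_variance <- function(values, category, year, animal,
                               family = c("gamma", "gaussian")) {
  family <- match.arg(family)
  dd <- data.frame(v = values, category = factor(category),
                   year = factor(year), animal = factor(animal))
  if (length(unique(dd$animal)) < 2 || anyNA(dd$v))
    stop("need >= 2 animals and complete values")
  dropped <- nlevels(dd$category) < 2 || nlevels(dd$year) < 2
  fixed <- if (!dropped) "category * year"
  else if (nlevels(dd$category) >= 2) "category"
  else if (nlevels(dd$year) >= 2) "year" else "1"
  form <- as.formula(paste("v ~", fixed, "+ (1 | animal)"))
  if (family == "gamma") {
    if (any(dd$v <= 0)) stop("gamma family needs positive values")
    m <- quiet_glmer(form, data = dd, family = stats::Gamma(link = "log"))
    disp <- stats::sigma(m)^2
    var_resid <- log1p(disp)    # lognormal approximation on the link scale
  } else {
    m <- suppressMessages(lme4::lmer(form, data = dd, REML = TRUE))
    var_resid <- stats::sigma(m)^2
  }
  X <- model.matrix(m)
  eta_fixed <- as.numeric(X %*% lme4::fixef(m))
  var_fixed <- var(eta_fixed)
  vc <- as.data.frame(lme4::VarCorr(m))
  var_ind <- vc$vcov[vc$grp == "animal"][1]
  total <- var_fixed + var_ind + var_resid
  structure(list(
    var_fixed = var_fixed, var_individual = var_ind,
    var_residual = var_resid,
    share_individual = var_ind / total,
    share_individual_no_resid = var_ind / (var_fixed + var_ind),
    shares = c(fixed = var_fixed / total, individual = var_ind / total,
               residual = var_resid / total),
    dropped_interaction = dropped, family = family, model = m),
    class = "variance_partition")
}

#' @export
#' @method print variance_partition
print.variance_partition <- function(x, ...) {
  cat("Variance partition (", x$family, ", link scale)\n", sep = "")
  cat(sprintf("  fixed (category x year): %.4f (%.1f%%)\n", x$var_fixed,
              100 * x$shares["fixed"]))
  cat(sprintf("  individual:              %.4f (%.1f%%)\n",
              x$var_individual, 100 * x$shares["individual"]))
  cat(sprintf("  residual:                %.4f (%.1f%%)\n", x$var_residual,
              100 * x$shares["residual"]))
  if (x$dropped_interaction)
    cat("  note: category x year interaction dropped (degenerate design)\n")
  invisible(x)
}

#' Phenological-compensation regression
#'
#' Within each category, gamma log-link mixed regression of haul-out
#' duration on arrival date (individual random intercept):
#' \code{log E[duration] = a + slope * arrival}. Reports the slope (per-day
#' multiplicative change in duration), its Wald CI, and the fitted
#' earliest-versus-latest arrival-decile duration ratio
#' \code{exp(slope * (mean arrival of earliest decile - mean arrival of
#' latest decile))}.
#'
#' @param duration positive haul-out durations, one per cycle.
#' @param arrival arrival dates (day-of-year).
#' @param category,animal parallel label vectors.
#' @param conf confidence level for the slope CI.
#' @return \code{data.table}, one row per category: slope, CI, z, p,
#'   decile ratio. Categories with fewer than 10 cycles are refused with a
#'   warning and omitted.
#' @export
compensation_regression <- function(duration, arrival, category, animal,
                                    conf = 0.95) {
  if (any(duration <= 0)) stop("non-positive durations")
  dd <- data.frame(duration = duration, arrival = arrival,
                   category = as.character(category),
                   animal = factor(animal))
  zq <- qnorm(1 - (1 - conf) / 2)
  out <- list()
  for (cc in sort(unique(dd$category))) {
    sub <- dd[dd$category == cc, ]
    if (nrow(sub) < 10) {
      warning("category ", cc, " has fewer than 10 cycles; refused")
      next
    }
    sub$arr_c <- sub$arrival - mean(sub$arrival)
    m <- quiet_glmer(duration ~ arr_c + (1 | animal), data = sub,
                     family = stats::Gamma(link = "log"))
    beta <- lme4::fixef(m)[["arr_c"]]
    se <- sqrt(as.matrix(suppressWarnings(vcov(m)))["arr_c", "arr_c"])
    qs <- quantile(sub$arrival, c(0.1, 0.9), names = FALSE)
    a_early <- mean(sub$arrival[sub$arrival <= qs[1]])
    a_late <- mean(sub$arrival[sub$arrival >= qs[2]])
    out[[cc]] <- data.table::data.table(
      category = cc, n = nrow(sub), slope = beta, se = se,
      ci_lo = beta - zq * se, ci_hi = beta + zq * se,
      z = beta / se, p = 2 * pnorm(-abs(beta / se)),
      decile_ratio = exp(beta * (a_early - a_late)))
  }
  data.table::rbindlist(out)[]
}

#' Literature constants for the breeding season
#'
#' Synthetic stand-in defaults for the externally sourced breeding-season
#' timing (mean breeding arrival in mid January with modest spread; birth 6
#' days after arrival; weaning and departure 27 days after birth). These
#' are configuration constants, never computed from data, and are labelled
#' as such in \code{\link{annual_cycle_chain}} output.
#'
#' @param arrival_mean,arrival_sd breeding arrival mean day-of-year and sd.
#' @param birth_offset days from breeding arrival to birth.
#' @param birth_sd sd of birth date.
#' @param lactation_days days from birth to weaning/departure.
#' @param departure_sd sd of post-breeding departure date.
#' @return named list.
#' @export
breeding_constants <- function(arrival_mean = 13, arrival_sd = 5,
                               birth_offset = 6, birth_sd = 5,
                               lactation_days = 27, departure_sd = 5.5) {
  list(arrival_mean = arrival_mean, arrival_sd = arrival_sd,
       birth_offset = birth_offset, birth_sd = birth_sd,
       lactation_days = lactation_days, departure_sd = departure_sd)
}

#' Annual-cycle variance chain
#'
#' Orders the eight life-history events of a reproductive female's year --
#' breeding arrival, birth, weaning/short-trip departure (all from supplied
#' literature constants), then moult arrival, moult start, moult end and
#' moult departure (computed from this pipeline), and the long trip -- and
#' reports each event's mean date and standard deviation. The interesting
#' property is the sd ordering across the moult events: arrival-duration
#' compensation shrinks variance from moult arrival toward departure.
#'
#' @param events merged per-cycle table with columns \code{arrival,
#'   moult_start, moult_end, departure} (reproductive females).
#' @param constants \code{\link{breeding_constants}}.
#' @return \code{data.table} (event, mean_day, sd, source) of class
#'   \code{annual_cycle}; attribute \code{sd_declines} says whether
#'   sd(moult arrival) > sd(moult start) > sd(moult departure).
#' @export
annual_cycle_chain <- function(events, constants = breeding_constants()) {
  dt <- data.table::as.data.table(events)
  need <- c("arrival", "moult_start", "moult_end", "departure")
  missing_ev <- setdiff(need, names(dt))
  if (length(missing_ev) > 0)
    warning("missing moult events omitted: ",
            paste(missing_ev, collapse = ", "))
  rows <- list(
    data.table::data.table(event = "breeding_arrival",
                           mean_day = constants$arrival_mean,
                           sd = constants$arrival_sd,
                           source = "external-constant"),
    data.table::data.table(event = "birth",
                           mean_day = constants$arrival_mean +
                             constants$birth_offset,
                           sd = constants$birth_sd,
                           source = "external-constant"),
    data.table::data.table(event = "weaning_departure",
                           mean_day = constants$arrival_mean +
                             constants$birth_offset +
                             constants$lactation_days,
                           sd = constants$departure_sd,
                           source = "external-constant"))
  lab <- c(arrival = "moult_arrival", moult_start = "moult_start",
           moult_end = "moult_end", departure = "moult_departure")
  for (col in intersect(need, names(dt))) {
    rows[[length(rows) + 1L]] <- data.table::data.table(
      event = lab[[col]], mean_day = mean(dt[[col]]), sd = sd(dt[[col]]),
      source = "this_pipeline")
  }
  rows[[length(rows) + 1L]] <- data.table::data.table(
    event = "long_trip_start",
    mean_day = if ("departure" %in% names(dt)) mean(dt$departure) else NA,
    sd = if ("departure" %in% names(dt)) sd(dt$departure) else NA,
    source = "alias_of_moult_departure")
  res <- data.table::rbindlist(rows)
  sds <- setNames(res$sd, res$event)
  declines <- all(c("moult_arrival", "moult_start", "moult_departure") %in%
                    names(sds)) &&
    sds[["moult_arrival"]] > sds[["moult_start"]] &&
    sds[["moult_start"]] > sds[["moult_departure"]]
  data.table::setattr(res, "sd_declines", declines)
  data.table::setattr(res, "class", c("annual_cycle", class(res)))
  res[]
}
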