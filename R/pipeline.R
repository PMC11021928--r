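#' Pipeline configuration
#'
#' Bundles the generator configuration, sampler settings and filter
#' thresholds for an end-to-end run. Threshold defaults are the analysis
#' defaults (at least 6 observations, one below 10\%, one above 90\%;
#' haul-out subset restricted to start-date CIs narrower than 6 days);
#' overrides are recorded in the run manifest.
#'
#' @param generator a \code{\link{generator_config}} (ignored when
#'   \code{sightings_csv} is given).
#' @param sightings_csv optional path to an existing sighting CSV (the
#'   survey-calendar sidecar \code{<path>.surveys.csv} must exist for the
#'   haul-out stage).
#' @param chains,iter,warmup moult-model sampler settings.
#' @param haulout_draws,haulout_warmup haul-out Gibbs settings.
#' @param min_observations,early_max,late_min cycle inclusion thresholds.
#' @param ci_width_max haul-out subset CI threshold, days.
#' @param window haul-out prior window, days.
#' @param seed integer master seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(generator = generator_config(),
                            sightings_csv = NULL,
                            chains = 2L, iter = 2000L, warmup = 800L,
                            haulout_draws = 1000L, haulout_warmup = 300L,
                            min_observations = 6, early_max = 10,
                            late_min = 90, ci_width_max = 6, window = 30L,
                            seed = 1L) {
  structure(list(generator = generator, sightings_csv = sightings_csv,
                 chains = chains, iter = iter, warmup = warmup,
                 haulout_draws = haulout_draws,
                 haulout_warmup = haulout_warmup,
                 min_observations = min_observations, early_max = early_max,
                 late_min = late_min, ci_width_max = ci_width_max,
                 window = window, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Any key of \code{\link{pipeline_config}} may appear; a \code{generator}
#' section holds \code{\link{generator_config}} keys, with a
#' \code{categories} subsection of per-category overrides
#' (\code{n_individuals}, \code{mean_moult_start}, ...).
#'
#' @param path config file (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  gen_args <- raw$generator
  cats <- default_categories()
  if (!is.null(gen_args$categories)) {
    for (nm in names(gen_args$categories)) {
      for (f in names(gen_args$categories[[nm]]))
        cats[[nm]][[f]] <- gen_args$categories[[nm]][[f]]
    }
    gen_args$categories <- NULL
  }
  gen <- do.call(generator_config, c(list(categories = cats), gen_args))
  raw$generator <- NULL
  do.call(pipeline_config, c(list(generator = gen), raw))
}

write_stage <- function(dt, out_dir, name) {
  path <- file.path(out_dir, name)
  data.table::fwrite(data.table::as.data.table(dt), path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes generation (or CSV ingestion), cycle filtering, the
#' hierarchical moult fit per category group, the detection-corrected
#' haul-out model, the population schedule and the comparison stage,
#' writing every stage's outputs plus a provenance manifest to
#' \code{out_dir}. A stage failure halts the run with the stage name;
#' outputs of completed stages are preserved. Reruns with an identical
#' config and seed produce identical event-summary CSVs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress and counts.
#' @return (invisibly) list with the key tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[moultphen] ", ...)
  manifest <- list(package = "moultphen",
                   version = as.character(packageVersion("moultphen")),
                   seed = config$seed,
                   config_hash = digest::digest(unclass_pipeline(config)),
                   stages = list())
  stage <- function(name, fun) {
    say("stage: ", name)
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(completed = TRUE)
    res
  }

  dat <- stage("ingest", function() {
    if (!is.null(config$sightings_csv)) {
      if (!file.exists(config$sightings_csv))
        stop("sightings file not found: ", config$sightings_csv)
      sightings <- read_sightings(config$sightings_csv)
      list(sightings = sightings, truth = NULL,
           surveys = attr(sightings, "surveys"))
    } else {
      gen <- config$generator
      gen$seed <- config$seed
      truth <- generate_truth(gen)
      sightings <- observe(truth, gen)
      write_sightings(sightings, file.path(out_dir, "sightings.csv"))
      write_stage(truth, out_dir, "truth.csv")
      list(sightings = sightings, truth = truth,
           surveys = survey_calendar(sightings))
    }
  })

  filt <- stage("filter", function() {
    f <- filter_cycles(dat$sightings, config$min_observations,
                       config$early_max, config$late_min)
    write_stage(f$report, out_dir, "exclusion_report.csv")
    say("  cycles in: ", nrow(f$cycles), "; eligible: ",
        sum(f$cycles$eligible))
    f
  })

  events <- stage("moultfit", function() {
    fits <- fit_by_category(filt$eligible, chains = config$chains,
                            iter = config$iter, warmup = config$warmup,
                            seed = config$seed)
    ev <- data.table::rbindlist(lapply(fits, derive_events),
                                idcol = "model_run")
    pop <- data.table::rbindlist(lapply(fits, population_summary),
                                 idcol = "model_run")
    write_stage(ev, out_dir, "moult_events.csv")
    write_stage(pop, out_dir, "population_summary.csv")
    say("  fitted ", nrow(ev), " cycles in ", length(fits), " model run(s)")
    ev
  })

  ho <- stage("haulout", function() {
    sel <- select_subset(events, config$ci_width_max)
    say("  haul-out subset: ", attr(sel, "n_kept"), " kept, ",
        attr(sel, "n_dropped"), " dropped")
    sub <- dat$sightings[sel[, .(animal_id, year)],
                         on = c("animal_id", "year")]
    hf <- fit_arrival_departure(sub, dat$surveys, window = config$window,
                                draws = config$haulout_draws,
                                warmup = config$haulout_warmup,
                                seed = config$seed + 1L)
    write_stage(hf$estimates, out_dir, "haulout.csv")
    write_stage(hf$detection, out_dir, "detection.csv")
    hf
  })

  merged <- stage("merge", function() {
    m <- ho$estimates[, .(animal_id, year, category,
                          arrival = arrival_mean,
                          departure = departure_mean)][
      events[, .(animal_id, year, moult_start = start_mean,
                 moult_end = end_mean,
                 moult_duration = duration_mean)],
      on = c("animal_id", "year"), nomatch = NULL]
    m[, haulout_duration := departure - arrival]
    write_stage(m, out_dir, "merged_events.csv")
    m
  })

  sync <- stage("synchrony", function() {
    sched <- build_schedule(merged)
    peaks <- peak_synchrony(sched)
    write_stage(sched, out_dir, "schedule.csv")
    jsonlite::write_json(
      list(peak_present = peaks$peak_present,
           peak_moulting = peaks$peak_moulting,
           window_moult_95 = population_window(merged$moult_start,
                                               merged$moult_end),
           window_present_95 = population_window(merged$arrival,
                                                 merged$departure)),
      file.path(out_dir, "peaks.json"), auto_unbox = TRUE, digits = NA)
    list(schedule = sched, peaks = peaks)
  })

  comp <- stage("compare", function() {
    res <- list()
    res$compare_duration <- compare_categories(
      merged$moult_duration, merged$category, merged$animal_id,
      merged$year)$table
    vp <- function(v) partition_variance(v, merged$category, merged$year,
                                         merged$animal_id)
    parts <- list(
      moult_duration = vp(merged$moult_duration),
      moult_start = vp(days_since_origin(merged$moult_start)),
      haulout_duration = vp(merged$haulout_duration))
    res$variance <- data.table::rbindlist(lapply(names(parts), function(nm) {
      p <- parts[[nm]]
      data.table::data.table(metric = nm, var_fixed = p$var_fixed,
                             var_individual = p$var_individual,
                             var_residual = p$var_residual,
                             share_individual = p$share_individual,
                             share_individual_no_resid =
                               p$share_individual_no_resid)
    }))
    res$compensation <- compensation_regression(
      merged$haulout_duration, merged$arrival, merged$category,
      merged$animal_id)
    res$chain <- annual_cycle_chain(
      merged[category == "adult_reproductive",
             .(arrival, moult_start, moult_end, departure)])
    write_stage(res$compare_duration, out_dir, "compare_duration.csv")
    write_stage(res$variance, out_dir, "variance_partition.csv")
    write_stage(res$compensation, out_dir, "compensation.csv")
    write_stage(res$chain, out_dir, "annual_cycle.csv")
    res
  })

  manifest$n_sightings <- nrow(dat$sightings)
  manifest$n_cycles_eligible <- sum(filt$cycles$eligible)
  manifest$n_haulout <- nrow(ho$estimates)
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done: ", out_dir)
  invisible(list(sightings = dat$sightings, truth = dat$truth,
                 events = events, haulout = ho, merged = merged,
                 synchrony = sync, compare = comp, manifest = manifest))
}

unclass_pipeline <- function(cfg) {
  x <- unclass(cfg)
  x$generator <- unclass_config(x$generator)
  x
}

#' Command-line entry point
#'
#' \code{moultphen_cli(c("pipeline", "--config", "cfg.yaml", "--out",
#' "runs/x"))} runs the full pipeline; \code{moultphen_cli(c("synthdata",
#' "--out", "sightings.csv", "--seed", "42"))} writes a synthetic sighting
#' table (with optional \code{--config}).
#'
#' @param args character vector of CLI arguments.
#' @return invisibly, the result of the underlying call.
#' @export
moultphen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop("usage: moultphen <pipeline|synthdata> [--config FILE] ",
         "[--out PATH] [--seed INT]")
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--out", type = "character", default = "out"),
      optparse::make_option("--seed", type = "integer", default = 1L))),
    args = args[-1])
  if (cmd == "pipeline") {
    cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
    else pipeline_config()
    cfg$seed <- opts$seed
    invisible(run_pipeline(cfg, opts$out))
  } else if (cmd == "synthdata") {
    gen <- if (!is.null(opts$config)) read_pipeline_config(opts$config)$generator
    else generator_config()
    gen$seed <- opts$seed
    truth <- generate_truth(gen)
    sightings <- observe(truth, gen)
    write_sightings(sightings, opts$out)
    invisible(sightings)
  } else stop("unknown command: ", cmd)
}
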