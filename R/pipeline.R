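# End-to-end orchestration: generate -> tax -> weight dynamics -> BMI
# tables -> diabetes projection -> CRA sensitivity, with reproducibility
# metadata. One root seed fans out to per-stage child seeds so stages can
# be re-run independently yet reproducibly.

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. `population` may be a
#' [population_config()], a list of overrides for it, or a path to a
#' population CSV. Defaults reproduce the package's standard study
#' conditions: n = 10,000 individuals, all four tax scenarios, a 10-year
#' weight horizon and a 2015-2050 diabetes projection under the
#' intermediate incidence scenario with RR 1.26 per serving.
#'
#' @param seed root seed; per-stage seeds are derived from it.
#' @param population population source (see Details).
#' @param scenarios tax scenario names to run.
#' @param horizon_years weight-model horizon.
#' @param caloric_density kcal/ml; @param serving_size_ml ml per serving.
#' @param hall a [hall_parameters()] object.
#' @param diabetes list with elements `incidence_scenario`,
#'   `rr_per_serving`, `excess_mortality_hr`, `start_year`, `end_year`.
#' @param report_years years at which averted cases are reported.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 20140101,
                       population = list(),
                       scenarios = tax_scenarios(),
                       horizon_years = 10,
                       caloric_density = 0.388,
                       serving_size_ml = 355,
                       hall = hall_parameters(),
                       diabetes = list(),
                       report_years = c(2030, 2050)) {
  scenarios <- match.arg(scenarios, tax_scenarios(), several.ok = TRUE)
  dm <- utils::modifyList(list(incidence_scenario = "intermediate",
                               rr_per_serving = 1.26,
                               excess_mortality_hr = 1,
                               start_year = 2015, end_year = 2050),
                          diabetes)
  if (is.list(population) && !inherits(population, "population_config")) {
    population <- utils::modifyList(list(seed = seed + 1), population)
    population <- do.call(population_config, population)
  }
  structure(list(seed = seed, population = population, scenarios = scenarios,
                 horizon_years = horizon_years,
                 caloric_density = caloric_density,
                 serving_size_ml = serving_size_ml, hall = hall,
                 diabetes = dm, report_years = report_years),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [run_config()] fields; unspecified fields keep
#' their defaults. Note that YAML 1.1 resolves a bare `n` key as a
#' boolean, so the population size key may be written `"n"` (quoted);
#' an unquoted `n` is repaired automatically.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.list(y$population) && "FALSE" %in% names(y$population))
    names(y$population)[names(y$population) == "FALSE"] <- "n"
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$hall)) y$hall <- do.call(hall_parameters, y$hall)
  do.call(run_config, y)
}

#' Run the full tax-to-health pipeline
#'
#' Executes population generation, tax application, the dynamic
#' weight-change model, BMI outcome tables, the diabetes projection and
#' the CRA sensitivity analysis for every configured scenario, and (when
#' `outdir` is given) writes the result tables and a run manifest.
#' Identical configuration and seed give identical outputs.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @param outdir optional output directory for CSV tables and manifest.
#' @return invisibly, a list with elements `population`, `consumption`
#'   (per-scenario summary tables), `bmi_change`, `prevalence`, `diabetes`
#'   (per-scenario projections and averted cases), `crm`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))

  pop <- if (is.character(config$population)) {
    read_population(config$population)
  } else {
    generate_population(config$population)
  }
  if (!nrow(pop)) stop("pipeline stage 'population': empty population",
                       call. = FALSE)

  dmcfg <- config$diabetes
  inc <- incidence_schedule(dmcfg$incidence_scenario)
  mort <- mortality_schedule()
  horizon <- dmcfg$start_year:dmcfg$end_year
  births <- birth_projection(years = horizon)
  base_proj <- project_diabetes(
    incidence = inc, mortality = mort, births = births, link = NULL,
    start_year = dmcfg$start_year, end_year = dmcfg$end_year,
    excess_mortality_hr = dmcfg$excess_mortality_hr)

  tables <- list(population = pop)
  consumption <- list(); bmi_change <- list(); prevalence <- list()
  diabetes <- list(); crm <- list()
  for (sc in config$scenarios) {
    ch <- apply_tax(pop, sc, config$caloric_density, config$serving_size_ml)
    consumption[[sc]] <- summarize_consumption(pop, ch)
    panel <- simulate_cohort(pop, ch$delta_kcal, config$hall,
                             years = config$horizon_years,
                             at_years = c(1, min(10, config$horizon_years)))
    bmi_change[[sc]] <- stratified_bmi_change(
      pop, panel, t = min(10, config$horizon_years))
    prevalence[[sc]] <- prevalence_by_category(
      pop, panel[, ncol(panel)], strata = c("overall", "quartile"))
    lk <- risk_link(ses_mean_servings_change(pop, ch),
                    rr_per_serving = dmcfg$rr_per_serving,
                    serving_size_ml = config$serving_size_ml)
    cf <- project_diabetes(
      incidence = inc, mortality = mort, births = births, link = lk,
      start_year = dmcfg$start_year, end_year = dmcfg$end_year,
      excess_mortality_hr = dmcfg$excess_mortality_hr)
    ry <- config$report_years[config$report_years %in% horizon]
    if (!length(ry)) ry <- dmcfg$end_year
    diabetes[[sc]] <- list(
      projection = cf,
      averted = averted_cases(base_proj, cf, ry))
    ode_mean <- -weighted_mean(attr(panel, "baseline_bmi") -
                                 panel[, ncol(panel)], pop$svy_weight)
    crm[[sc]] <- crm_sensitivity_table(pop, ch, ode_mean_change = ode_mean)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ssbtax")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    scenarios = config$scenarios,
    horizon_years = config$horizon_years,
    caloric_density = config$caloric_density,
    serving_size_ml = config$serving_size_ml,
    diabetes = config$diabetes,
    population_n = nrow(pop))

  out <- list(population = pop, consumption = consumption,
              bmi_change = bmi_change, prevalence = prevalence,
              diabetes = list(baseline = base_proj, scenarios = diabetes),
              crm = crm, manifest = manifest)
  if (!is.null(outdir)) write_report(out, outdir)
  invisible(out)
}

#' Write pipeline result tables
#'
#' Emits fixed-header CSVs for the consumption, BMI-change, prevalence,
#' diabetes and sensitivity tables plus `manifest.json` and a
#' human-readable `summary.txt`. Re-running with identical inputs yields
#' byte-identical files.
#'
#' @param result a [run_pipeline()] result.
#' @param outdir directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(result, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir, call. = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  bind_scenarios <- function(lst) {
    do.call(rbind, lapply(names(lst), function(sc)
      cbind(scenario = sc, as.data.frame(lst[[sc]]))))
  }
  if (!is.null(result$population)) emit(result$population, "population.csv")
  if (length(result$consumption))
    emit(bind_scenarios(result$consumption), "table_consumption.csv")
  if (length(result$bmi_change))
    emit(bind_scenarios(result$bmi_change), "table_bmi_change.csv")
  if (length(result$prevalence))
    emit(bind_scenarios(result$prevalence), "table_prevalence.csv")
  if (length(result$diabetes$scenarios)) {
    proj <- bind_scenarios(c(list(no_tax = result$diabetes$baseline),
                             lapply(result$diabetes$scenarios, `[[`,
                                    "projection")))
    emit(proj, "table_diabetes_projection.csv")
    av <- do.call(rbind, lapply(names(result$diabetes$scenarios), function(sc) {
      a <- result$diabetes$scenarios[[sc]]$averted
      data.frame(scenario = sc, year = as.integer(names(a)),
                 cumulative_averted = as.numeric(a))
    }))
    emit(av, "table_averted_cases.csv")
  }
  if (length(result$crm)) emit(bind_scenarios(result$crm), "crm_sensitivity.csv")

  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(result$manifest, mpath, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, mpath)

  spath <- file.path(outdir, "summary.txt")
  con <- file(spath, "w")
  on.exit(close(con))
  writeLines(c("ssbtax pipeline run",
               sprintf("population: %d individuals",
                       result$manifest$population_n %||% 0L),
               sprintf("scenarios: %s",
                       paste(result$manifest$scenarios, collapse = ", ")),
               sprintf("tables written: %d", length(paths))), con)
  paths <- c(paths, spath)
  invisible(paths)
}
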