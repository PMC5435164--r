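# Tax scenarios and their application to individual consumption.
#
# The four scenarios encode the SES-stratified percent reductions in taxed
# SSB purchases attributed to the 2014 one-peso-per-litre tax (average
# yearly effect and peak monthly effect), plus a hypothetical 20% tax
# assumed to double both sets of effects.

.tax_registry <- list(
  avg10 = list(name = "avg10",
               label = "10% tax, average 2014 effect",
               reduction_by_ses = c(low = 0.091, medium = 0.056, high = 0.055),
               overall_reduction = 0.061),
  peak10 = list(name = "peak10",
                label = "10% tax, peak monthly 2014 effect",
                reduction_by_ses = c(low = 0.174, medium = 0.131, high = 0.068),
                overall_reduction = 0.119),
  avg20 = list(name = "avg20",
               label = "20% tax, doubled average effect",
               reduction_by_ses = c(low = 0.182, medium = 0.112, high = 0.110),
               overall_reduction = 0.122),
  peak20 = list(name = "peak20",
                label = "20% tax, doubled peak monthly effect",
                reduction_by_ses = c(low = 0.348, medium = 0.262, high = 0.136),
                overall_reduction = 0.238))

# the 20% scenarios are stored literally; enforce the doubling relation
local({
  stopifnot(
    all(.tax_registry$avg20$reduction_by_ses ==
          pmin(2 * .tax_registry$avg10$reduction_by_ses, 1 - 1e-12)),
    all(.tax_registry$peak20$reduction_by_ses ==
          pmin(2 * .tax_registry$peak10$reduction_by_ses, 1 - 1e-12)),
    vapply(.tax_registry, function(s)
      all(s$reduction_by_ses >= 0 & s$reduction_by_ses < 1), logical(1)))
})

#' Tax scenario registry
#'
#' `tax_scenario(name)` returns one of the four immutable scenarios
#' (`avg10`, `peak10`, `avg20`, `peak20`), each mapping SES tertile to the
#' fractional reduction in taxed-SSB purchases; `tax_scenarios()` lists the
#' valid names.
#'
#' @param name scenario name.
#' @return a list of class `tax_scenario` with elements `name`, `label`,
#'   `reduction_by_ses` (named fractions) and `overall_reduction`.
#' @examples
#' tax_scenario("avg10")$reduction_by_ses
#' @export
tax_scenario <- function(name) {
  if (length(name) != 1 || !name %in% names(.tax_registry))
    stop("unknown tax scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(.tax_registry), collapse = ", "),
         call. = FALSE)
  structure(.tax_registry[[name]], class = "tax_scenario")
}

#' @rdname tax_scenario
#' @export
tax_scenarios <- function() names(.tax_registry)

#' @export
print.tax_scenario <- function(x, ...) {
  cat(sprintf("<tax_scenario> %s (%s)\n", x$name, x$label))
  cat(sprintf("  SSB purchase reduction: low %.1f%%, medium %.1f%%, high %.1f%%\n",
              100 * x$reduction_by_ses["low"], 100 * x$reduction_by_ses["medium"],
              100 * x$reduction_by_ses["high"]))
  invisible(x)
}

#' Apply a tax scenario to individual consumption
#'
#' The percent purchase reduction of the individual's SES tertile is
#' applied to baseline consumption as a permanent step change:
#' `delta_ml = -reduction[ses] * ssb_ml`. Volume change is converted to a
#' caloric change with a constant caloric density and to a servings change
#' with a fixed serving size. A substitution fraction (default 0, the base
#' case: substitution toward non-caloric beverages) scales the caloric
#' change only.
#'
#' @param pop an `ssb_population`.
#' @param scenario a `tax_scenario` or scenario name.
#' @param caloric_density kcal per ml of taxed SSB; the default 0.388 is
#'   the baseline population ratio 125.50 kcal / 323.49 ml.
#' @param serving_size_ml ml per serving (default one 355-ml can).
#' @param substitution_fraction fraction of removed SSB calories replaced
#'   by other caloric intake.
#' @return data.frame of class `consumption_change` with columns
#'   `id, delta_ml, delta_kcal, delta_servings` (all <= 0).
#' @export
apply_tax <- function(pop, scenario, caloric_density = 0.388,
                      serving_size_ml = 355, substitution_fraction = 0) {
  if (is.character(scenario)) scenario <- tax_scenario(scenario)
  stopifnot(inherits(scenario, "tax_scenario"), caloric_density > 0,
            serving_size_ml > 0,
            substitution_fraction >= 0, substitution_fraction < 1)
  if (!all(pop$ses %in% .SES_LEVELS))
    stop("population contains invalid SES levels", call. = FALSE)
  red <- scenario$reduction_by_ses[pop$ses]
  delta_ml <- -red * pop$ssb_ml
  out <- data.frame(
    id = pop$id,
    delta_ml = unname(delta_ml),
    delta_kcal = unname(delta_ml * caloric_density * (1 - substitution_fraction)),
    delta_servings = unname(delta_ml / serving_size_ml))
  structure(out, class = c("consumption_change", "data.frame"),
            scenario = scenario$name, caloric_density = caloric_density,
            serving_size_ml = serving_size_ml)
}

#' Weighted consumption summary, overall and by stratum
#'
#' Survey-weighted mean (SD) of baseline taxed-SSB volume and energy and of
#' the tax-induced changes, overall and within sex, age-group, SES and
#' consumption-quartile strata.
#'
#' @param pop an `ssb_population`.
#' @param changes the matching [apply_tax()] result.
#' @param strata subset of `c("overall","sex","age_group","ses","quartile")`.
#' @return data.frame with one row per stratum level and columns for each
#'   weighted mean and SD.
#' @export
summarize_consumption <- function(pop, changes,
                                  strata = c("overall", "sex", "age_group",
                                             "ses", "quartile")) {
  if (!identical(pop$id, changes$id))
    stop("`changes` is not aligned with `pop` by id", call. = FALSE)
  strata <- match.arg(strata, several.ok = TRUE)
  cd <- attr(changes, "caloric_density")
  if (is.null(cd)) cd <- 0.388
  vars <- list(baseline_ml = pop$ssb_ml, baseline_kcal = pop$ssb_ml * cd,
               delta_ml = changes$delta_ml, delta_kcal = changes$delta_kcal)
  labels <- stratum_labels(pop, strata)
  do.call(rbind, lapply(names(labels), function(nm) {
    idx <- labels[[nm]]
    row <- data.frame(stratum = nm, n = sum(idx))
    for (v in names(vars)) {
      row[[paste0(v, "_mean")]] <- if (any(idx))
        weighted_mean(vars[[v]][idx], pop$svy_weight[idx]) else NA_real_
      row[[paste0(v, "_sd")]] <- if (any(idx))
        weighted_sd(vars[[v]][idx], pop$svy_weight[idx]) else NA_real_
    }
    row
  }))
}

# named list of logical row-selectors for the requested strata
stratum_labels <- function(pop, strata) {
  out <- list()
  if ("overall" %in% strata) out[["overall"]] <- rep(TRUE, nrow(pop))
  if ("sex" %in% strata)
    for (s in .SEXES) out[[paste0("sex:", s)]] <- pop$sex == s
  if ("age_group" %in% strata) {
    ag <- age_group(pop$age)
    for (g in .AGE_GROUPS) out[[paste0("age:", g)]] <- ag == g
  }
  if ("ses" %in% strata)
    for (s in .SES_LEVELS) out[[paste0("ses:", s)]] <- pop$ses == s
  if ("quartile" %in% strata && nrow(pop)) {
    q <- assign_quartiles(pop)
    for (lv in levels(q)) out[[paste0("ssb:", lv)]] <- q == lv
  }
  out
}
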