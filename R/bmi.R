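# WHO BMI classification and survey-weighted outcome tables.

.BMI_CATEGORIES <- c("normal", "overweight", "obese")

#' WHO BMI category
#'
#' Lower-inclusive intervals: normal `[0, 25)`, overweight `[25, 30)`,
#' obese `[30, Inf)`, so 25.0 classifies as overweight and 30.0 as obese.
#'
#' @param bmi positive finite BMI values, kg/m2.
#' @return factor with levels `normal, overweight, obese`.
#' @examples
#' classify_bmi(c(24.99, 25, 30))
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("BMI must be positive and finite", call. = FALSE)
  cut(bmi, c(0, 25, 30, Inf), right = FALSE, labels = .BMI_CATEGORIES)
}

#' Weighted BMI-category prevalence, baseline vs scenario
#'
#' Survey-weighted prevalence of normal weight, overweight and obesity at
#' baseline and under a scenario's BMI values, with the relative percent
#' change `100 * (scenario - baseline) / baseline` per cell. Strata with no
#' members are reported as `NA`, not zero.
#'
#' @param pop an `ssb_population`.
#' @param bmis_at_t scenario BMI values aligned with `pop` (e.g. one column
#'   of a [simulate_cohort()] panel).
#' @param strata subset of `c("overall","sex","age_group","ses","quartile")`.
#' @return data.frame with columns
#'   `stratum, category, baseline_pct, scenario_pct, pct_change`.
#' @export
prevalence_by_category <- function(pop, bmis_at_t,
                                   strata = c("overall", "quartile")) {
  if (length(bmis_at_t) != nrow(pop))
    stop("`bmis_at_t` must align with `pop`", call. = FALSE)
  strata <- match.arg(strata, c("overall", "sex", "age_group", "ses",
                                "quartile"), several.ok = TRUE)
  base_cat <- classify_bmi(pop$weight_kg / pop$height_m^2)
  scen_cat <- classify_bmi(bmis_at_t)
  labels <- stratum_labels(pop, strata)
  do.call(rbind, lapply(names(labels), function(nm) {
    idx <- labels[[nm]]
    if (!any(idx))
      return(data.frame(stratum = nm, category = .BMI_CATEGORIES,
                        baseline_pct = NA_real_, scenario_pct = NA_real_,
                        pct_change = NA_real_))
    w <- pop$svy_weight[idx]
    pct <- function(cat) vapply(.BMI_CATEGORIES, function(k)
      100 * sum(w[cat[idx] == k]) / sum(w), numeric(1))
    b <- pct(base_cat)
    s <- pct(scen_cat)
    data.frame(stratum = nm, category = .BMI_CATEGORIES,
               baseline_pct = unname(b), scenario_pct = unname(s),
               pct_change = unname(ifelse(b > 0, 100 * (s - b) / b, NA_real_)))
  }))
}

#' Stratified mean BMI and mean BMI reduction
#'
#' Survey-weighted mean baseline BMI and mean BMI decrease at horizon `t`
#' years, per stratum, with the decrease also expressed as a percent of
#' baseline (the layout of the stratified BMI-change tables).
#'
#' @param pop an `ssb_population`.
#' @param panel a `bmi_panel` from [simulate_cohort()] covering year `t`.
#' @param t report horizon in years (must be one of the panel's columns).
#' @param strata subset of `c("overall","sex","age_group","ses","quartile")`.
#' @return data.frame with columns `stratum, n, baseline_bmi,
#'   bmi_reduction, pct_change` (`bmi_reduction` positive for decreases).
#' @export
stratified_bmi_change <- function(pop, panel, t = 10,
                                  strata = c("overall", "sex", "age_group",
                                             "ses", "quartile")) {
  strata <- match.arg(strata, several.ok = TRUE)
  col <- match(paste0("y", t), colnames(panel))
  if (is.na(col))
    stop("panel does not contain year ", t, call. = FALSE)
  if (nrow(panel) != nrow(pop) || !identical(attr(panel, "id"), pop$id))
    stop("panel is not aligned with `pop` (missing trajectories?)",
         call. = FALSE)
  base <- attr(panel, "baseline_bmi")
  red <- base - panel[, col]
  labels <- stratum_labels(pop, strata)
  do.call(rbind, lapply(names(labels), function(nm) {
    idx <- labels[[nm]]
    if (!any(idx))
      return(data.frame(stratum = nm, n = 0, baseline_bmi = NA_real_,
                        bmi_reduction = NA_real_, pct_change = NA_real_))
    w <- pop$svy_weight[idx]
    b <- weighted_mean(base[idx], w)
    r <- weighted_mean(red[idx], w)
    data.frame(stratum = nm, n = sum(idx), baseline_bmi = b,
               bmi_reduction = r, pct_change = 100 * r / b)
  }))
}
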