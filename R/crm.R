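# Comparative risk assessment (CRA) sensitivity analysis: direct
# meta-analytic BMI change per daily SSB serving, bypassing the dynamic
# energy-balance model. Used to bracket the 10-year ODE result.

#' Meta-analytic BMI-per-serving coefficients
#'
#' The coefficient set used in the sensitivity analysis: pooled
#' experimental (0.85) and observational (0.22) kg/m2 per serving/day,
#' plus the lowest (0.11), middle (1.09) and highest (2.12) single-study
#' observational estimates.
#'
#' @return data.frame with columns `source, beta, class`.
#' @export
crm_coefficients <- function() {
  data.frame(
    source = c("pooled_experimental", "pooled_observational",
               "mozaffarian", "chen", "barone"),
    beta = c(0.85, 0.22, 0.11, 1.09, 2.12),
    class = c("experimental", "observational", "observational",
              "observational", "observational"))
}

#' CRA BMI change for a servings change
#'
#' Linear, time-independent exposure-response:
#' `delta_bmi = beta * delta_servings` (kg/m2).
#'
#' @param delta_servings servings/person/day change (<= 0 for reductions).
#' @param beta coefficient, kg/m2 per serving/day (> 0).
#' @return BMI change, kg/m2 (same sign as `delta_servings`).
#' @export
crm_bmi_change <- function(delta_servings, beta) {
  stopifnot(all(beta > 0))
  beta * delta_servings
}

#' CRA sensitivity table
#'
#' Survey-weighted mean BMI change under each coefficient, applied to the
#' individual servings changes, optionally alongside the dynamic-model
#' population mean for comparison.
#'
#' @param pop an `ssb_population`.
#' @param changes the matching [apply_tax()] result.
#' @param coefficients a coefficient set as from [crm_coefficients()].
#' @param ode_mean_change optional weighted mean 10-year BMI change from
#'   the dynamic model (kg/m2, negative for reductions).
#' @return data.frame `source, beta, class, mean_delta_bmi` (plus an
#'   `ode_model` row when `ode_mean_change` is given), sorted by `beta`.
#' @export
crm_sensitivity_table <- function(pop, changes,
                                  coefficients = crm_coefficients(),
                                  ode_mean_change = NULL) {
  if (!nrow(coefficients)) stop("coefficient set is empty", call. = FALSE)
  if (!identical(pop$id, changes$id))
    stop("`changes` is not aligned with `pop` by id", call. = FALSE)
  out <- coefficients
  out$mean_delta_bmi <- vapply(coefficients$beta, function(b)
    weighted_mean(crm_bmi_change(changes$delta_servings, b), pop$svy_weight),
    numeric(1))
  out <- out[order(out$beta), ]
  if (!is.null(ode_mean_change))
    out <- rbind(out, data.frame(source = "ode_model", beta = NA_real_,
                                 class = "dynamic",
                                 mean_delta_bmi = ode_mean_change))
  rownames(out) <- NULL
  out
}
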