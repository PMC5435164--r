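# Multi-cohort Markov state-transition projection of diagnosed diabetes.
#
# Cohort counts are carried on an age (0-100, open top bin) x sex x SES
# grid with states {alive without diagnosed diabetes, alive with diagnosed
# diabetes, dead}. Each annual cycle: susceptibles acquire diagnosed
# diabetes with probability 1 - exp(-m * lambda(age)) where m is the
# SES-specific counterfactual multiplier (1 at baseline); deaths follow
# 1 - exp(-hr * mu(age, sex)) with an optional excess-mortality hazard
# ratio for diabetics; everyone ages one year and projected births enter
# at age 0.

#' Relative-risk link between SSB change and diabetes incidence
#'
#' Encodes the meta-analytic relative risk per daily SSB serving (default
#' 1.26; 95% CI 1.12-1.41 available for sensitivity) together with the
#' SES-group mean per-capita servings change. The counterfactual incidence
#' multiplier is `rr^delta_servings`, applied on the hazard scale.
#'
#' @param delta_servings_by_ses named (low/medium/high) mean per-capita
#'   servings/day change, <= 0 under the tax.
#' @param rr_per_serving relative risk per serving/day.
#' @param serving_size_ml serving size used to derive the servings change.
#' @return list of class `risk_link`.
#' @export
risk_link <- function(delta_servings_by_ses, rr_per_serving = 1.26,
                      serving_size_ml = 355) {
  stopifnot(rr_per_serving > 0, serving_size_ml > 0)
  if (!all(.SES_LEVELS %in% names(delta_servings_by_ses)))
    stop("`delta_servings_by_ses` must be named low/medium/high", call. = FALSE)
  structure(list(rr_per_serving = rr_per_serving,
                 serving_size_ml = serving_size_ml,
                 delta_servings_by_ses = delta_servings_by_ses[.SES_LEVELS]),
            class = "risk_link")
}

#' @rdname risk_link
#' @param link a `risk_link`.
#' @param ses SES level(s); defaults to all three.
#' @return `incidence_multiplier`: named multipliers
#'   `rr^delta_servings` (1 when the change is 0).
#' @export
incidence_multiplier <- function(link, ses = .SES_LEVELS) {
  m <- link$rr_per_serving ^ link$delta_servings_by_ses[ses]
  stopifnot(all(m > 0), all(is.finite(m)))
  m
}

#' SES-group mean servings change from individual consumption changes
#'
#' Survey-weighted per-capita mean of `delta_servings` within each SES
#' tertile; the population-level exposure change the Markov model uses.
#'
#' @param pop an `ssb_population`.
#' @param changes the matching [apply_tax()] result.
#' @return named numeric (low/medium/high), servings/person/day.
#' @export
ses_mean_servings_change <- function(pop, changes) {
  if (!identical(pop$id, changes$id))
    stop("`changes` is not aligned with `pop` by id", call. = FALSE)
  out <- vapply(.SES_LEVELS, function(s) {
    idx <- pop$ses == s
    weighted_mean(changes$delta_servings[idx], pop$svy_weight[idx])
  }, numeric(1))
  out
}

#' Synthetic national population structure
#'
#' Age pyramid with exponentially declining counts, split by sex and SES
#' shares; the starting occupancy of the multi-cohort grid.
#'
#' @param total total population size, persons.
#' @param decay exponential decline of counts with age, 1/years.
#' @param ages integer ages (top bin open-ended).
#' @param sex_split,ses_probs named shares (defaults as in
#'   [population_config()]).
#' @return array `[age, sex, ses]` of persons.
#' @export
population_structure <- function(total = 121e6, decay = 0.015, ages = 0:100,
                                 sex_split = c(male = 0.4887,
                                               female = 0.5113),
                                 ses_probs = c(low = 0.3365, medium = 0.3291,
                                               high = 0.3343) / 0.9999) {
  shape <- exp(-decay * ages)
  counts <- total * shape / sum(shape)
  arr <- outer(counts, sex_split) %o% ses_probs
  dimnames(arr) <- list(age = ages, sex = names(sex_split),
                        ses = names(ses_probs))
  arr
}

#' Project diagnosed diabetes with a multi-cohort Markov model
#'
#' Advances the population grid annually from `start_year` to `end_year`.
#' Baseline prevalence at `start_year` is generated from a single-cohort
#' recursion run at `init_incidence_fraction` of the scenario incidence
#' (past incidence below projected incidence reproduces the rising secular
#' trend). When a `risk_link` is supplied its SES-specific multipliers
#' scale the incidence hazard from the first projected year onward (the
#' consumption reduction is a step at the start of year one).
#'
#' @param pop_structure starting `[age, sex, ses]` array from
#'   [population_structure()].
#' @param incidence an incidence [rate_schedule][incidence_schedule()].
#' @param mortality a mortality [rate_schedule][mortality_schedule()].
#' @param births a [birth_projection()] covering the horizon.
#' @param link optional [risk_link()]; `NULL` projects the no-tax baseline.
#' @param start_year,end_year projection horizon (annual cycles).
#' @param excess_mortality_hr hazard ratio applied to mortality of
#'   diagnosed diabetics (default 1: no excess).
#' @param init_incidence_fraction fraction of scenario incidence used to
#'   seed prevalence at `start_year`.
#' @return data.frame of class `diabetes_projection` with columns
#'   `year, prevalence_pct` (adults 20+), `incident_cases`,
#'   `alive, dead` (grid totals); attribute `"conservation_error"` holds
#'   the maximum absolute person-count accounting error across years.
#' @export
project_diabetes <- function(pop_structure = population_structure(),
                             incidence = incidence_schedule(),
                             mortality = mortality_schedule(),
                             births = birth_projection(),
                             link = NULL,
                             start_year = 2015, end_year = 2050,
                             excess_mortality_hr = 1,
                             init_incidence_fraction = 0.5) {
  ages <- as.integer(dimnames(pop_structure)$age)
  nage <- length(ages)
  sexes <- dimnames(pop_structure)$sex
  sess <- dimnames(pop_structure)$ses
  lam <- schedule_rates(incidence, ages)
  mu <- vapply(sexes, function(s) schedule_rates(mortality, ages, s),
               numeric(nage))
  years <- start_year:end_year
  if (!all(years[-length(years)] %in% births$year))
    stop("birth projection does not cover the horizon", call. = FALSE)
  mult <- if (is.null(link)) stats::setNames(rep(1, length(sess)), sess)
          else incidence_multiplier(link)[sess]
  stopifnot(excess_mortality_hr > 0)

  # seed start-year prevalence by age from a quieter historical regime
  lam0 <- init_incidence_fraction * lam
  pr <- numeric(nage)
  for (i in seq_along(ages)[-1]) {
    if (ages[i] <= 20) next
    pr[i] <- pr[i - 1] + (1 - pr[i - 1]) * (1 - exp(-lam0[i - 1]))
  }
  S <- sweep(pop_structure, 1, 1 - pr, "*")
  D <- sweep(pop_structure, 1, pr, "*")
  dead <- array(0, dim(pop_structure), dimnames = dimnames(pop_structure))

  launched <- sum(pop_structure)
  births_in <- 0
  res <- data.frame(year = years, prevalence_pct = NA_real_,
                    incident_cases = NA_real_, alive = NA_real_,
                    dead = NA_real_)
  cons_err <- 0
  adult <- ages >= 20
  record <- function(k, new_cases) {
    res$prevalence_pct[k] <<- 100 * sum(D[adult, , ]) /
      sum(S[adult, , ] + D[adult, , ])
    res$incident_cases[k] <<- new_cases
    res$alive[k] <<- sum(S + D)
    res$dead[k] <<- sum(dead)
    cons_err <<- max(cons_err,
                     abs(sum(S + D + dead) - launched - births_in))
  }
  record(1, 0)
  for (k in seq_along(years)[-1]) {
    pinc <- 1 - exp(-outer(lam, mult))        # [age, ses]
    new <- array(0, dim(S))
    for (j in seq_along(sess)) new[, , j] <- S[, , j] * pinc[, j]
    S <- S - new
    D <- D + new
    pdie_S <- 1 - exp(-mu)                    # [age, sex]
    pdie_D <- 1 - exp(-excess_mortality_hr * mu)
    dS <- sweep(S, c(1, 2), pdie_S, "*")
    dD <- sweep(D, c(1, 2), pdie_D, "*")
    S <- S - dS
    D <- D - dD
    dead <- dead + dS + dD
    shift <- function(a) {
      top <- a[nage, , ] + a[nage - 1, , ]
      a[2:nage, , ] <- a[1:(nage - 1), , ]
      a[nage, , ] <- top
      a[1, , ] <- 0
      a
    }
    S <- shift(S); D <- shift(D); dead <- shift(dead)
    yb <- years[k - 1]
    for (s in sexes) {
      b <- births$births[births$year == yb & births$sex == s]
      if (length(b)) {
        ses_share <- prop.table(apply(pop_structure, 3, sum))
        S[1, s, ] <- b * ses_share
        births_in <- births_in + b
      }
    }
    if (any(S < -1e-6) || any(D < -1e-6))
      stop("internal invariant failure: negative cohort counts", call. = FALSE)
    record(k, sum(new))
  }
  structure(res, class = c("diabetes_projection", "data.frame"),
            conservation_error = cons_err,
            scenario = attr(incidence, "scenario"),
            multipliers = mult, link = link)
}

#' @export
print.diabetes_projection <- function(x, ...) {
  cat(sprintf("<diabetes_projection> %d-%d (%s incidence)\n",
              min(x$year), max(x$year),
              attr(x, "scenario") %||% "custom"))
  arm <- if (is.null(attr(x, "link"))) "baseline (no tax)" else
    sprintf("counterfactual (multipliers %s)",
            paste(sprintf("%.3f", attr(x, "multipliers")), collapse = "/"))
  cat("  arm:", arm, "\n")
  cat(sprintf("  adult prevalence: %.1f%% (%d) -> %.1f%% (%d)\n",
              x$prevalence_pct[1], x$year[1],
              x$prevalence_pct[nrow(x)], x$year[nrow(x)]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cumulative averted diagnosed-diabetes cases
#'
#' Cumulative difference in incident cases (baseline minus counterfactual)
#' from the start of the projection through `by_year`.
#'
#' @param baseline,counterfactual two [project_diabetes()] results with
#'   identical horizons and demographic inputs.
#' @param by_year report year(s); defaults to the final year.
#' @return named numeric, persons.
#' @export
averted_cases <- function(baseline, counterfactual, by_year = NULL) {
  if (!identical(baseline$year, counterfactual$year))
    stop("projections have mismatched horizons", call. = FALSE)
  if (is.null(by_year)) by_year <- max(baseline$year)
  cum <- cumsum(baseline$incident_cases - counterfactual$incident_cases)
  idx <- match(by_year, baseline$year)
  if (anyNA(idx)) stop("`by_year` outside the projection horizon", call. = FALSE)
  stats::setNames(cum[idx], by_year)
}
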