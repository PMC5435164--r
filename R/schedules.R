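# Demographic rate schedules for the diabetes projection: age-specific
# diagnosed-diabetes incidence (three secular scenarios), sex-specific
# Gompertz all-cause mortality, and projected annual births.

.INCIDENCE_SCENARIOS <- c("optimistic", "intermediate", "pessimistic")

new_rate_schedule <- function(df, kind) {
  stopifnot(all(df$rate >= 0), all(is.finite(df$rate)))
  for (s in split(df, df$sex))
    if (is.unsorted(s$age, strictly = TRUE))
      stop("age grid must be strictly increasing", call. = FALSE)
  structure(df, class = c("rate_schedule", "data.frame"), kind = kind)
}

#' Age-specific diagnosed-diabetes incidence schedule
#'
#' Annual incidence hazard of diagnosed diabetes as a logistic function of
#' age: zero below age 20, rising to a plateau of
#' `multiplier * rate_max / (1 + exp(-slope * (age - midpoint)))`. The three
#' named scenarios encode secular assumptions about future incidence
#' (optimistic < intermediate < pessimistic at every age).
#'
#' @param scenario one of `"optimistic"`, `"intermediate"`, `"pessimistic"`.
#' @param rate_max plateau hazard of the intermediate scenario, events per
#'   person-year.
#' @param midpoint age at half the plateau, years.
#' @param slope logistic steepness, 1/years.
#' @param multipliers named scenario-level multipliers, must be increasing
#'   from optimistic to pessimistic.
#' @param ages integer age grid.
#' @return a `rate_schedule` data.frame with columns `kind,sex,age,rate`.
#' @export
incidence_schedule <- function(scenario = c("intermediate", "optimistic",
                                            "pessimistic"),
                               rate_max = 0.020, midpoint = 50, slope = 0.08,
                               multipliers = c(optimistic = 0.75,
                                               intermediate = 1,
                                               pessimistic = 1.3),
                               ages = 0:100) {
  scenario <- match.arg(scenario)
  if (rate_max <= 0 || slope < 0)
    stop("`rate_max` must be > 0 and `slope` >= 0", call. = FALSE)
  if (is.unsorted(multipliers[.INCIDENCE_SCENARIOS], strictly = TRUE))
    stop("multipliers must satisfy optimistic < intermediate < pessimistic",
         call. = FALSE)
  m <- multipliers[[scenario]]
  rate <- ifelse(ages < 20, 0,
                 m * rate_max / (1 + exp(-slope * (ages - midpoint))))
  out <- new_rate_schedule(
    data.frame(kind = "incidence", sex = "both", age = ages, rate = rate),
    "incidence")
  attr(out, "scenario") <- scenario
  out
}

#' Sex-specific Gompertz mortality schedule
#'
#' All-cause mortality hazard `level * exp(slope * age)` per sex, capped so
#' the annual hazard stays below `cap` (the discretised one-year death
#' probability `1 - exp(-rate)` is then always inside `[0, 1)`).
#'
#' @param level_male,level_female Gompertz level, events per person-year at
#'   age 0.
#' @param slope Gompertz log-slope, 1/years; 0 gives constant mortality.
#' @param cap upper bound on the annual hazard.
#' @param ages integer age grid.
#' @return a `rate_schedule` data.frame with male and female rows.
#' @export
mortality_schedule <- function(level_male = 7e-5, level_female = 5e-5,
                               slope = 0.085, cap = 0.7, ages = 0:100) {
  if (level_male < 0 || level_female < 0 || slope < 0)
    stop("Gompertz parameters must be non-negative", call. = FALSE)
  df <- do.call(rbind, lapply(.SEXES, function(s) {
    lev <- if (s == "male") level_male else level_female
    data.frame(kind = "mortality", sex = s, age = ages,
               rate = pmin(lev * exp(slope * ages), cap))
  }))
  new_rate_schedule(df, "mortality")
}

#' Projected annual births by sex
#'
#' @param years contiguous calendar years of the projection horizon.
#' @param births_per_year total births per year (constant, or a vector the
#'   length of `years`).
#' @param male_fraction fraction of births that are male.
#' @return data.frame of class `birth_projection` with columns
#'   `year,sex,births`.
#' @export
birth_projection <- function(years = 2015:2050, births_per_year = 2.2e6,
                             male_fraction = 0.512) {
  if (any(births_per_year < 0)) stop("births must be >= 0", call. = FALSE)
  if (male_fraction < 0 || male_fraction > 1)
    stop("`male_fraction` must be in [0, 1]", call. = FALSE)
  if (any(diff(years) != 1))
    stop("`years` must be contiguous", call. = FALSE)
  b <- rep_len(births_per_year, length(years))
  out <- rbind(
    data.frame(year = years, sex = "male", births = b * male_fraction),
    data.frame(year = years, sex = "female", births = b * (1 - male_fraction)))
  structure(out[order(out$year), ], class = c("birth_projection", "data.frame"))
}

# rate at given ages for one sex, from a rate_schedule
schedule_rates <- function(sched, ages, sex = "both") {
  sub <- sched[sched$sex %in% c(sex, "both"), ]
  idx <- match(ages, sub$age)
  if (anyNA(idx))
    stop("rate schedule does not cover all requested ages", call. = FALSE)
  sub$rate[idx]
}
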