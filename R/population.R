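# Synthetic survey-like adult population: demographics, anthropometry and
# taxed-SSB consumption with the marginal structure the downstream models
# assume. Consumption is zero-inflated log-normal; BMI is drawn per
# sex x age-group stratum; SES carries a multiplicative consumption shift.

.SEXES <- c("male", "female")
.SES_LEVELS <- c("low", "medium", "high")
.AGE_GROUPS <- c("20-39", "40-59", "60+")
.POP_COLUMNS <- c("id", "sex", "age", "height_m", "weight_kg", "ses",
                  "ssb_ml", "svy_weight")

#' Configuration of the synthetic population generator
#'
#' Returns a validated configuration list. The defaults encode the marginal
#' structure of the adult Mexican population the pipeline emulates: the
#' 44.87/55.13 male/female split, 47.21/34.20/18.59 age-group split and
#' 33.65/32.91/33.43 SES tertile shares; sex-and-age-specific mean BMI
#' giving an overall weighted mean near 28.4 kg/m2; and a zero-inflated
#' log-normal taxed-SSB distribution calibrated numerically so that the
#' population mean is close to 323.49 ml/day with quartile cut points near
#' 33.94/129.64/402.86 ml/day. SES tertiles carry a multiplicative
#' consumption gradient (low > medium > high) whose share-weighted average
#' is ~1, preserving the overall mean.
#'
#' @param n number of individuals to generate.
#' @param seed integer seed; all generator randomness flows from it.
#' @param sex_split named proportions for male/female.
#' @param age_group_probs named proportions for the 20-39/40-59/60+ bands.
#' @param ses_probs named proportions for low/medium/high SES.
#' @param bmi_means_by_stratum 2 x 3 matrix (sex by age group) of mean BMI,
#'   kg/m2.
#' @param bmi_sd common BMI standard deviation, kg/m2.
#' @param bmi_range BMI values are redrawn into this range so that implied
#'   weights stay physiologic.
#' @param height_params_by_sex list with `male`/`female` elements, each
#'   `c(mean, sd)` in metres.
#' @param ssb_zero_prob probability of zero taxed-SSB consumption.
#' @param ssb_lognormal_mu,ssb_lognormal_sigma log-scale parameters of the
#'   positive consumption component (log ml/day).
#' @param ses_consumption_shift named multiplicative factors per SES level.
#' @param age_consumption_shift named multiplicative factors per age group
#'   (younger adults consume more); the group-share weighted average of
#'   each shift vector is ~1 so the overall mean is preserved.
#' @param svy_weight_sdlog log-scale SD of the expansion weights
#'   (log-normal with mean 1); 0 gives unit weights.
#' @param age_max upper truncation of the open 60+ band, years.
#' @return a list of class `population_config`.
#' @seealso [generate_population()]
#' @export
population_config <- function(n = 10000,
                              seed = 20140101,
                              sex_split = c(male = 0.4487, female = 0.5513),
                              age_group_probs = c("20-39" = 0.4721,
                                                  "40-59" = 0.3420,
                                                  "60+" = 0.1859),
                              ses_probs = c(low = 0.3365, medium = 0.3291,
                                            high = 0.3343) / 0.9999,
                              bmi_means_by_stratum = rbind(
                                male   = c(27.40, 28.16, 26.86),
                                female = c(28.14, 30.77, 28.48)),
                              bmi_sd = 4.5,
                              bmi_range = c(16, 55),
                              height_params_by_sex = list(
                                male = c(mean = 1.65, sd = 0.07),
                                female = c(mean = 1.53, sd = 0.065)),
                              ssb_zero_prob = 0.2035,
                              ssb_lognormal_mu = 5.3305,
                              ssb_lognormal_sigma = 1.1557,
                              ses_consumption_shift = c(low = 1.08,
                                                        medium = 1.00,
                                                        high = 0.92),
                              age_consumption_shift = c("20-39" = 1.25,
                                                        "40-59" = 0.8725,
                                                        "60+" = 0.60),
                              svy_weight_sdlog = 0.3,
                              age_max = 90) {
  cfg <- list(n = n, seed = seed, sex_split = sex_split,
              age_group_probs = age_group_probs, ses_probs = ses_probs,
              bmi_means_by_stratum = bmi_means_by_stratum, bmi_sd = bmi_sd,
              bmi_range = bmi_range,
              height_params_by_sex = height_params_by_sex,
              ssb_zero_prob = ssb_zero_prob,
              ssb_lognormal_mu = ssb_lognormal_mu,
              ssb_lognormal_sigma = ssb_lognormal_sigma,
              ses_consumption_shift = ses_consumption_shift,
              age_consumption_shift = age_consumption_shift,
              svy_weight_sdlog = svy_weight_sdlog, age_max = age_max)
  validate_population_config(cfg)
  structure(cfg, class = "population_config")
}

validate_population_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n < 0 ||
      cfg$n != round(cfg$n))
    stop("`n` must be a single non-negative integer", call. = FALSE)
  for (nm in c("sex_split", "age_group_probs", "ses_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(sprintf("`%s` must be non-negative and sum to 1 (got sum %.12f)",
                   nm, sum(p)), call. = FALSE)
  }
  sds <- c(cfg$bmi_sd, cfg$ssb_lognormal_sigma,
           cfg$height_params_by_sex$male["sd"],
           cfg$height_params_by_sex$female["sd"])
  if (any(sds <= 0)) stop("all standard deviations must be > 0", call. = FALSE)
  if (cfg$ssb_zero_prob < 0 || cfg$ssb_zero_prob >= 1)
    stop("`ssb_zero_prob` must lie in [0, 1)", call. = FALSE)
  if (any(cfg$ses_consumption_shift <= 0) || any(cfg$age_consumption_shift <= 0))
    stop("consumption shift factors must be positive", call. = FALSE)
  invisible(cfg)
}

# evaluate fn with a private RNG stream; global .Random.seed is untouched
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic adult population
#'
#' Draws `cfg$n` individuals with sex, age, height, weight, SES tertile,
#' taxed-SSB consumption (ml/person/day) and an expansion weight.
#' Deterministic given `cfg$seed`. BMI is drawn from a sex x age-group
#' normal (redrawn into `bmi_range`), weight is `BMI * height^2`, and
#' consumption is zero with probability `ssb_zero_prob` and otherwise
#' log-normal, scaled by the SES consumption shift.
#'
#' @param cfg a [population_config()].
#' @return data.frame of class `ssb_population` with columns
#'   `id, sex, age, height_m, weight_kg, ses, ssb_ml, svy_weight`.
#' @examples
#' pop <- generate_population(population_config(n = 500))
#' summary(pop)
#' @export
generate_population <- function(cfg = population_config()) {
  if (!inherits(cfg, "population_config")) cfg <- do.call(population_config, cfg)
  validate_population_config(cfg)
  n <- cfg$n
  if (n == 0) {
    out <- data.frame(id = integer(0), sex = character(0), age = integer(0),
                      height_m = numeric(0), weight_kg = numeric(0),
                      ses = character(0), ssb_ml = numeric(0),
                      svy_weight = numeric(0))
    return(structure(out, class = c("ssb_population", "data.frame"),
                     config = cfg))
  }
  with_local_seed(cfg$seed, function() {
    sex <- sample(.SEXES, n, replace = TRUE, prob = cfg$sex_split)
    ageg <- sample(.AGE_GROUPS, n, replace = TRUE, prob = cfg$age_group_probs)
    lo <- c("20-39" = 20, "40-59" = 40, "60+" = 60)[ageg]
    hi <- c("20-39" = 39, "40-59" = 59, "60+" = cfg$age_max)[ageg]
    age <- as.integer(floor(stats::runif(n, lo, hi + 1)))
    ses <- sample(.SES_LEVELS, n, replace = TRUE, prob = cfg$ses_probs)

    hp <- cfg$height_params_by_sex
    height <- ifelse(sex == "male",
                     stats::rnorm(n, hp$male["mean"], hp$male["sd"]),
                     stats::rnorm(n, hp$female["mean"], hp$female["sd"]))
    height <- pmin(pmax(height, 1.2), 2.2)

    gi <- match(ageg, .AGE_GROUPS)
    mu_bmi <- cfg$bmi_means_by_stratum[cbind(match(sex, .SEXES), gi)]
    bmi <- stats::rnorm(n, mu_bmi, cfg$bmi_sd)
    # redraw out-of-range values (truncated normal by rejection)
    bad <- which(bmi < cfg$bmi_range[1] | bmi > cfg$bmi_range[2])
    while (length(bad)) {
      bmi[bad] <- stats::rnorm(length(bad), mu_bmi[bad], cfg$bmi_sd)
      bad <- bad[bmi[bad] < cfg$bmi_range[1] | bmi[bad] > cfg$bmi_range[2]]
    }
    weight <- pmin(pmax(bmi * height^2, 30), 250)

    zero <- stats::runif(n) < cfg$ssb_zero_prob
    ssb <- ifelse(zero, 0,
                  stats::rlnorm(n, cfg$ssb_lognormal_mu, cfg$ssb_lognormal_sigma))
    ssb <- ssb * cfg$ses_consumption_shift[ses] *
      cfg$age_consumption_shift[ageg]

    svyw <- if (cfg$svy_weight_sdlog > 0)
      stats::rlnorm(n, -cfg$svy_weight_sdlog^2 / 2, cfg$svy_weight_sdlog)
    else rep(1, n)

    out <- data.frame(id = seq_len(n), sex = sex, age = age,
                      height_m = height, weight_kg = weight, ses = ses,
                      ssb_ml = as.numeric(ssb), svy_weight = svyw,
                      row.names = NULL)
    structure(out, class = c("ssb_population", "data.frame"), config = cfg)
  })
}

#' @export
print.ssb_population <- function(x, ...) {
  cat(sprintf("<ssb_population> %d adults\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  weighted mean SSB: %.1f ml/day; weighted mean BMI: %.2f kg/m2\n",
                weighted_mean(x$ssb_ml, x$svy_weight),
                weighted_mean(x$weight_kg / x$height_m^2, x$svy_weight)))
  }
  invisible(x)
}

#' @export
summary.ssb_population <- function(object, ...) {
  if (!nrow(object)) return(invisible(object))
  w <- object$svy_weight
  bmi <- object$weight_kg / object$height_m^2
  out <- data.frame(
    statistic = c("n", "weighted share female (%)", "weighted mean age (y)",
                  "weighted mean BMI (kg/m2)", "weighted mean SSB (ml/day)",
                  "weighted SD SSB (ml/day)"),
    value = c(nrow(object),
              100 * weighted_mean(object$sex == "female", w),
              weighted_mean(object$age, w),
              weighted_mean(bmi, w),
              weighted_mean(object$ssb_ml, w),
              weighted_sd(object$ssb_ml, w)))
  print(out, row.names = FALSE, digits = 5)
  invisible(out)
}

#' Weighted consumption quartiles
#'
#' Builds population taxed-SSB consumption quartiles from the
#' survey-weighted quartiles of `ssb_ml`. Individuals whose consumption
#' equals a boundary are assigned to the lower quartile, matching the
#' convention Q1 <= b1 < Q2 <= b2 < Q3 <= b3 < Q4.
#'
#' @param pop an `ssb_population` (non-empty).
#' @return factor of quartile labels `Q1..Q4`, one per row of `pop`, with
#'   the three boundary values (ml/day) in attribute `"boundaries"`.
#' @export
assign_quartiles <- function(pop) {
  if (!nrow(pop)) stop("cannot compute quartiles of an empty population",
                       call. = FALSE)
  stopifnot(all(pop$svy_weight > 0))
  b <- weighted_quantile(pop$ssb_ml, pop$svy_weight, c(0.25, 0.5, 0.75))
  q <- 1L + (pop$ssb_ml > b[1]) + (pop$ssb_ml > b[2]) + (pop$ssb_ml > b[3])
  out <- factor(paste0("Q", q), levels = paste0("Q", 1:4))
  names(out) <- pop$id
  attr(out, "boundaries") <- unname(b)
  out
}

#' Write / read a population CSV
#'
#' The CSV carries the documented header
#' `id,sex,age,height_m,weight_kg,ses,ssb_ml,svy_weight`. Reading validates
#' every row against the individual-level invariants (age >= 20, height in
#' 1.2-2.2 m, weight in 30-250 kg, non-negative consumption, positive
#' weight) and fails with the offending row number; unknown extra columns
#' are dropped with a warning.
#'
#' @param pop an `ssb_population` or compatible data.frame.
#' @param path file path.
#' @return `write_population` returns `path` invisibly; `read_population`
#'   returns an `ssb_population`.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop)[, .POP_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.POP_COLUMNS, names(df))
  if (length(missing))
    stop("population file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), .POP_COLUMNS)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    df <- df[, .POP_COLUMNS]
  }
  for (col in c("age", "height_m", "weight_kg", "ssb_ml", "svy_weight")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("non-numeric value in column '%s' at row %d", col, bad),
           call. = FALSE)
    }
  }
  check <- function(ok, what) {
    if (any(!ok))
      stop(sprintf("invalid %s at row %d", what, which(!ok)[1]), call. = FALSE)
  }
  check(df$age >= 20, "age (must be >= 20)")
  check(df$height_m >= 1.2 & df$height_m <= 2.2, "height_m (must be in [1.2, 2.2])")
  check(df$weight_kg >= 30 & df$weight_kg <= 250, "weight_kg (must be in [30, 250])")
  check(df$ssb_ml >= 0, "ssb_ml (must be >= 0)")
  check(df$svy_weight > 0, "svy_weight (must be > 0)")
  check(df$sex %in% .SEXES, "sex (must be male/female)")
  check(df$ses %in% .SES_LEVELS, "ses (must be low/medium/high)")
  structure(df, class = c("ssb_population", "data.frame"))
}

# age-group label used throughout the stratified tables
age_group <- function(age) {
  cut(age, c(20, 40, 60, Inf), right = FALSE, labels = .AGE_GROUPS)
}
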