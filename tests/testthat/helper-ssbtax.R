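# shared fixtures, built in code

# small hand-specified population for exact arithmetic checks
toy_population <- function(ssb = c(100, 300), ses = c("low", "low"),
                           weight = c(70, 80), height = c(1.6, 1.7),
                           sex = c("male", "female"), age = c(30, 50),
                           svy = rep(1, length(ssb))) {
  n <- length(ssb)
  structure(
    data.frame(id = seq_len(n), sex = rep_len(sex, n), age = rep_len(age, n),
               height_m = rep_len(height, n), weight_kg = rep_len(weight, n),
               ses = rep_len(ses, n), ssb_ml = ssb,
               svy_weight = rep_len(svy, n)),
    class = c("ssb_population", "data.frame"))
}

# a reference sedentary adult used in the ODE checks
reference_adult <- function(sex = "male", age = 40, height = 1.70,
                            bmi = 28) {
  toy_population(ssb = 300, ses = "medium", weight = bmi * height^2,
                 height = height, sex = sex, age = age)
}

# memoised default-calibration population shared across expensive tests
.fixture_env <- new.env(parent = emptyenv())
default_population <- function(n = 10000, seed = 20140101) {
  key <- paste0("pop_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_population(population_config(n = n, seed = seed))
  .fixture_env[[key]]
}

# memoised 10-year BMI panel for a tax scenario on the default population
default_panel <- function(scenario, n = 10000, seed = 20140101) {
  key <- paste0("panel_", scenario, "_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    pop <- default_population(n, seed)
    ch <- apply_tax(pop, scenario)
    .fixture_env[[key]] <- simulate_cohort(pop, ch$delta_kcal, at_years = c(1, 10))
  }
  .fixture_env[[key]]
}

# a hand-built rate schedule (bypasses the logistic/Gompertz constructors)
manual_schedule <- function(ages, rates, kind = "incidence", sex = "both") {
  structure(data.frame(kind = kind, sex = sex, age = ages, rate = rates),
            class = c("rate_schedule", "data.frame"), kind = kind)
}

# independent fine-step forward-Euler integration of the same physiology,
# written directly from the model equations; used as the ODE oracle
euler_oracle <- function(state, delta, days, dt = 0.05,
                         params = hall_parameters()) {
  p <- params
  F <- state$F; L <- state$L; G <- state$G; E <- state$ECF
  CI0 <- p$carb_fraction_baseline * state$I0
  CI <- max(CI0 + p$carb_fraction_delta * delta, 0)
  I <- state$I0 + delta
  denom_cache <- function(F) {
    pf <- p$forbes_C / (p$forbes_C + F)
    list(pf = pf,
         den = 1 + (1 - pf) * p$eta_F / p$rho_F + pf * p$eta_L / p$rho_L)
  }
  for (k in seq_len(round(days / dt))) {
    dG <- (CI - CI0 * (G / state$G)^2) / p$rho_G
    dE <- (p$xi_ci * (CI / CI0 - 1) - p$xi_na * (E - state$ECF)) / p$na_conc
    BW <- F + L + G * (1 + p$water_per_glycogen) + E
    dc <- denom_cache(F)
    Eb <- state$K + p$gamma_F * F + p$gamma_L * L + state$act * BW +
      p$tef_fraction * I + p$beta_AT * delta
    B <- (I - Eb - p$rho_G * dG) / dc$den
    F <- F + dt * (1 - dc$pf) * B / p$rho_F
    L <- L + dt * dc$pf * B / p$rho_L
    G <- G + dt * dG
    E <- E + dt * dE
  }
  F + L + G * (1 + p$water_per_glycogen) + E
}

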