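# Chow-Hall dynamic energy-balance model of individual body-weight change.
#
# State: fat mass F, lean tissue L, glycogen G and extracellular fluid ECF
# (kg). Body weight is BW = F + L + G*(1 + water_per_glycogen) + ECF. An
# intake perturbation delta (kcal/day, step at t = 0) is partitioned
# between fat and lean tissue along the Forbes curve via
# p(F) = C/(C + F); expenditure is
#   E = K + gamma_F*F + gamma_L*L + delta_act*BW + tef*I + beta_AT*(I - I0)
#       + eta_F*dF/dt + eta_L*dL/dt
# with K and the physical-activity coefficient delta_act calibrated at
# baseline so that E = I0 = PAL * RMR (energy balance before the tax).
# Glycogen tracks carbohydrate intake (dG = (CI - k*G^2)/rho_G) and ECF
# relaxes toward a carbohydrate-dependent offset; both matter only in the
# first weeks.

#' Parameters of the Chow-Hall weight-change model
#'
#' Defaults are standard values from the Hall energy-balance literature:
#' tissue energy densities 9441 (fat) and 1816 (lean) kcal/kg, resting
#' expenditure coefficients 3.2 and 22 kcal/kg/day, deposition costs 180
#' and 230 kcal/kg, adaptive thermogenesis 0.14 of the intake change,
#' thermic effect of food 0.1 of intake, and a Forbes partition constant
#' `C = forbes_slope * rho_L / rho_F` (~2 kg) derived from the Forbes
#' lean-vs-fat slope of 10.4 kg. Everyone is simulated at the sedentary
#' physical activity level 1.5 unless overridden.
#'
#' @param rho_F,rho_L energy density of fat / lean tissue, kcal/kg.
#' @param gamma_F,gamma_L resting-expenditure coefficients, kcal/kg/day.
#' @param eta_F,eta_L tissue-deposition costs, kcal/kg.
#' @param beta_AT adaptive-thermogenesis fraction of the intake change.
#' @param tef_fraction thermic effect of food, fraction of intake.
#' @param forbes_slope Forbes lean-vs-log-fat slope, kg.
#' @param forbes_C Forbes partition constant, kg; computed from
#'   `forbes_slope` when `NULL`.
#' @param rho_G glycogen energy density, kcal/kg.
#' @param glycogen_baseline baseline glycogen store, kg.
#' @param water_per_glycogen kg of water bound per kg glycogen.
#' @param na_conc extracellular sodium concentration, mg/L.
#' @param xi_na sodium excretion response, mg/day per L of ECF change.
#' @param xi_ci sodium response to carbohydrate restriction, mg/day.
#' @param carb_fraction_baseline carbohydrate fraction of baseline intake.
#' @param carb_fraction_delta carbohydrate fraction of the intake change
#'   (1: the removed SSB calories are all sugar).
#' @param ecf_fraction baseline ECF as a fraction of body weight.
#' @param pal physical activity level (total / resting expenditure).
#' @return list of class `hall_parameters`.
#' @export
hall_parameters <- function(rho_F = 9441, rho_L = 1816,
                            gamma_F = 3.2, gamma_L = 22,
                            eta_F = 180, eta_L = 230,
                            beta_AT = 0.14, tef_fraction = 0.10,
                            forbes_slope = 10.4, forbes_C = NULL,
                            rho_G = 4180, glycogen_baseline = 0.5,
                            water_per_glycogen = 2.7,
                            na_conc = 3220, xi_na = 3000, xi_ci = 4000,
                            carb_fraction_baseline = 0.5,
                            carb_fraction_delta = 1,
                            ecf_fraction = 0.22, pal = 1.5) {
  if (is.null(forbes_C)) forbes_C <- forbes_slope * rho_L / rho_F
  p <- list(rho_F = rho_F, rho_L = rho_L, gamma_F = gamma_F,
            gamma_L = gamma_L, eta_F = eta_F, eta_L = eta_L,
            beta_AT = beta_AT, tef_fraction = tef_fraction,
            forbes_slope = forbes_slope, forbes_C = forbes_C, rho_G = rho_G,
            glycogen_baseline = glycogen_baseline,
            water_per_glycogen = water_per_glycogen, na_conc = na_conc,
            xi_na = xi_na, xi_ci = xi_ci,
            carb_fraction_baseline = carb_fraction_baseline,
            carb_fraction_delta = carb_fraction_delta,
            ecf_fraction = ecf_fraction, pal = pal)
  dens <- c(rho_F, rho_L, rho_G, gamma_F, gamma_L, eta_F, eta_L, forbes_C,
            na_conc, xi_na, xi_ci)
  if (any(dens <= 0)) stop("densities and coefficients must be > 0", call. = FALSE)
  if (beta_AT < 0 || beta_AT >= 1 || tef_fraction < 0 || tef_fraction >= 1)
    stop("`beta_AT` and `tef_fraction` must lie in [0, 1)", call. = FALSE)
  if (pal < 1) stop("`pal` must be >= 1", call. = FALSE)
  if (pal * (1 - tef_fraction) <= 1)
    stop("`pal` too low: no energy left for physical activity after TEF",
         call. = FALSE)
  structure(p, class = "hall_parameters")
}

# Mifflin-St Jeor resting metabolic rate, kcal/day (vectorised)
resting_metabolic_rate <- function(weight_kg, height_m, age, sex) {
  10 * weight_kg + 625 * height_m - 5 * age + ifelse(sex == "male", 5, -161)
}

# Deurenberg (1991) body-fat fraction from BMI, age and sex
deurenberg_fat_fraction <- function(bmi, age, sex) {
  (1.20 * bmi + 0.23 * age - 10.8 * (sex == "male") - 5.4) / 100
}

# vectorised baseline state for all rows of `pop`; returns a list of
# equal-length vectors (used by both the scalar and cohort interfaces)
init_states <- function(pop, params = hall_parameters()) {
  bmi <- pop$weight_kg / pop$height_m^2
  ff <- deurenberg_fat_fraction(bmi, pop$age, pop$sex)
  F0 <- ff * pop$weight_kg
  G0 <- rep(params$glycogen_baseline, nrow(pop))
  ECF0 <- params$ecf_fraction * pop$weight_kg
  L0 <- pop$weight_kg - F0 - G0 * (1 + params$water_per_glycogen) - ECF0
  bad <- which(F0 <= 0 | F0 >= pop$weight_kg | L0 <= 0)
  if (length(bad))
    stop("fat-mass estimator gave non-physiologic composition for id(s): ",
         paste(utils::head(pop$id[bad], 5), collapse = ", "), call. = FALSE)
  rmr <- resting_metabolic_rate(pop$weight_kg, pop$height_m, pop$age, pop$sex)
  I0 <- params$pal * rmr
  # activity coefficient from baseline balance: I0 = RMR + act*BW + tef*I0
  act <- rmr * (params$pal * (1 - params$tef_fraction) - 1) / pop$weight_kg
  K <- rmr - params$gamma_F * F0 - params$gamma_L * L0
  list(F = F0, L = L0, G = G0, ECF = ECF0, K = K, I0 = I0, act = act,
       BW0 = pop$weight_kg, height = pop$height_m, id = pop$id)
}

#' Baseline body composition and energy balance for one individual
#'
#' Partitions measured weight into fat (Deurenberg sex/age/BMI estimator),
#' lean tissue, baseline glycogen (plus bound water) and extracellular
#' fluid, and calibrates the expenditure offset `K` and the
#' physical-activity coefficient so that total expenditure equals the
#' inferred baseline intake `I0 = PAL * RMR` (Mifflin-St Jeor RMR).
#' Non-physiologic compositions raise an error naming the individual.
#'
#' @param ind one-row `ssb_population` (or any row with the same columns).
#' @param params a [hall_parameters()] object.
#' @return list of class `body_state` with components `F`, `L`, `G`, `ECF`
#'   (kg), `K` (kcal/day), `I0` (kcal/day) and `act` (kcal/kg/day).
#' @export
initialize_state <- function(ind, params = hall_parameters()) {
  stopifnot(nrow(ind) == 1)
  st <- init_states(ind, params)
  structure(lapply(st, `[`, 1), class = "body_state", params = params)
}

#' @export
print.body_state <- function(x, ...) {
  cat(sprintf("<body_state> F %.1f kg, L %.1f kg, G %.2f kg, ECF %.1f kg (BW %.1f kg)\n",
              x$F, x$L, x$G, x$ECF, x$BW0))
  cat(sprintf("  baseline intake %.0f kcal/day, K %.0f kcal/day\n", x$I0, x$K))
  invisible(x)
}

# one RK4 derivative evaluation; st is a list of vectors, delta a vector
hall_deriv <- function(F, L, G, ECF, st, delta, p) {
  CI0 <- p$carb_fraction_baseline * st$I0
  CI <- pmax(CI0 + p$carb_fraction_delta * delta, 0)
  I <- st$I0 + delta
  dG <- (CI - CI0 * (G / st$G)^2) / p$rho_G
  dECF <- (p$xi_ci * (CI / CI0 - 1) - p$xi_na * (ECF - st$ECF)) / p$na_conc
  BW <- F + L + G * (1 + p$water_per_glycogen) + ECF
  pf <- p$forbes_C / (p$forbes_C + F)
  Ebase <- st$K + p$gamma_F * F + p$gamma_L * L + st$act * BW +
    p$tef_fraction * I + p$beta_AT * delta
  B <- (I - Ebase - p$rho_G * dG) /
    (1 + (1 - pf) * p$eta_F / p$rho_F + pf * p$eta_L / p$rho_L)
  list(dF = (1 - pf) * B / p$rho_F, dL = pf * B / p$rho_L,
       dG = dG, dECF = dECF)
}

# fixed-step RK4 over `days`; returns matrix of body weight (rows =
# individuals, cols = save_days). st: vectorised init_states output.
hall_integrate <- function(st, delta, params, days, dt = 1,
                           save_days = days) {
  n <- length(st$F)
  delta <- rep_len(delta, n)
  Fm <- st$F; Lm <- st$L; Gm <- st$G; Em <- st$ECF
  save_days <- sort(unique(save_days))
  out <- matrix(NA_real_, n, length(save_days),
                dimnames = list(NULL, paste0("d", save_days)))
  bw <- function() Fm + Lm + Gm * (1 + params$water_per_glycogen) + Em
  si <- 1
  if (save_days[1] == 0) { out[, 1] <- bw(); si <- 2 }
  nstep <- ceiling(days / dt - 1e-9)
  t <- 0
  for (k in seq_len(nstep)) {
    h <- min(k * dt, days) - t
    k1 <- hall_deriv(Fm, Lm, Gm, Em, st, delta, params)
    k2 <- hall_deriv(Fm + h / 2 * k1$dF, Lm + h / 2 * k1$dL,
                     Gm + h / 2 * k1$dG, Em + h / 2 * k1$dECF, st, delta, params)
    k3 <- hall_deriv(Fm + h / 2 * k2$dF, Lm + h / 2 * k2$dL,
                     Gm + h / 2 * k2$dG, Em + h / 2 * k2$dECF, st, delta, params)
    k4 <- hall_deriv(Fm + h * k3$dF, Lm + h * k3$dL,
                     Gm + h * k3$dG, Em + h * k3$dECF, st, delta, params)
    Fm <- Fm + h / 6 * (k1$dF + 2 * k2$dF + 2 * k3$dF + k4$dF)
    Lm <- Lm + h / 6 * (k1$dL + 2 * k2$dL + 2 * k3$dL + k4$dL)
    Gm <- Gm + h / 6 * (k1$dG + 2 * k2$dG + 2 * k3$dG + k4$dG)
    Em <- Em + h / 6 * (k1$dECF + 2 * k2$dECF + 2 * k3$dECF + k4$dECF)
    t <- min(k * dt, days)
    if (any(!is.finite(Fm)) || any(!is.finite(Lm)))
      stop(sprintf("non-finite state at day %.1f for id(s) %s",
                   t, paste(utils::head(st$id[!is.finite(Fm + Lm)], 5),
                            collapse = ", ")), call. = FALSE)
    while (si <= length(save_days) && t >= save_days[si] - 1e-6) {
      out[, si] <- bw()
      si <- si + 1
    }
  }
  out
}

#' Simulate one individual's weight trajectory
#'
#' Integrates the coupled fat/lean/glycogen/ECF system under a permanent
#' intake step of `delta_kcal` kcal/day using fixed-step fourth-order
#' Runge-Kutta, and returns weight and BMI at the requested times (always
#' including 1 and 10 years when within the horizon).
#'
#' @param state a `body_state` from [initialize_state()].
#' @param ind the matching one-row population data.
#' @param delta_kcal intake change, kcal/day (negative under the tax).
#' @param years integration horizon.
#' @param dt step size, days.
#' @param save_days days at which to report; defaults to a coarse grid
#'   plus the 1- and 10-year marks.
#' @param params a [hall_parameters()] object (defaults to the one used at
#'   initialization).
#' @return data.frame of class `weight_trajectory` with columns
#'   `t_days, weight_kg, bmi`.
#' @export
simulate_weight <- function(state, ind, delta_kcal, years = 10, dt = 1,
                            save_days = NULL, params = NULL) {
  stopifnot(dt > 0, years > 0)
  if (is.null(params)) params <- attr(state, "params")
  if (is.null(params)) params <- hall_parameters()
  days <- round(365 * years)
  if (is.null(save_days)) {
    save_days <- unique(sort(c(seq(0, days, by = 91), 365,
                               min(3650, days), days)))
    save_days <- save_days[save_days <= days]
  }
  st <- lapply(state, identity)
  bw <- hall_integrate(st, delta_kcal, params, days, dt, save_days)
  out <- data.frame(t_days = sort(unique(save_days)),
                    weight_kg = as.numeric(bw[1, ]))
  out$bmi <- out$weight_kg / st$height[1]^2
  structure(out, class = c("weight_trajectory", "data.frame"),
            delta_kcal = delta_kcal, id = st$id[1])
}

#' @export
print.weight_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<weight_trajectory> id %s, delta %.1f kcal/day: %.2f kg -> %.2f kg over %.1f y\n",
              attr(x, "id"), attr(x, "delta_kcal"),
              x$weight_kg[1], x$weight_kg[n], x$t_days[n] / 365))
  invisible(x)
}

#' @export
plot.weight_trajectory <- function(x, ...) {
  plot(x$t_days / 365, x$weight_kg, type = "l", xlab = "years",
       ylab = "body weight (kg)", ...)
  invisible(x)
}

#' Simulate weight change for a whole population
#'
#' Vectorised counterpart of [simulate_weight()]: all individuals are
#' integrated simultaneously and BMI is reported at the requested
#' year marks.
#'
#' @param pop an `ssb_population`.
#' @param delta_kcal per-individual intake change, kcal/day (recycled).
#' @param params a [hall_parameters()] object.
#' @param years horizon.
#' @param dt RK4 step, days.
#' @param at_years report times, years.
#' @return matrix of class `bmi_panel` (rows = individuals, columns =
#'   report times) of BMI values, with baseline BMI in attribute
#'   `"baseline_bmi"` and report times in attribute `"years"`.
#' @export
simulate_cohort <- function(pop, delta_kcal, params = hall_parameters(),
                            years = 10, dt = 1, at_years = c(1, 10)) {
  st <- init_states(pop, params)
  at_years <- sort(unique(at_years))
  stopifnot(max(at_years) <= years)
  bw <- hall_integrate(st, delta_kcal, params, round(365 * years), dt,
                       save_days = round(365 * at_years))
  bmi <- bw / st$height^2
  colnames(bmi) <- paste0("y", at_years)
  structure(bmi, class = c("bmi_panel", "matrix"),
            baseline_bmi = pop$weight_kg / pop$height_m^2,
            years = at_years, id = pop$id)
}

#' Closed-form steady-state weight change
#'
#' Solves the algebraic steady-state condition `E(F*, L*) = I0 + delta`
#' along the Forbes curve through the individual's baseline composition
#' (with glycogen and ECF at their perturbed equilibria), giving the
#' t -> infinity limit of [simulate_weight()]. Used as a long-horizon
#' validation oracle for the ODE.
#'
#' @inheritParams simulate_weight
#' @return steady-state body-weight change, kg (negative for negative
#'   `delta_kcal`).
#' @export
steady_state_weight_change <- function(state, ind, delta_kcal,
                                       params = NULL) {
  if (is.null(params)) params <- attr(state, "params")
  if (is.null(params)) params <- hall_parameters()
  p <- params
  F0 <- state$F; L0 <- state$L
  CI0 <- p$carb_fraction_baseline * state$I0
  CI <- max(CI0 + p$carb_fraction_delta * delta_kcal, 0)
  Gs <- state$G * sqrt(CI / CI0)
  ECFs <- state$ECF + (p$xi_ci / p$xi_na) * (CI / CI0 - 1)
  I <- state$I0 + delta_kcal
  lean <- function(F) L0 + p$forbes_C * (p$rho_F / p$rho_L) * log(F / F0)
  bodyw <- function(F) F + lean(F) + Gs * (1 + p$water_per_glycogen) + ECFs
  g <- function(F) {
    state$K + p$gamma_F * F + p$gamma_L * lean(F) + state$act * bodyw(F) +
      p$tef_fraction * I + p$beta_AT * delta_kcal - I
  }
  lo <- 1e-3
  hi <- 2 * state$BW0
  if (g(lo) * g(hi) > 0)
    stop("no steady state in the physiologic range for this perturbation",
         call. = FALSE)
  Fs <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  bodyw(Fs) - state$BW0
}
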