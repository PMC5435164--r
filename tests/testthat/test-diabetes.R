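toy_structure <- function(counts, ages, ses = "low", sex = "male") {
  arr <- array(counts, c(length(ages), 1, 1),
               dimnames = list(age = ages, sex = sex, ses = ses))
  arr
}

test_that("the counterfactual multiplier is the RR raised to the servings change", {
  lk <- risk_link(c(low = -1, medium = -0.5, high = 0))
  m <- incidence_multiplier(lk)
  expect_equal(unname(m["low"]), 0.7936508, tolerance = 1e-6)
  expect_equal(unname(m["medium"]), 0.8908708, tolerance = 1e-6)
  expect_equal(unname(m["high"]), 1)
  expect_error(risk_link(c(low = -1)), "named")
})

test_that("SES-group servings changes are the weighted per-capita means", {
  pop <- toy_population(ssb = c(355, 710, 355), ses = c("low", "low", "high"),
                        svy = c(1, 1, 2))
  ch <- apply_tax(pop, "avg10", serving_size_ml = 355)
  d <- ses_mean_servings_change(pop, ch)
  expect_equal(unname(d["low"]), -0.091 * (1 + 2) / 2)
  expect_equal(unname(d["high"]), -0.055)
  expect_true(is.nan(d["medium"]) || is.na(d["medium"]))
})

test_that("a two-year three-age cohort matches the pencil-and-paper table", {
  ages <- c(50, 51, 52)
  lam <- c(0.1, 0.2, 0.3)
  mu <- 0.05
  inc <- manual_schedule(ages, lam)
  mort <- manual_schedule(ages, rep(mu, 3), kind = "mortality", sex = "male")
  births <- birth_projection(2015:2017, 0)
  proj <- project_diabetes(toy_structure(rep(1000, 3), ages),
                           incidence = inc, mortality = mort, births = births,
                           start_year = 2015, end_year = 2017,
                           init_incidence_fraction = 0)

  # year 1 -> 2, worked by hand age by age:
  new1 <- 1000 * (1 - exp(-lam))                   # incident cases
  S1 <- 1000 - new1
  D1 <- new1
  die <- 1 - exp(-mu)                              # same both states (HR = 1)
  S1 <- S1 * (1 - die); D1 <- D1 * (1 - die)
  # ageing: top bin accumulates, age-50 slot empties (no births)
  S2015 <- c(0, S1[1], S1[2] + S1[3])
  D2015 <- c(0, D1[1], D1[2] + D1[3])
  expect_equal(proj$incident_cases[2], sum(new1))
  expect_equal(proj$prevalence_pct[2], 100 * sum(D2015) / sum(S2015 + D2015))

  # year 2 -> 3 from the shifted table
  new2 <- S2015 * (1 - exp(-lam))
  S2 <- (S2015 - new2) * (1 - die)
  D2 <- (D2015 + new2) * (1 - die)
  S2016 <- c(0, S2[1], S2[2] + S2[3])
  D2016 <- c(0, D2[1], D2[2] + D2[3])
  expect_equal(proj$incident_cases[3], sum(new2))
  expect_equal(proj$prevalence_pct[3], 100 * sum(D2016) / sum(S2016 + D2016))
  expect_lt(attr(proj, "conservation_error"), 1e-9)
})

test_that("cohort recursion agrees with a stochastic microsimulation", {
  ages <- c(40, 41, 42, 43)
  lam <- c(0.05, 0.08, 0.12, 0.15)
  mu <- 0.02
  inc <- manual_schedule(ages, lam)
  mort <- manual_schedule(ages, rep(mu, 4), kind = "mortality", sex = "male")
  births <- birth_projection(2015:2018, 0)
  n0 <- 200000
  proj <- project_diabetes(toy_structure(c(n0, 0, 0, 0), ages),
                           incidence = inc, mortality = mort, births = births,
                           start_year = 2015, end_year = 2018,
                           init_incidence_fraction = 0)
  # individual-level simulation of the same single cohort
  set.seed(1234)
  state <- integer(n0)  # 0 susceptible, 1 diagnosed, 2 dead
  pdie <- 1 - exp(-mu)
  for (k in 1:3) {
    p_inc <- 1 - exp(-lam[k])
    sus <- state == 0
    state[sus][stats::runif(sum(sus)) < p_inc] <- 1L
    alive <- state < 2
    state[alive][stats::runif(sum(alive)) < pdie] <- 2L
  }
  prev_micro <- mean(state[state < 2] == 1)
  n_alive <- sum(state < 2)
  se <- sqrt(prev_micro * (1 - prev_micro) / n_alive)
  prev_model <- proj$prevalence_pct[4] / 100
  expect_lt(abs(prev_model - prev_micro), 3 * se)
})

test_that("a null counterfactual reproduces the baseline exactly", {
  base <- project_diabetes(end_year = 2030)
  null_link <- risk_link(c(low = 0, medium = 0, high = 0))
  same <- project_diabetes(link = null_link, end_year = 2030)
  expect_equal(as.data.frame(base), as.data.frame(same), ignore_attr = TRUE)
  expect_equal(unname(averted_cases(base, same, 2030)), 0)
})

test_that("zero incidence yields zero prevalence in every year", {
  inc0 <- manual_schedule(0:100, rep(0, 101))
  proj <- project_diabetes(incidence = inc0, end_year = 2030,
                           init_incidence_fraction = 0.5)
  expect_true(all(proj$prevalence_pct == 0))
})

test_that("abolishing incidence averts exactly the baseline incident cases", {
  base <- project_diabetes(end_year = 2025)
  lk <- risk_link(c(low = -1000, medium = -1000, high = -1000))
  none <- project_diabetes(link = lk, end_year = 2025)
  expect_equal(unname(averted_cases(base, none, 2025)),
               sum(base$incident_cases), tolerance = 1e-9)
  short <- project_diabetes(end_year = 2024)
  expect_error(averted_cases(base, short), "mismatched")
  expect_error(averted_cases(base, base, 2060), "horizon")
})

test_that("smaller multipliers lower prevalence and raise averted cases", {
  base <- project_diabetes(end_year = 2035)
  lk_small <- risk_link(c(low = -0.1, medium = -0.1, high = -0.1))
  lk_big <- risk_link(c(low = -0.4, medium = -0.4, high = -0.4))
  a <- project_diabetes(link = lk_small, end_year = 2035)
  b <- project_diabetes(link = lk_big, end_year = 2035)
  expect_true(all(b$prevalence_pct[-1] < a$prevalence_pct[-1]))
  expect_true(all(a$prevalence_pct[-1] < base$prevalence_pct[-1]))
  expect_gt(unname(averted_cases(base, b, 2035)),
            unname(averted_cases(base, a, 2035)))
})

test_that("incidence scenarios order the projected prevalence", {
  projs <- lapply(c("optimistic", "intermediate", "pessimistic"), function(s)
    project_diabetes(incidence = incidence_schedule(s), end_year = 2035))
  expect_true(all(projs[[3]]$prevalence_pct >= projs[[2]]$prevalence_pct))
  expect_true(all(projs[[2]]$prevalence_pct >= projs[[1]]$prevalence_pct))
})

test_that("the RR confidence bounds bracket the central averted-case count", {
  d <- c(low = -0.09, medium = -0.05, high = -0.05)
  base <- project_diabetes(end_year = 2030)
  av <- vapply(c(1.12, 1.26, 1.41), function(rr)
    unname(averted_cases(base,
                         project_diabetes(link = risk_link(d, rr_per_serving = rr),
                                          end_year = 2030), 2030)),
    numeric(1))
  expect_lt(av[1], av[2])
  expect_lt(av[2], av[3])
})

test_that("diabetic excess mortality lowers observed prevalence", {
  base <- project_diabetes(end_year = 2035)
  hr <- project_diabetes(end_year = 2035, excess_mortality_hr = 1.8)
  expect_lt(hr$prevalence_pct[21], base$prevalence_pct[21])
  expect_lt(attr(hr, "conservation_error"), 1e-6 * 121e6)
})
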