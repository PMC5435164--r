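test_that("generation is deterministic given a seed and empty for n = 0", {
  cfg <- population_config(n = 200, seed = 99)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- generate_population(population_config(n = 200, seed = 100))
  expect_false(identical(a$ssb_ml, d$ssb_ml))
  empty <- generate_population(population_config(n = 0))
  expect_s3_class(empty, "ssb_population")
  expect_identical(nrow(empty), 0L)
})

test_that("generated individuals satisfy the domain invariants", {
  pop <- default_population(n = 5000)
  expect_true(all(pop$age >= 20))
  expect_true(all(pop$height_m >= 1.2 & pop$height_m <= 2.2))
  expect_true(all(pop$weight_kg >= 30 & pop$weight_kg <= 250))
  expect_true(all(pop$ssb_ml >= 0))
  expect_true(all(pop$svy_weight > 0))
  expect_true(all(is.finite(pop$weight_kg / pop$height_m^2)))
})

test_that("marginals recover the configured targets at large n", {
  cfg <- population_config(n = 50000, seed = 7)
  pop <- generate_population(cfg)
  # categorical splits within 1.5 percentage points
  expect_lt(abs(mean(pop$sex == "male") - cfg$sex_split["male"]), 0.015)
  ag <- table(cut(pop$age, c(20, 40, 60, Inf), right = FALSE)) / nrow(pop)
  expect_lt(max(abs(ag - cfg$age_group_probs)), 0.015)
  ses <- table(factor(pop$ses, c("low", "medium", "high"))) / nrow(pop)
  expect_lt(max(abs(ses - cfg$ses_probs)), 0.015)
  # SSB mean and SD within 5% of the analytic values the config implies
  m1 <- (1 - cfg$ssb_zero_prob) *
    exp(cfg$ssb_lognormal_mu + cfg$ssb_lognormal_sigma^2 / 2)
  m2 <- (1 - cfg$ssb_zero_prob) *
    exp(2 * cfg$ssb_lognormal_mu + 2 * cfg$ssb_lognormal_sigma^2)
  sh <- cfg$ses_consumption_shift[c("low", "medium", "high")]
  pr <- cfg$ses_probs[c("low", "medium", "high")]
  sha <- cfg$age_consumption_shift
  pra <- cfg$age_group_probs
  target_mean <- sum(pr * sh) * sum(pra * sha) * m1
  target_sd <- sqrt(sum(pr * sh^2) * sum(pra * sha^2) * m2 - target_mean^2)
  expect_lt(abs(mean(pop$ssb_ml) / target_mean - 1), 0.05)
  expect_lt(abs(sd(pop$ssb_ml) / target_sd - 1), 0.05)
})

test_that("SES consumption gradient puts low above high", {
  pop <- default_population(n = 20000, seed = 5)
  m <- tapply(pop$ssb_ml, pop$ses, mean)
  expect_gt(m["low"], m["medium"])
  expect_gt(m["medium"], m["high"])
})

test_that("quartile assignment follows the weighted order statistics", {
  pop <- toy_population(ssb = c(10, 100, 300, 500), ses = rep("low", 4))
  q <- assign_quartiles(pop)
  expect_identical(as.character(q), c("Q1", "Q2", "Q3", "Q4"))
  # boundary ties go to the lower quartile
  b <- attr(q, "boundaries")
  pop2 <- toy_population(ssb = c(b[1], b[1] + 1e-9, 300, 500),
                         ses = rep("low", 4))
  q2 <- assign_quartiles(pop2)
  expect_identical(as.character(q2)[1:2], c("Q1", "Q2"))
})

test_that("quartile boundaries are invariant to doubling all weights", {
  pop <- default_population(n = 2000)
  doubled <- pop
  doubled$svy_weight <- 2 * doubled$svy_weight
  expect_identical(attr(assign_quartiles(pop), "boundaries"),
                   attr(assign_quartiles(doubled), "boundaries"))
  expect_error(assign_quartiles(pop[0, ]), "empty")
})

test_that("default-calibration quartile boundaries sit near the survey cut points", {
  pop <- default_population(n = 10000)
  b <- attr(assign_quartiles(pop), "boundaries")
  printed <- c(33.94, 129.64, 402.86)
  expect_true(all(abs(b / printed - 1) < 0.15))
})

test_that("population CSV round-trips losslessly and validates rows", {
  pop <- default_population(n = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(as.data.frame(back), as.data.frame(pop),
               ignore_attr = TRUE, tolerance = 1e-12)

  bad <- as.data.frame(pop)
  bad$ssb_ml[3] <- -5
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_population(path), "row 3")

  young <- as.data.frame(pop)
  young$age[7] <- 15
  utils::write.csv(young, path, row.names = FALSE)
  expect_error(read_population(path), "age.*row 7")

  utils::write.csv(as.data.frame(pop)[, -4], path, row.names = FALSE)
  expect_error(read_population(path), "missing column")

  extra <- cbind(as.data.frame(pop), note = "x")
  utils::write.csv(extra, path, row.names = FALSE)
  expect_warning(got <- read_population(path), "unknown column")
  expect_identical(names(got),
                   c("id", "sex", "age", "height_m", "weight_kg", "ses",
                     "ssb_ml", "svy_weight"))
})

test_that("configuration validation rejects malformed probability vectors", {
  expect_error(population_config(ses_probs = c(low = 0.5, medium = 0.4,
                                               high = 0.2)), "sum to 1")
  expect_error(population_config(n = -1), "non-negative")
  expect_error(population_config(bmi_sd = 0), "standard deviations")
  expect_error(population_config(ssb_zero_prob = 1), "ssb_zero_prob")
})

test_that("incidence schedules are zero in childhood and ordered by scenario", {
  opt <- incidence_schedule("optimistic")
  mid <- incidence_schedule("intermediate")
  pes <- incidence_schedule("pessimistic")
  expect_identical(opt$rate[opt$age == 10], 0)
  at50 <- function(s) s$rate[s$age == 50]
  expect_gt(at50(pes), at50(mid))
  expect_gt(at50(mid), at50(opt))
  expect_true(all(pes$rate >= mid$rate))
  expect_true(all(mid$rate >= opt$rate))
  adult <- mid$rate[mid$age >= 20]
  expect_true(all(diff(adult) >= 0))
  expect_error(incidence_schedule("catastrophic"), "should be one of")
})

test_that("Gompertz mortality is monotone and degenerates correctly", {
  m <- mortality_schedule()
  for (s in c("male", "female")) {
    r <- m$rate[m$sex == s]
    expect_true(all(diff(r) >= 0))
    expect_gt(m$rate[m$sex == s & m$age == 80], m$rate[m$sex == s & m$age == 40])
  }
  flat <- mortality_schedule(slope = 0)
  expect_identical(length(unique(flat$rate[flat$sex == "male"])), 1L)
  expect_true(all(m$rate >= 0 & m$rate <= 0.7))
  expect_error(mortality_schedule(level_male = -1), "non-negative")
})

test_that("birth projections validate their horizon", {
  b <- birth_projection(2015:2020, 1e6)
  expect_equal(sum(b$births[b$year == 2015]), 1e6)
  expect_error(birth_projection(c(2015, 2017)), "contiguous")
  expect_error(birth_projection(2015:2016, -5), ">= 0")
})
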