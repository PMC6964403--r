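test_that("weighted prevalence is the weight-normalized mean with complete-case handling", {
  d <- data.frame(weight = c(1, 1, 1), flag = c(0, 0, 0))
  expect_identical(weighted_prevalence(d, "flag"), 0)

  d <- data.frame(weight = c(1, 3), flag = c(1, 0))
  expect_equal(weighted_prevalence(d, "flag"), 0.25)

  # equal weights reduce to the unweighted proportion
  set.seed(11)
  x <- rbinom(50, 1, 0.3)
  d <- data.frame(weight = rep(2.7, 50), flag = x)
  expect_equal(weighted_prevalence(d, "flag"), mean(x))

  # missing indicators leave numerator and denominator together
  d <- data.frame(weight = c(1, 3, 10), flag = c(1, 0, NA))
  expect_equal(weighted_prevalence(d, "flag"), 0.25)

  # rescaling all weights changes nothing
  set.seed(12)
  d <- data.frame(weight = runif(40, 0.5, 5), flag = rbinom(40, 1, 0.4))
  for (k in c(0.001, 7, 1e6)) {
    d2 <- transform(d, weight = weight * k)
    expect_equal(weighted_prevalence(d2, "flag"),
                 weighted_prevalence(d, "flag"))
  }

  # empty domains are loud, never a silent zero
  d <- data.frame(weight = 1, flag = NA_real_)
  expect_error(weighted_prevalence(d, "flag"), "no respondents")
  d <- data.frame(weight = c(1, 1), flag = c(0, 1))
  expect_error(weighted_prevalence(d, "flag", domain = c(FALSE, FALSE)),
               "no respondents")
})

test_that("chronic disease prevalence is a per-respondent union, not a sum", {
  d <- data.frame(weight = c(1, 1),
                  asthma = c(1, 0), copd = c(0, 0),
                  heart_disease = c(0, 0), diabetes = c(1, 0))
  expect_equal(chronic_disease_prevalence(d), 0.5)  # comorbidity counts once

  # respondents missing any component are excluded from the union estimate
  d2 <- rbind(d, data.frame(weight = 100, asthma = NA, copd = 0,
                            heart_disease = 0, diabetes = 0))
  expect_equal(chronic_disease_prevalence(d2), 0.5)

  # disjoint conditions at 0.1 each union to ~0.4
  set.seed(13)
  n <- 20000
  which_cond <- sample(0:9, n, replace = TRUE)  # 0..3 -> one condition each
  d3 <- data.frame(weight = runif(n, 0.5, 2),
                   asthma = as.integer(which_cond == 0),
                   copd = as.integer(which_cond == 1),
                   heart_disease = as.integer(which_cond == 2),
                   diabetes = as.integer(which_cond == 3))
  expect_equal(chronic_disease_prevalence(d3), 0.4, tolerance = 0.02)

  # union bounds: at least the max component, at most the sum
  set.seed(14)
  d4 <- data.frame(weight = runif(500, 0.5, 2),
                   asthma = rbinom(500, 1, 0.2), copd = rbinom(500, 1, 0.1),
                   heart_disease = rbinom(500, 1, 0.15),
                   diabetes = rbinom(500, 1, 0.05))
  comp <- vapply(c("asthma", "copd", "heart_disease", "diabetes"),
                 function(k) weighted_prevalence(d4, k), numeric(1))
  u <- chronic_disease_prevalence(d4)
  expect_gte(u, max(comp))
  expect_lte(u, sum(comp))
})

test_that("pregnancy point prevalence is events times durations over female population", {
  base <- data.frame(stratum = "25-34", live_births = 0, fetal_losses = 0,
                     induced_abortions = 0, female_population = 1e5)
  expect_equal(unname(pregnancy_point_prevalence(base)["25-34"]), 0)

  x <- transform(base, live_births = 1000)
  p <- pregnancy_point_prevalence(x, durations = list(birth = 0.75,
                                                      loss = 11 / 52,
                                                      abortion = 10 / 52))
  expect_equal(unname(p["25-34"]), 0.0075)
  expect_equal(unname(p["45-64"]), 0)  # strata without events stay at 0

  # linear in the counts and in each duration
  x2 <- transform(x, live_births = 2000, fetal_losses = 0)
  expect_equal(pregnancy_point_prevalence(x2, list(birth = 0.75, loss = 11/52,
                                                   abortion = 10/52))["25-34"],
               2 * p["25-34"])
  p_half <- pregnancy_point_prevalence(x, list(birth = 0.375, loss = 11/52,
                                               abortion = 10/52))
  expect_equal(unname(p_half["25-34"]), 0.00375)

  # counts inconsistent with the population are a data error
  bad <- transform(base, live_births = 2e5)
  expect_error(pregnancy_point_prevalence(bad), "exceeds 1")
})

test_that("pregnancy and urbanicity adjustments are the stated convex forms", {
  expect_equal(effective_pregnancy_prevalence(0.02, 0.5), 0.01)
  expect_equal(effective_pregnancy_prevalence(0.3, 0), 0)
  expect_equal(effective_pregnancy_prevalence(0, 0.7), 0)

  expect_equal(urbanicity_adjusted_prevalence(0.2, 0.4, 1.0), 0.2)
  expect_equal(urbanicity_adjusted_prevalence(0.2, 0.4, 0.0), 0.4)
  expect_equal(urbanicity_adjusted_prevalence(0.2, 0.4, 0.25), 0.35)
})

test_that("built prevalence tables cover exactly the criteria scope with valid values", {
  w <- simulate_world(tiny_config())
  pt <- build_prevalence_table(w$survey, w$supplied, w$pregnancy_inputs,
                               w$regions, criteria_set("restrictive"))
  cs <- criteria_set("restrictive")
  expect_setequal(unique(pt$factor), cs$name)
  for (i in seq_len(nrow(cs))) {
    expect_setequal(unique(pt$stratum[pt$factor == cs$name[i]]),
                    cs$age_scope[[i]])
  }
  expect_true(all(pt$value >= 0 & pt$value <= 1))

  # wholesale factors carry prevalence 1 on their scope
  expect_true(all(pt$value[pt$factor %in% c("age_lt10", "age_ge75")] == 1))

  # survey cells agree with the reference per-domain estimator
  st <- as.character(age_to_stratum(w$survey$age))
  rg <- w$regions$region_id[1]
  dom <- st == "45-64" & w$survey$region_id == rg
  expect_equal(prevalence_lookup(pt, rg, "45-64", "chronic_disease"),
               chronic_disease_prevalence(w$survey, dom))

  # an unresolvable supplied factor names the missing cells
  inc <- criteria_set("inclusive")
  supplied_broken <- w$supplied[w$supplied$factor != "low_vitc", ]
  expect_error(build_prevalence_table(w$survey, supplied_broken,
                                      w$pregnancy_inputs, w$regions, inc),
               "unresolvable.*low_vitc")
})

test_that("fully urban regions take the national urban outdoor-work value", {
  cfg <- tiny_config(urban_fraction_range = c(1, 1))
  w <- simulate_world(cfg)
  pt <- build_prevalence_table(w$survey, w$supplied, w$pregnancy_inputs,
                               w$regions, criteria_set("inclusive"))
  urb <- w$supplied[w$supplied$factor == "outdoor_work" &
                      w$supplied$urbanicity %in% "urban", ]
  for (st in c("16-19", "45-64")) {
    expect_equal(prevalence_lookup(pt, "R001", st, "outdoor_work"),
                 urb$value[urb$stratum == st])
  }
})

test_that("a large synthetic region recovers its true prevalences", {
  cfg <- generator_config(n_regions = 4, n_respondents_per_region = 20000,
                          seed = 5)
  w <- simulate_world(cfg)
  pt <- build_prevalence_table(w$survey, w$supplied, w$pregnancy_inputs,
                               w$regions, criteria_set("inclusive"))
  truth <- w$truth$prevalence
  for (rg in unique(w$regions$region_id)) {
    for (st in c("25-34", "45-64", "65-74")) {
      expect_equal(prevalence_lookup(pt, rg, st, "chronic_disease"),
                   prevalence_lookup(truth, rg, st, "chronic_disease"),
                   tolerance = 0.15)  # relative; ~3 MC SEs at these n
      expect_equal(prevalence_lookup(pt, rg, st, "less_than_hs"),
                   prevalence_lookup(truth, rg, st, "less_than_hs"),
                   tolerance = 0.25)
    }
    # derived factors are exact given the region table
    expect_equal(prevalence_lookup(pt, rg, "25-34", "pregnancy"),
                 prevalence_lookup(truth, rg, "25-34", "pregnancy"),
                 tolerance = 1e-10)
    expect_equal(prevalence_lookup(pt, rg, "45-64", "outdoor_work"),
                 prevalence_lookup(truth, rg, "45-64", "outdoor_work"),
                 tolerance = 1e-10)
  }
})
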