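test_that("generator configs are validated", {
  expect_error(generator_config(n_regions = 3), ">= 4")
  expect_error(generator_config(region_heterogeneity = 0), "> 0")
  expect_error(generator_config(region_heterogeneity = -2), "> 0")
  expect_error(generator_config(weight_dispersion = -0.1), ">= 0")
  expect_error(generator_config(urban_fraction_range = c(0.5, 1.4)),
               "within \\[0,1\\]")
  shares <- generator_config()$national_age_shares
  shares[1] <- shares[1] + 0.05
  expect_error(generator_config(national_age_shares = shares), "sum to 1")
  expect_error(generator_config(cells_per_region = 0), ">= 1")
})

test_that("identical seed and config give identical worlds", {
  w1 <- simulate_world(tiny_config(seed = 77))
  w2 <- simulate_world(tiny_config(seed = 77))
  expect_identical(w1$regions, w2$regions)
  expect_identical(w1$survey, w2$survey)
  expect_identical(w1$surface, w2$surface)
  expect_identical(w1$truth, w2$truth)
  w3 <- simulate_world(tiny_config(seed = 78))
  expect_false(identical(w1$survey, w3$survey))
})

test_that("infinite heterogeneity reproduces the national age shares in every region", {
  cfg <- tiny_config(region_heterogeneity = Inf)
  gen <- generate_regions(cfg)
  for (rg in unique(gen$regions$region_id)) {
    sub <- gen$regions[gen$regions$region_id == rg, ]
    expect_equal(setNames(sub$population / sum(sub$population), sub$stratum),
                 cfg$national_age_shares, tolerance = 1e-3)  # rounding only
  }
})

test_that("the urbanicity-PM2.5 gradient is present by default and absent at zero", {
  # built-in gradient: strong positive rank correlation at the full scale
  hits <- 0
  for (s in 1:100) {
    cfg <- generator_config(seed = 1000 + s)
    gen <- generate_regions(cfg)
    rho <- spearman_rho(gen$region_means$urban_fraction,
                        gen$region_means$pm25)$rho
    hits <- hits + (rho > 0.5)
  }
  expect_gte(hits / 100, 0.95)

  # zero gradient: rho centred on 0 across seeds
  rhos <- vapply(1:40, function(s) {
    cfg <- generator_config(n_regions = 60, seed = 2000 + s,
                            pollutant_params = list(
                              pm25 = list(baseline = 5, urban_gradient = 0,
                                          region_sd = 1, spatial_sd = 0.3,
                                          interannual_sd = 0.4),
                              o3 = list(baseline = 28, urban_gradient = 0,
                                        region_sd = 4, spatial_sd = 0.8,
                                        interannual_sd = 1.2)))
    gen <- generate_regions(cfg)
    spearman_rho(gen$region_means$urban_fraction, gen$region_means$pm25)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("sampling weights behave as inverse inclusion probabilities", {
  # uniform tilt + zero dispersion: every weight in a region is equal
  cfg <- tiny_config(weight_dispersion = 0,
                     sampling_tilt = list(age = setNames(rep(1, 10),
                                                         age_stratum_labels()),
                                          rural = 1))
  w <- simulate_world(cfg)
  for (rg in unique(w$survey$region_id)) {
    expect_equal(var(w$survey$weight[w$survey$region_id == rg]), 0)
  }

  # tilted sampling: weights differ, but their sum recovers the region
  # population in expectation
  cfg2 <- generator_config(n_regions = 4, n_respondents_per_region = 20000,
                           seed = 3, weight_dispersion = 0)
  w2 <- simulate_world(cfg2)
  for (rg in unique(w2$survey$region_id)) {
    pop <- sum(w2$regions$population[w2$regions$region_id == rg])
    expect_equal(sum(w2$survey$weight[w2$survey$region_id == rg]), pop,
                 tolerance = 0.05)
    expect_gt(var(w2$survey$weight[w2$survey$region_id == rg]), 0)
  }
})

test_that("zero true prevalence yields all-zero indicators", {
  pp <- generator_config()$prevalence_params
  pp$chronic_disease[] <- 0
  cfg <- tiny_config(prevalence_params = pp, missing_rate = 0)
  w <- simulate_world(cfg)
  m <- as.matrix(w$survey[c("asthma", "copd", "heart_disease", "diabetes")])
  expect_true(all(m == 0))
})

test_that("weighted estimates cover the truth at survey scale", {
  # one large region: estimate within 3 SEs of the regional truth
  inside <- 0
  for (s in 1:60) {
    cfg <- generator_config(n_regions = 4, n_respondents_per_region = 20000,
                            seed = 5000 + s)
    gen <- generate_regions(cfg)
    sv <- generate_survey(gen, cfg)
    sv <- sv[sv$region_id == "R001", ]
    st <- as.character(age_to_stratum(sv$age))
    dom <- st == "45-64"
    est <- chronic_disease_prevalence(sv, dom)
    truth <- prevalence_lookup(gen$truth_prevalence, "R001", "45-64",
                               "chronic_disease")
    # linearization SE of the weighted ratio estimator
    m <- as.matrix(sv[c("asthma", "copd", "heart_disease", "diabetes")])
    x <- ifelse(rowSums(is.na(m)) > 0, NA_real_, as.numeric(rowSums(m) > 0))
    ok <- dom & !is.na(x)
    wgt <- sv$weight[ok]
    se <- sqrt(sum(wgt^2 * (x[ok] - est)^2)) / sum(wgt)
    inside <- inside + (abs(est - truth) <= 3 * se)
  }
  expect_gte(inside / 60, 0.95)
})

test_that("weighted prevalence error shrinks with sample size", {
  err_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- generator_config(n_regions = 4, n_respondents_per_region = n,
                              seed = 6000 + s)
      gen <- generate_regions(cfg)
      sv <- generate_survey(gen, cfg)
      sv <- sv[sv$region_id == "R002", ]
      st <- as.character(age_to_stratum(sv$age))
      est <- chronic_disease_prevalence(sv, st == "45-64")
      truth <- prevalence_lookup(gen$truth_prevalence, "R002", "45-64",
                                 "chronic_disease")
      abs(est - truth)
    }, numeric(1)))
  }
  e_small <- err_at(400, 1:12)
  e_big <- err_at(6400, 1:12)
  expect_lt(e_big, e_small)       # consistency
  expect_gt(e_small / e_big, 1.5) # roughly 1/sqrt(n) scaling (x4 ideal)
})

test_that("the synthetic truth is self-consistent with the cascade", {
  w <- simulate_world(tiny_config(seed = 12))
  redo_r <- region_cascades(w$regions, w$truth$prevalence, "restrictive")
  redo_i <- region_cascades(w$regions, w$truth$prevalence, "inclusive")
  expect_equal(w$truth$totals$restrictive,
               redo_r$total_percent[match(w$truth$totals$region_id,
                                          redo_r$region_id)])
  expect_equal(w$truth$totals$inclusive,
               redo_i$total_percent[match(w$truth$totals$region_id,
                                          redo_i$region_id)])
  # and the pregnancy event tables reproduce the configured truth exactly
  preg <- pregnancy_point_prevalence(w$pregnancy_inputs)
  implied <- effective_pregnancy_prevalence(preg["25-34"],
                                            w$config$female_fraction["25-34"])
  expect_equal(unname(implied),
               prevalence_lookup(w$truth$prevalence, "R001", "25-34",
                                 "pregnancy"))
})

test_that("surfaces cover every region with non-negative concentrations", {
  w <- simulate_world(tiny_config())
  regs <- unique(w$regions$region_id)
  for (pol in c("pm25", "o3")) {
    sub <- w$surface[w$surface$pollutant == pol, ]
    expect_setequal(unique(sub$region_id), regs)
    expect_true(all(sub$concentration >= 0))
    expect_true(all(table(sub$region_id, sub$year) ==
                      w$config$cells_per_region))
  }
})

test_that("worlds round-trip through the CSV dialects", {
  w <- simulate_world(tiny_config(seed = 4))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_equal(read_regions_csv(file.path(dir, "regions.csv")), w$regions,
               tolerance = 1e-12)
  sv <- read_survey_csv(file.path(dir, "survey.csv"))
  expect_equal(sv$weight, w$survey$weight, tolerance = 1e-12)
  expect_identical(sv$less_than_hs, w$survey$less_than_hs)
  tr <- read_prevalence_csv(file.path(dir, "truth.csv"))
  expect_equal(tr$value, w$truth$prevalence$value, tolerance = 1e-12)
  sf <- read_surface_csv(file.path(dir, "surface.csv"))
  expect_equal(sf$concentration, w$surface$concentration, tolerance = 1e-12)
  pg <- read_pregnancy_csv(file.path(dir, "pregnancy_inputs.csv"))
  expect_equal(pg$live_births, w$pregnancy_inputs$live_births,
               tolerance = 1e-12)
})
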