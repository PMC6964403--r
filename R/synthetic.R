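#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every knob of the synthetic world: regional
#' demography, true factor prevalences, survey design, and pollutant-surface
#' parameters. Defaults emulate the study conditions of the national
#' analysis this package implements: 110 health regions, roughly 1,100
#' shared-file respondents per region, a national age structure and factor
#' prevalences whose cascade lands near one third of the population under
#' restrictive criteria and two thirds under inclusive criteria, and a
#' built-in positive urbanicity gradient on PM2.5 (regions with more urban
#' population see higher fine-particle concentrations) with no such gradient
#' for ozone.
#'
#' @param n_regions Number of regions (`>= 4` so quartiles exist).
#' @param n_respondents_per_region Survey respondents drawn per region.
#' @param seed Global seed; each generation stage derives a child seed from
#'   it by a fixed offset, so stages are individually reproducible.
#' @param national_age_shares Named fractions over the ten canonical strata,
#'   summing to 1.
#' @param female_fraction Named female share per stratum.
#' @param prevalence_params True national prevalences: list with elements
#'   `chronic_disease`, `less_than_hs`, `low_vitc` (named per-stratum
#'   vectors), `outdoor_work_urban`, `outdoor_work_rural` (named per-stratum
#'   vectors), `birth_rate` (annual live births per female per stratum),
#'   `fetal_loss_ratio`, `abortion_ratio` (events per live birth).
#' @param region_heterogeneity Dirichlet concentration for perturbing the
#'   national age shares per region (`> 0`; larger = more homogeneous;
#'   `Inf` = every region gets the national shares exactly).
#' @param prevalence_heterogeneity Logit-scale s.d. of regional perturbation
#'   of the survey-resolvable prevalences (chronic disease, education);
#'   `0` = all regions share the national truth.
#' @param weight_dispersion Coefficient of variation of the multiplicative
#'   (mean-1 lognormal) noise on sampling weights; `0` = deterministic
#'   inverse-inclusion-probability weights.
#' @param sampling_tilt List with `age` (named per-stratum over/under-
#'   sampling factors) and `rural` (extra factor for rural respondents).
#'   The default oversamples the elderly and rural residents so that
#'   weighted and unweighted estimates genuinely differ; with a uniform
#'   tilt and zero dispersion all weights in a region are equal.
#' @param urban_fraction_range Interval the regional urban population
#'   fractions are drawn uniformly from.
#' @param pollutant_params Per-pollutant list (`pm25` in ug/m3, `o3` in ppb)
#'   of `baseline`, `urban_gradient` (added concentration per unit urban
#'   fraction), `region_sd` (regional spread unrelated to urbanicity),
#'   `spatial_sd` (cell-level, fixed in time), `interannual_sd` (regional,
#'   per year).
#' @param n_years Number of years on the surface, ending at `last_year`.
#' @param last_year Final surface year.
#' @param cells_per_region Grid cells per region (`>= 1`).
#' @param missing_rate Independent missingness probability per survey
#'   indicator.
#' @param region_population_meanlog,region_population_sdlog Lognormal
#'   parameters for regional population sizes.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_regions = 110L,
    n_respondents_per_region = 1100L,
    seed = 1L,
    national_age_shares = c("<10" = 0.108, "10-14" = 0.054, "15" = 0.011,
                            "16-19" = 0.048, "20-24" = 0.067, "25-34" = 0.135,
                            "35-44" = 0.131, "45-64" = 0.289, "65-74" = 0.092,
                            "75+" = 0.065),
    female_fraction = c("<10" = 0.49, "10-14" = 0.49, "15" = 0.49,
                        "16-19" = 0.49, "20-24" = 0.49, "25-34" = 0.50,
                        "35-44" = 0.50, "45-64" = 0.50, "65-74" = 0.52,
                        "75+" = 0.60),
    prevalence_params = list(
      chronic_disease = c("10-14" = 0.11, "15" = 0.11, "16-19" = 0.11,
                          "20-24" = 0.10, "25-34" = 0.11, "35-44" = 0.13,
                          "45-64" = 0.22, "65-74" = 0.38),
      less_than_hs = c("20-24" = 0.10, "25-34" = 0.08, "35-44" = 0.08,
                       "45-64" = 0.12, "65-74" = 0.21, "75+" = 0.30),
      low_vitc = c("10-14" = 0.10, "15" = 0.10, "16-19" = 0.12,
                   "20-24" = 0.14, "25-34" = 0.13, "35-44" = 0.12,
                   "45-64" = 0.12, "65-74" = 0.12, "75+" = 0.12),
      outdoor_work_urban = c("16-19" = 0.31, "20-24" = 0.31, "25-34" = 0.22,
                             "35-44" = 0.22, "45-64" = 0.22, "65-74" = 0.22),
      outdoor_work_rural = c("16-19" = 0.43, "20-24" = 0.43, "25-34" = 0.31,
                             "35-44" = 0.31, "45-64" = 0.31, "65-74" = 0.31),
      birth_rate = c("15" = 0.012, "16-19" = 0.024, "20-24" = 0.050,
                     "25-34" = 0.0825, "35-44" = 0.030, "45-64" = 0.0012),
      fetal_loss_ratio = 0.15,
      abortion_ratio = 0.25),
    region_heterogeneity = 150,
    prevalence_heterogeneity = 0.2,
    weight_dispersion = 0.5,
    sampling_tilt = list(age = c("<10" = 0.8, "10-14" = 0.8, "15" = 0.8,
                                 "16-19" = 0.9, "20-24" = 0.9, "25-34" = 1.0,
                                 "35-44" = 1.0, "45-64" = 1.1, "65-74" = 1.5,
                                 "75+" = 1.5),
                         rural = 1.3),
    urban_fraction_range = c(0.1, 1.0),
    pollutant_params = list(
      pm25 = list(baseline = 5.0, urban_gradient = 3.5, region_sd = 1.0,
                  spatial_sd = 0.3, interannual_sd = 0.4),
      o3 = list(baseline = 28, urban_gradient = 0, region_sd = 4.0,
                spatial_sd = 0.8, interannual_sd = 1.2)),
    n_years = 3L,
    last_year = 2012L,
    cells_per_region = 4L,
    missing_rate = 0.02,
    region_population_meanlog = log(160000),
    region_population_sdlog = 1.0) {
  labs <- age_stratum_labels()
  cfg <- as.list(environment())
  if (cfg$n_regions < 4L) stop("n_regions must be >= 4 (quartiles)",
                               call. = FALSE)
  if (!setequal(names(national_age_shares), labs)) {
    stop("national_age_shares must be named by the ten canonical strata",
         call. = FALSE)
  }
  cfg$national_age_shares <- national_age_shares[labs]
  if (abs(sum(cfg$national_age_shares) - 1) > 1e-9) {
    stop("national_age_shares must sum to 1", call. = FALSE)
  }
  cfg$female_fraction <- female_fraction[labs]
  prevs <- unlist(prevalence_params[c("chronic_disease", "less_than_hs",
                                      "low_vitc", "outdoor_work_urban",
                                      "outdoor_work_rural")])
  if (any(prevs < 0 | prevs > 1)) {
    stop("all configured prevalences must lie in [0,1]", call. = FALSE)
  }
  if (!is.infinite(region_heterogeneity) && region_heterogeneity <= 0) {
    stop("region_heterogeneity must be > 0", call. = FALSE)
  }
  if (weight_dispersion < 0) stop("weight_dispersion must be >= 0",
                                  call. = FALSE)
  if (prevalence_heterogeneity < 0) {
    stop("prevalence_heterogeneity must be >= 0", call. = FALSE)
  }
  if (n_years < 1L) stop("n_years must be >= 1", call. = FALSE)
  if (cells_per_region < 1L) stop("cells_per_region must be >= 1",
                                  call. = FALSE)
  if (length(urban_fraction_range) != 2L ||
      any(urban_fraction_range < 0 | urban_fraction_range > 1) ||
      diff(urban_fraction_range) < 0) {
    stop("urban_fraction_range must be an interval within [0,1]",
         call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

# fixed stage offsets of the global seed (stage-level reproducibility)
.stage_seed <- function(cfg, stage) {
  offset <- c(regions = 101L, survey = 202L, surface = 303L)[[stage]]
  (as.integer(cfg$seed) + offset) %% .Machine$integer.max
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# logit-normal regional perturbation of a prevalence, degenerate sd -> p
.perturb_prev <- function(p, sd, n) {
  if (sd == 0 || p <= 0 || p >= 1) return(rep(p, n))
  .inv_logit(stats::rnorm(n, .logit(p), sd))
}

#' Generate synthetic regions
#'
#' Draws regional populations (lognormal sizes), age structures (Dirichlet
#' perturbations of the national shares), urban fractions (uniform over the
#' configured interval), regional true prevalences (logit-normal
#' perturbations of the national values for the survey-resolvable factors),
#' and regional mean pollutant concentrations. PM2.5 means increase with
#' urban fraction through the configured gradient, building in a positive
#' urbanicity-PM2.5 rank correlation; O3 means carry no urbanicity
#' gradient.
#'
#' @param config A [generator_config()].
#' @return List with `regions` (one row per region x stratum: `region_id`,
#'   `stratum`, `population`, `female_fraction`, `urban_fraction`),
#'   `region_means` (per-region true mean concentration per pollutant), and
#'   `truth_prevalence` (a [prevalence_table()] of true effective
#'   prevalences, region-scoped).
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.stage_seed(config, "regions"))
  labs <- age_stratum_labels()
  R <- config$n_regions
  rid <- sprintf("R%03d", seq_len(R))
  pop_total <- round(stats::rlnorm(R, config$region_population_meanlog,
                                   config$region_population_sdlog))
  shares <- if (is.infinite(config$region_heterogeneity)) {
    matrix(config$national_age_shares, nrow = R, ncol = 10L, byrow = TRUE)
  } else {
    alpha <- config$region_heterogeneity * config$national_age_shares
    g <- matrix(stats::rgamma(R * 10L, shape = rep(alpha, each = R)),
                nrow = R)
    g / rowSums(g)
  }
  colnames(shares) <- labs
  urban <- stats::runif(R, config$urban_fraction_range[1],
                        config$urban_fraction_range[2])
  regions <- data.frame(
    region_id = rep(rid, each = 10L),
    stratum = rep(labs, times = R),
    population = pmax(1, round(as.vector(t(shares * pop_total)))),
    female_fraction = rep(unname(config$female_fraction), times = R),
    urban_fraction = rep(urban, each = 10L),
    stringsAsFactors = FALSE)

  pol <- lapply(config$pollutant_params, function(pp) {
    pmax(0.1, pp$baseline + pp$urban_gradient * urban +
           stats::rnorm(R, 0, pp$region_sd))
  })
  region_means <- data.frame(region_id = rid, urban_fraction = urban,
                             pm25 = pol$pm25, o3 = pol$o3,
                             stringsAsFactors = FALSE)

  # regional truth for survey-resolvable factors (logit-normal perturbation)
  pp <- config$prevalence_params
  truth <- list()
  for (fct in c("chronic_disease", "less_than_hs")) {
    for (st in names(pp[[fct]])) {
      truth[[paste(fct, st)]] <- data.frame(
        scope = rid, stratum = st, factor = fct, urbanicity = NA_character_,
        value = .perturb_prev(pp[[fct]][[st]],
                              config$prevalence_heterogeneity, R),
        provenance = "truth", stringsAsFactors = FALSE)
    }
  }
  # outdoor work truth: national urban/rural values mixed by urban fraction
  for (st in names(pp$outdoor_work_urban)) {
    truth[[paste("ow", st)]] <- data.frame(
      scope = rid, stratum = st, factor = "outdoor_work",
      urbanicity = NA_character_,
      value = urbanicity_adjusted_prevalence(pp$outdoor_work_urban[[st]],
                                             pp$outdoor_work_rural[[st]],
                                             urban),
      provenance = "truth", stringsAsFactors = FALSE)
  }
  # vitamin C truth: national, no regional variation
  truth[["vitc"]] <- data.frame(
    scope = "NATIONAL", stratum = names(pp$low_vitc), factor = "low_vitc",
    urbanicity = NA_character_, value = unname(pp$low_vitc),
    provenance = "truth", stringsAsFactors = FALSE)
  # pregnancy truth: national among-female point prevalence from the
  # configured rates, applied to each stratum's female fraction
  preg_f <- .true_pregnancy_among_females(config)
  for (st in names(preg_f)) {
    if (preg_f[[st]] == 0) next
    truth[[paste("preg", st)]] <- data.frame(
      scope = rid, stratum = st, factor = "pregnancy",
      urbanicity = NA_character_,
      value = preg_f[[st]] * config$female_fraction[[st]],
      provenance = "truth", stringsAsFactors = FALSE)
  }
  list(regions = regions, region_means = region_means,
       truth_prevalence = prevalence_table(do.call(rbind, truth)))
}

# among-female pregnancy point prevalence implied by the configured annual
# rates and default gestational durations (same formula the estimator uses)
.true_pregnancy_among_females <- function(config) {
  pp <- config$prevalence_params
  br <- pp$birth_rate
  out <- setNames(numeric(10L), age_stratum_labels())
  out[names(br)] <- br * (40 / 52) + br * pp$fetal_loss_ratio * (11 / 52) +
    br * pp$abortion_ratio * (10 / 52)
  out
}

#' Generate national pregnancy event tables
#'
#' Converts the configured annual birth rates into national annual counts of
#' live births, fetal losses, and induced abortions per stratum, using the
#' generated regional female populations as the denominator, so that the
#' pregnancy estimator applied to these tables recovers the generator's
#' true among-female prevalence exactly.
#'
#' @param world_regions The `regions` data frame from [generate_regions()].
#' @param config A [generator_config()].
#' @return Data frame in the pregnancy-inputs dialect (`stratum`,
#'   `live_births`, `fetal_losses`, `induced_abortions`,
#'   `female_population`).
#' @export
generate_pregnancy_inputs <- function(world_regions, config) {
  pp <- config$prevalence_params
  fpop <- tapply(world_regions$population * world_regions$female_fraction,
                 world_regions$stratum, sum)
  strata <- names(pp$birth_rate)
  births <- pp$birth_rate * fpop[strata]
  data.frame(stratum = strata,
             live_births = unname(births),
             fetal_losses = unname(births * pp$fetal_loss_ratio),
             induced_abortions = unname(births * pp$abortion_ratio),
             female_population = unname(fpop[strata]),
             stringsAsFactors = FALSE)
}

#' Generate the supplied national prevalence tables
#'
#' Emits the tables the pipeline expects for factors not estimable from the
#' survey: outdoor work by stratum and urbanicity, and low vitamin C intake
#' by stratum.
#'
#' @param config A [generator_config()].
#' @return A [prevalence_table()] of national supplied rows.
#' @export
generate_supplied_tables <- function(config) {
  pp <- config$prevalence_params
  ow_u <- data.frame(scope = "NATIONAL", stratum = names(pp$outdoor_work_urban),
                     factor = "outdoor_work", urbanicity = "urban",
                     value = unname(pp$outdoor_work_urban),
                     provenance = "supplied", stringsAsFactors = FALSE)
  ow_r <- data.frame(scope = "NATIONAL", stratum = names(pp$outdoor_work_rural),
                     factor = "outdoor_work", urbanicity = "rural",
                     value = unname(pp$outdoor_work_rural),
                     provenance = "supplied", stringsAsFactors = FALSE)
  vc <- data.frame(scope = "NATIONAL", stratum = names(pp$low_vitc),
                   factor = "low_vitc", urbanicity = NA_character_,
                   value = unname(pp$low_vitc),
                   provenance = "supplied", stringsAsFactors = FALSE)
  prevalence_table(rbind(ow_u, ow_r, vc))
}

#' Generate survey microdata
#'
#' Draws respondents per region under age-by-urbanicity stratified sampling
#' with the configured tilt. Each respondent gets an age (uniform within the
#' sampled stratum), sex, urbanicity, binary indicators drawn Bernoulli from
#' the region's true prevalences (the four chronic conditions are drawn
#' independently with per-condition probabilities whose union equals the
#' true chronic prevalence), and a sampling weight equal to the inverse
#' inclusion probability times mean-1 lognormal noise with the configured
#' coefficient of variation -- so weighted age/urbanicity margins match the
#' region's population margins in expectation.
#'
#' @param world Output of [generate_regions()].
#' @param config A [generator_config()].
#' @return Data frame of survey records in the microdata CSV dialect.
#' @export
generate_survey <- function(world, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.stage_seed(config, "survey"))
  labs <- age_stratum_labels()
  regions <- world$regions
  truth <- world$truth_prevalence
  n <- config$n_respondents_per_region
  tilt_age <- config$sampling_tilt$age[labs]
  tilt_rural <- config$sampling_tilt$rural
  sdlog <- sqrt(log(1 + config$weight_dispersion^2))
  lo <- .stratum_lo; hi <- pmin(.stratum_hi, 96)

  per_region <- lapply(unique(regions$region_id), function(rg) {
    sub <- regions[regions$region_id == rg, ]
    sub <- sub[match(labs, sub$stratum), ]
    urb_frac <- sub$urban_fraction[1]
    share <- sub$population / sum(sub$population)
    # 20 sampling cells: stratum x {urban, rural}
    cell_share <- c(share * urb_frac, share * (1 - urb_frac))
    cell_tilt <- c(tilt_age, tilt_age * tilt_rural)
    prob <- cell_share * cell_tilt
    if (sum(prob) == 0) stop("region ", rg, " has empty sampling frame",
                             call. = FALSE)
    prob <- prob / sum(prob)
    cell <- sample.int(20L, n, replace = TRUE, prob = prob)
    a <- ifelse(cell > 10L, cell - 10L, cell)     # stratum index
    rural <- cell > 10L
    age <- floor(stats::runif(n, lo[a], hi[a]))
    female <- stats::rbinom(n, 1L, sub$female_fraction[a]) == 1L
    # inverse inclusion probability: N * sum(share*tilt) / (n * tilt_cell)
    w <- sum(sub$population) * sum(cell_share * cell_tilt) /
      (n * cell_tilt[cell])
    if (config$weight_dispersion > 0) {
      w <- w * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    }
    # chronic conditions: union across four independent conditions matches
    # the true union prevalence; out-of-scope strata have no condition
    p_union_st <- vapply(labs, function(st)
      .truth_value(truth, rg, st, "chronic_disease"), numeric(1))
    p_cond <- 1 - (1 - p_union_st[a])^(1 / 4)
    dis <- matrix(stats::rbinom(4L * n, 1L, rep(p_cond, 4L)), ncol = 4L)
    # education indicator is undefined (missing) outside its age scope
    p_edu_st <- vapply(labs, function(st)
      prevalence_lookup(truth, rg, st, "less_than_hs"), numeric(1))
    p_edu <- p_edu_st[a]
    edu <- stats::rbinom(n, 1L, ifelse(is.na(p_edu), 0, p_edu))
    edu[is.na(p_edu)] <- NA_integer_
    data.frame(region_id = rg, age = age,
               sex = ifelse(female, "female", "male"),
               urbanicity = ifelse(rural, "rural", "urban"),
               weight = w,
               asthma = dis[, 1], copd = dis[, 2], heart_disease = dis[, 3],
               diabetes = dis[, 4], less_than_hs = edu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_region)
  rownames(out) <- NULL
  if (config$missing_rate > 0) {
    for (col in c("asthma", "copd", "heart_disease", "diabetes",
                  "less_than_hs")) {
      drop <- stats::runif(nrow(out)) < config$missing_rate
      out[[col]][drop] <- NA_integer_
    }
  }
  out
}

# truth lookup returning 0 for out-of-scope cells (indicator simply absent)
.truth_value <- function(truth, region, stratum, fct) {
  v <- prevalence_lookup(truth, region, stratum, fct)
  if (is.na(v)) 0 else v
}

#' Generate a gridded pollutant surface
#'
#' Each region owns a fixed number of grid cells. A cell's annual value is
#' the region's true mean concentration plus a time-invariant cell-level
#' spatial offset plus a regional inter-annual deviation, truncated at zero
#' (concentrations cannot be negative).
#'
#' @param world Output of [generate_regions()].
#' @param config A [generator_config()]; the surface covers
#'   `config$n_years` years ending at `config$last_year`.
#' @return Data frame in the surface CSV dialect: `cell_id`, `region_id`,
#'   `pollutant`, `year`, `concentration`.
#' @export
generate_pollutant_surface <- function(world, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.stage_seed(config, "surface"))
  rm <- world$region_means
  R <- nrow(rm)
  C <- config$cells_per_region
  if (C < 1L) stop("every region must own at least one grid cell",
                   call. = FALSE)
  years <- seq(config$last_year - config$n_years + 1L, config$last_year)
  Y <- length(years)
  parts <- lapply(c("pm25", "o3"), function(pol) {
    pp <- config$pollutant_params[[pol]]
    mu <- rm[[pol]]
    spatial <- stats::rnorm(R * C, 0, pp$spatial_sd)            # per cell
    annual <- stats::rnorm(R * Y, 0, pp$interannual_sd)         # region-year
    cell_idx <- rep(seq_len(R * C), times = Y)
    year_idx <- rep(seq_len(Y), each = R * C)
    reg_idx <- ((cell_idx - 1L) %/% C) + 1L
    conc <- pmax(0, mu[reg_idx] + spatial[cell_idx] +
                   annual[(year_idx - 1L) * R + reg_idx])
    data.frame(cell_id = sprintf("%s_c%04d", pol, cell_idx),
               region_id = rm$region_id[reg_idx],
               pollutant = pol, year = years[year_idx],
               concentration = conc, stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Simulate a complete synthetic world
#'
#' Orchestrates the full generator: regions, true prevalences, survey
#' microdata, supplied national tables, pregnancy event tables, and the
#' pollutant surface, plus the self-consistent truth -- true regional
#' susceptibility percents obtained by running the cascade on the true
#' prevalences. Identical seed and config give byte-identical output.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_world`: `config`, `regions`,
#'   `region_means`, `survey`, `supplied`, `pregnancy_inputs`, `surface`,
#'   and `truth` (`prevalence` table plus `totals`, the per-region
#'   restrictive/inclusive percents implied by the true prevalences).
#' @export
simulate_world <- function(config = generator_config()) {
  gen <- generate_regions(config)
  survey <- generate_survey(gen, config)
  supplied <- generate_supplied_tables(config)
  preg <- generate_pregnancy_inputs(gen$regions, config)
  surface <- generate_pollutant_surface(gen, config)
  totals <- data.frame(
    region_id = unique(gen$regions$region_id),
    restrictive = region_cascades(gen$regions, gen$truth_prevalence,
                                  "restrictive")$total_percent,
    inclusive = region_cascades(gen$regions, gen$truth_prevalence,
                                "inclusive")$total_percent,
    stringsAsFactors = FALSE)
  structure(list(config = config, regions = gen$regions,
                 region_means = gen$region_means, survey = survey,
                 supplied = supplied, pregnancy_inputs = preg,
                 surface = surface,
                 truth = list(prevalence = gen$truth_prevalence,
                              totals = totals)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("Synthetic world: %d regions, %s respondents, ",
                     "%d surface years (seed %d)\n"),
              x$config$n_regions,
              format(nrow(x$survey), big.mark = ","),
              x$config$n_years, x$config$seed))
  cat(sprintf("  true national restrictive / inclusive percent: %.1f / %.1f\n",
              aggregate_regions(x$truth$totals$restrictive,
                                tapply(x$regions$population,
                                       x$regions$region_id, sum)[
                                         x$truth$totals$region_id]),
              aggregate_regions(x$truth$totals$inclusive,
                                tapply(x$regions$population,
                                       x$regions$region_id, sum)[
                                         x$truth$totals$region_id])))
  invisible(x)
}
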