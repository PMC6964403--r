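#' Survey-weighted prevalence
#'
#' Point estimate of a binary indicator's prevalence from weighted survey
#' microdata: `sum(w * x) / sum(w)` over respondents in the domain with a
#' non-missing indicator. Respondents with a missing indicator are dropped
#' from both numerator and denominator (complete-case per indicator). The
#' estimate is invariant to rescaling all weights by a positive constant.
#'
#' @param records Survey microdata: a data frame with a positive `weight`
#'   column and the indicator column, coded 0/1 with `NA` for missing.
#' @param indicator Name of the indicator column.
#' @param domain Optional logical vector (recycled against `records`)
#'   selecting the estimation domain, or a function of the data frame
#'   returning one. Default: all records.
#' @return Prevalence in `[0, 1]`.
#' @examples
#' d <- data.frame(weight = c(1, 3), flag = c(1, 0))
#' weighted_prevalence(d, "flag")  # 0.25
#' @export
weighted_prevalence <- function(records, indicator, domain = NULL) {
  if (!indicator %in% names(records)) {
    stop("indicator column '", indicator, "' not found", call. = FALSE)
  }
  keep <- if (is.null(domain)) rep(TRUE, nrow(records))
          else if (is.function(domain)) domain(records)
          else rep_len(as.logical(domain), nrow(records))
  x <- records[[indicator]][keep]
  w <- records$weight[keep]
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  if (!length(x)) stop("no respondents in domain with a non-missing '",
                       indicator, "'", call. = FALSE)
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("indicator must be binary 0/1", call. = FALSE)
  sum(w * x) / sum(w)
}

#' Chronic-disease (union) prevalence
#'
#' Prevalence of having any of asthma, COPD, heart disease, or diabetes.
#' The union is formed per respondent before weighting, so a respondent with
#' several conditions counts once -- this is what accounts for comorbidity
#' rather than summing the four single-condition prevalences. Respondents
#' missing any of the four indicators are excluded from the estimate.
#'
#' @param records Survey microdata with columns `asthma`, `copd`,
#'   `heart_disease`, `diabetes` (each 0/1/NA) and `weight`.
#' @param domain As in [weighted_prevalence()].
#' @return Prevalence of the union indicator in `[0, 1]`.
#' @export
chronic_disease_prevalence <- function(records, domain = NULL) {
  comp <- c("asthma", "copd", "heart_disease", "diabetes")
  miss <- setdiff(comp, names(records))
  if (length(miss)) stop("missing indicator columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(records[comp])
  records$chronic_disease <- ifelse(rowSums(is.na(m)) > 0, NA_real_,
                                    as.numeric(rowSums(m) > 0))
  weighted_prevalence(records, "chronic_disease", domain)
}

#' Pregnancy point prevalence among females
#'
#' Expected proportion of women pregnant at any given time, per age stratum:
#' each annual outcome count (live births, fetal losses, induced abortions)
#' contributes `count * gestation_duration_in_years` woman-years of
#' concurrent pregnancy, and the sum is divided by the stratum's female
#' population. Linear in every count and every duration.
#'
#' Default gestational durations (40/52, 11/52, and 10/52 years for live
#' births, fetal losses, and induced abortions) follow the emergency-
#' preparedness worksheet convention; they are arguments, not constants.
#'
#' @param inputs Data frame with columns `stratum`, `live_births`,
#'   `fetal_losses`, `induced_abortions`, `female_population` (annual counts,
#'   `>= 0`).
#' @param durations Named list of gestational durations in years, elements
#'   `birth`, `loss`, `abortion`, each in `(0, 1]`.
#' @return Named numeric vector over all ten canonical strata: prevalence
#'   among females, 0 for strata absent from `inputs`.
#' @examples
#' x <- data.frame(stratum = "25-34", live_births = 1000, fetal_losses = 0,
#'                 induced_abortions = 0, female_population = 1e5)
#' pregnancy_point_prevalence(x, durations = list(birth = 0.75, loss = 11/52,
#'                                                abortion = 10/52))
#' @export
pregnancy_point_prevalence <- function(inputs,
                                       durations = list(birth = 40 / 52,
                                                        loss = 11 / 52,
                                                        abortion = 10 / 52)) {
  need <- c("stratum", "live_births", "fetal_losses", "induced_abortions",
            "female_population")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("pregnancy inputs missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- unlist(durations[c("birth", "loss", "abortion")])
  if (any(d <= 0 | d > 1)) stop("gestation durations must lie in (0, 1] years",
                                call. = FALSE)
  cnt <- as.matrix(inputs[c("live_births", "fetal_losses", "induced_abortions")])
  if (any(cnt < 0) || any(inputs$female_population < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  point <- as.numeric(cnt %*% d)
  has_events <- point > 0
  if (any(has_events & inputs$female_population <= 0)) {
    stop("strata with pregnancy events need a positive female population",
         call. = FALSE)
  }
  prev <- ifelse(inputs$female_population > 0,
                 point / inputs$female_population, 0)
  if (any(prev > 1)) {
    stop("pregnancy point prevalence exceeds 1: annual counts inconsistent ",
         "with female population", call. = FALSE)
  }
  out <- setNames(numeric(10L), age_stratum_labels())
  out[as.character(inputs$stratum)] <- prev
  out
}

#' Stratum-wide pregnancy prevalence
#'
#' Pregnancy is estimated among females; the cascade operates on whole age
#' strata, so the female-only prevalence is applied to the female proportion
#' of each stratum.
#'
#' @param preg_among_females Prevalence among females, in `[0,1]`.
#' @param female_fraction Female share of the stratum population, in `[0,1]`.
#' @return Elementwise product: the stratum-wide prevalence.
#' @export
effective_pregnancy_prevalence <- function(preg_among_females, female_fraction) {
  stopifnot(all(preg_among_females >= 0 & preg_among_females <= 1),
            all(female_fraction >= 0 & female_fraction <= 1))
  preg_among_females * female_fraction
}

#' Urbanicity-adjusted prevalence
#'
#' Mixes urban and rural prevalences of a factor by a region's urban
#' population fraction (convex combination). Used for factors known only
#' nationally by urban/rural status, e.g. outdoor work.
#'
#' @param p_urban,p_rural Prevalences in `[0,1]`.
#' @param urban_fraction Region's urban population share in `[0,1]`.
#' @return `urban_fraction * p_urban + (1 - urban_fraction) * p_rural`.
#' @export
urbanicity_adjusted_prevalence <- function(p_urban, p_rural, urban_fraction) {
  stopifnot(all(p_urban >= 0 & p_urban <= 1),
            all(p_rural >= 0 & p_rural <= 1),
            all(urban_fraction >= 0 & urban_fraction <= 1))
  urban_fraction * p_urban + (1 - urban_fraction) * p_rural
}

# --- prevalence table --------------------------------------------------------

#' Construct / validate a prevalence table
#'
#' The normalized long-format container for all factor prevalences: one row
#' per (`scope`, `stratum`, `factor`[, `urbanicity`]) with the prevalence
#' `value` and a `provenance` tag (`survey-estimated`, `supplied`, or
#' `derived`). `scope` is a region id or `"NATIONAL"`; region rows override
#' national rows on lookup.
#'
#' @param df Data frame with columns `scope`, `stratum`, `factor`, `value`
#'   and optionally `urbanicity`, `provenance`.
#' @return The validated data frame with class `prevalence_table`.
#' @export
prevalence_table <- function(df) {
  need <- c("scope", "stratum", "factor", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("prevalence table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"urbanicity" %in% names(df)) df$urbanicity <- NA_character_
  if (!"provenance" %in% names(df)) df$provenance <- "supplied"
  if (any(!is.finite(df$value) | df$value < 0 | df$value > 1)) {
    stop("prevalence values must lie in [0,1]", call. = FALSE)
  }
  bad <- setdiff(unique(df$stratum), age_stratum_labels())
  if (length(bad)) stop("unknown strata in prevalence table: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  df <- df[c("scope", "stratum", "factor", "urbanicity", "value", "provenance")]
  class(df) <- c("prevalence_table", "data.frame")
  df
}

#' Look up a prevalence
#'
#' Region-specific entries take precedence over `NATIONAL` ones; entries with
#' an `urbanicity` tag are ignored here (they are inputs to the urbanicity
#' adjustment, not per-region values).
#'
#' @param table A [prevalence_table()].
#' @param region Region id (or `"NATIONAL"`).
#' @param stratum Canonical stratum label.
#' @param factor Factor name.
#' @return The prevalence, or `NA` if no entry resolves.
#' @export
prevalence_lookup <- function(table, region, stratum, factor) {
  rows <- table$stratum == stratum & table$factor == factor &
    is.na(table$urbanicity)
  reg <- rows & table$scope == region
  if (any(reg)) return(table$value[which(reg)[1L]])
  nat <- rows & table$scope == "NATIONAL"
  if (any(nat)) return(table$value[which(nat)[1L]])
  NA_real_
}

# weighted survey estimate for one factor over region x stratum cells
# (vectorized: one pass over the microdata), with a national fallback for
# cells that have no complete-case respondents; agrees cell-by-cell with
# weighted_prevalence() on the corresponding domain
.survey_factor_rows <- function(survey, fct, scope, regions_ids, x) {
  st <- as.character(age_to_stratum(survey$age))
  ok <- !is.na(x) & st %in% scope
  xs <- x[ok]; ws <- survey$weight[ok]; sts <- st[ok]
  rgs <- as.character(survey$region_id)[ok]
  if (length(ws) && any(!is.finite(ws) | ws <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  key <- paste(rgs, sts, sep = "\r")
  val_cell <- tapply(ws * xs, key, sum) / tapply(ws, key, sum)
  val_nat <- tapply(ws * xs, sts, sum) / tapply(ws, sts, sum)
  grid <- expand.grid(scope = regions_ids, stratum = scope,
                      stringsAsFactors = FALSE)
  val <- as.numeric(val_cell[paste(grid$scope, grid$stratum, sep = "\r")])
  prov <- ifelse(is.na(val), "survey-estimated-national", "survey-estimated")
  fallback <- is.na(val)
  val[fallback] <- as.numeric(val_nat[grid$stratum[fallback]])
  if (anyNA(val)) {
    bad <- unique(sprintf("(%s, %s)", fct, grid$stratum[is.na(val)]))
    stop("unresolvable survey factor cells: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(scope = grid$scope, stratum = grid$stratum, factor = fct,
             urbanicity = NA_character_, value = val, provenance = prov,
             stringsAsFactors = FALSE)
}

#' Build the full prevalence table for a criteria set
#'
#' Resolves every factor of a criteria set to per-region, per-stratum
#' prevalences, following each factor's geographic resolution:
#'
#' * `chronic_disease` and `less_than_hs` are survey-weighted estimates per
#'   region and stratum (union indicator for chronic disease); cells with no
#'   complete-case respondents fall back to the national survey estimate.
#' * `pregnancy` is estimated nationally among females from annual event
#'   counts, then converted to a stratum-wide prevalence per region using
#'   that region's female fractions.
#' * `outdoor_work` uses national urban/rural prevalences by stratum, mixed
#'   per region by its urban population fraction.
#' * `low_vitc` is a national age-specific prevalence broadcast to regions.
#' * Wholesale age factors get prevalence 1 over their scope.
#'
#' @param survey Survey microdata data frame (see [read_survey_csv()] for the
#'   dialect).
#' @param supplied [prevalence_table()] (or plain data frame) of supplied
#'   national prevalences: `outdoor_work` rows tagged `urbanicity`
#'   urban/rural, `low_vitc` rows untagged.
#' @param pregnancy_inputs Annual event counts per stratum (see
#'   [pregnancy_point_prevalence()]).
#' @param regions Region table: one row per region x stratum with columns
#'   `region_id`, `stratum`, `population`, `female_fraction`,
#'   `urban_fraction`.
#' @param criteria A [criteria_set()].
#' @param durations Gestational durations, passed to
#'   [pregnancy_point_prevalence()].
#' @return A [prevalence_table()] covering every (factor, in-scope stratum,
#'   region) the criteria set needs.
#' @export
build_prevalence_table <- function(survey, supplied, pregnancy_inputs, regions,
                                   criteria,
                                   durations = list(birth = 40 / 52,
                                                    loss = 11 / 52,
                                                    abortion = 10 / 52)) {
  stopifnot(inherits(criteria, "criteria_set"))
  supplied <- as.data.frame(supplied)
  if (!"urbanicity" %in% names(supplied)) supplied$urbanicity <- NA_character_
  rids <- unique(regions$region_id)
  urb <- regions$urban_fraction[match(rids, regions$region_id)]
  parts <- list()
  preg_f <- NULL
  for (i in seq_len(nrow(criteria))) {
    fct <- criteria$name[i]
    scope <- criteria$age_scope[[i]]
    if (criteria$wholesale[i]) {
      parts[[fct]] <- data.frame(scope = "NATIONAL", stratum = scope,
                                 factor = fct, urbanicity = NA_character_,
                                 value = 1, provenance = "derived",
                                 stringsAsFactors = FALSE)
    } else if (fct == "chronic_disease") {
      m <- as.matrix(survey[c("asthma", "copd", "heart_disease", "diabetes")])
      union <- ifelse(rowSums(is.na(m)) > 0, NA_real_,
                      as.numeric(rowSums(m) > 0))
      parts[[fct]] <- .survey_factor_rows(survey, fct, scope, rids, union)
    } else if (fct == "less_than_hs") {
      parts[[fct]] <- .survey_factor_rows(survey, fct, scope, rids,
                                          survey$less_than_hs)
    } else if (fct == "pregnancy") {
      preg_f <- pregnancy_point_prevalence(pregnancy_inputs, durations)
      grid <- expand.grid(scope = rids, stratum = scope,
                          stringsAsFactors = FALSE)
      ff <- regions$female_fraction[match(
        paste(grid$scope, grid$stratum),
        paste(regions$region_id, regions$stratum))]
      if (anyNA(ff)) stop("regions table lacks female_fraction for some ",
                          "region x stratum cells", call. = FALSE)
      grid$factor <- fct; grid$urbanicity <- NA_character_
      grid$value <- effective_pregnancy_prevalence(preg_f[grid$stratum], ff)
      grid$provenance <- "derived"
      parts[[fct]] <- grid
    } else if (fct == "outdoor_work") {
      pu <- supplied[supplied$factor == fct &
                       supplied$urbanicity %in% "urban", ]
      pr <- supplied[supplied$factor == fct &
                       supplied$urbanicity %in% "rural", ]
      missing <- scope[!(scope %in% pu$stratum & scope %in% pr$stratum)]
      if (length(missing)) {
        stop("unresolvable supplied factor cells: ",
             paste(sprintf("(%s, %s)", fct, missing), collapse = ", "),
             call. = FALSE)
      }
      grid <- expand.grid(scope = rids, stratum = scope,
                          stringsAsFactors = FALSE)
      grid$factor <- fct; grid$urbanicity <- NA_character_
      grid$value <- urbanicity_adjusted_prevalence(
        pu$value[match(grid$stratum, pu$stratum)],
        pr$value[match(grid$stratum, pr$stratum)],
        urb[match(grid$scope, rids)])
      grid$provenance <- "derived"
      parts[[fct]] <- grid
    } else {
      # national age-specific supplied factor (e.g. low vitamin C intake)
      sp <- supplied[supplied$factor == fct & is.na(supplied$urbanicity), ]
      missing <- setdiff(scope, sp$stratum)
      if (length(missing)) {
        stop("unresolvable supplied factor cells: ",
             paste(sprintf("(%s, %s)", fct, missing), collapse = ", "),
             call. = FALSE)
      }
      parts[[fct]] <- data.frame(scope = "NATIONAL", stratum = scope,
                                 factor = fct, urbanicity = NA_character_,
                                 value = sp$value[match(scope, sp$stratum)],
                                 provenance = "supplied",
                                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  prevalence_table(out)
}
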