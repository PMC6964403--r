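#' Susceptibility factor specifications
#'
#' A factor spec describes one susceptibility factor: its position in the
#' sequential cascade, the age strata it applies to, whether it applies to
#' the whole population or only via the female fraction (pregnancy), and
#' whether it is "wholesale" -- i.e. the entire in-scope age band counts as
#' susceptible (prevalence fixed at 1), as for the young-age and old-age
#' factors.
#'
#' @param name Factor identifier (used as the key into the prevalence table).
#' @param age_scope Character vector of canonical stratum labels the factor
#'   applies to; prevalence is 0 outside the scope.
#' @param sex Either `"all"` or `"female"`; `"female"` factors are entered in
#'   the cascade as a stratum-wide prevalence, i.e. the female-only
#'   prevalence multiplied by the stratum's female fraction (see
#'   [effective_pregnancy_prevalence()]).
#' @param wholesale If `TRUE`, prevalence is 1 on the scope and no prevalence
#'   table entry is needed.
#' @return A one-row data frame; rows of these are stacked into a criteria
#'   set.
#' @export
factor_spec <- function(name, age_scope, sex = c("all", "female"),
                        wholesale = FALSE) {
  sex <- match.arg(sex)
  bad <- setdiff(age_scope, age_stratum_labels())
  if (length(bad)) {
    stop("unknown stratum labels in age_scope: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(name = name, sex = sex, wholesale = wholesale,
             age_scope = I(list(age_scope)), stringsAsFactors = FALSE)
}

.all_strata <- function() age_stratum_labels()
.strata_between <- function(from, to) {
  labs <- age_stratum_labels()
  labs[seq(match(from, labs), match(to, labs))]
}

#' Canonical criteria sets
#'
#' The two nested factor sets defining who counts as more susceptible.
#' The restrictive set has four factors: age under 10, age 75 and over (both
#' wholesale), chronic disease (any of asthma, COPD, heart disease, or
#' diabetes; ages 10-74), and pregnancy. The inclusive set appends outdoor
#' work (from age 16), less than high-school education (from age 20), low
#' vitamin C intake (from age 10), and a final wholesale "remainder" factor
#' that captures everyone aged 10-19 or 65-74 not already flagged, which
#' widens the age criteria to under 20 and 65-plus.
#'
#' The factor order is frozen: wholesale age factors first, then chronic
#' disease, pregnancy, outdoor work, education, vitamin C, and the remainder
#' last. The total percent with at least one factor is invariant to the
#' order (the survivor product is symmetric); the order only shapes the
#' per-factor decomposition.
#'
#' @param name `"restrictive"` or `"inclusive"`, or `"custom"` with an
#'   explicit `factors` data frame built from [factor_spec()] rows.
#' @param factors For `name = "custom"`: a data frame of stacked
#'   [factor_spec()] rows, applied in row order.
#' @return An object of class `criteria_set`: a data frame of factor specs in
#'   cascade order with an `order_index` column.
#' @examples
#' criteria_set("restrictive")$name
#' @export
criteria_set <- function(name = c("restrictive", "inclusive", "custom"),
                         factors = NULL) {
  name <- match.arg(name)
  restrictive <- rbind(
    factor_spec("age_lt10", "<10", wholesale = TRUE),
    factor_spec("age_ge75", "75+", wholesale = TRUE),
    factor_spec("chronic_disease", .strata_between("10-14", "65-74")),
    factor_spec("pregnancy", .strata_between("15", "45-64"), sex = "female")
  )
  fs <- switch(name,
    restrictive = restrictive,
    inclusive = rbind(
      restrictive,
      factor_spec("outdoor_work", .strata_between("16-19", "65-74")),
      factor_spec("less_than_hs", .strata_between("20-24", "75+")),
      factor_spec("low_vitc", .strata_between("10-14", "75+")),
      factor_spec("remainder_10_19_65_74",
                  c("10-14", "15", "16-19", "65-74"), wholesale = TRUE)
    ),
    custom = {
      if (is.null(factors)) stop("custom criteria need a factors data frame",
                                 call. = FALSE)
      factors
    }
  )
  if (anyDuplicated(fs$name)) stop("factor names must be unique", call. = FALSE)
  fs$order_index <- seq_len(nrow(fs))
  attr(fs, "criteria") <- name
  class(fs) <- c("criteria_set", class(fs))
  fs
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("Criteria set:", attr(x, "criteria"), "(", nrow(x), "factors )\n")
  for (i in seq_len(nrow(x))) {
    scope <- x$age_scope[[i]]
    cat(sprintf("  %d. %-22s %s%s [%s]\n", x$order_index[i], x$name[i],
                if (x$wholesale[i]) "wholesale " else "",
                if (x$sex[i] == "female") "(female) " else "",
                paste(range_label(scope), collapse = "")))
  }
  invisible(x)
}

# compact "a..b" label for a contiguous run of strata (falls back to a list)
range_label <- function(scope) {
  labs <- age_stratum_labels()
  idx <- sort(match(scope, labs))
  if (identical(idx, seq(min(idx), max(idx)))) {
    if (length(idx) == 1L) labs[idx] else paste0(labs[min(idx)], "..", labs[max(idx)])
  } else paste(labs[idx], collapse = ",")
}
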