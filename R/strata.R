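#' Canonical age strata
#'
#' The analysis divides the population into ten age bands chosen so that every
#' susceptibility factor's age scope aligns with band boundaries: pregnancy
#' estimation includes 15-year-olds while outdoor work begins at 16, which is
#' why the 10-19 range is split into unequal pieces. Bands are half-open
#' intervals on completed years of age: `[0,10), [10,15), [15,16), [16,20),
#' [20,25), [25,35), [35,45), [45,65), [65,75), [75,Inf)`.
#'
#' @return Character vector of the ten stratum labels, in age order.
#' @examples
#' age_stratum_labels()
#' @export
age_stratum_labels <- function() {
  c("<10", "10-14", "15", "16-19", "20-24",
    "25-34", "35-44", "45-64", "65-74", "75+")
}

# lower (inclusive) and upper (exclusive) bounds of each band, in years
.stratum_lo <- c(0, 10, 15, 16, 20, 25, 35, 45, 65, 75)
.stratum_hi <- c(10, 15, 16, 20, 25, 35, 45, 65, 75, Inf)

#' Stratum bounds table
#'
#' @return Data frame with columns `label`, `lo` (inclusive) and `hi`
#'   (exclusive), one row per canonical stratum.
#' @export
age_stratum_bounds <- function() {
  data.frame(label = age_stratum_labels(), lo = .stratum_lo, hi = .stratum_hi,
             stringsAsFactors = FALSE)
}

#' Map ages to canonical strata
#'
#' Each completed age in years maps to exactly one of the ten canonical
#' strata.
#'
#' @param age Numeric vector of ages in completed years, `>= 0`.
#' @return Factor of stratum labels with levels in age order.
#' @examples
#' age_to_stratum(c(0, 9, 10, 15, 16, 44, 80))
#' @export
age_to_stratum <- function(age) {
  if (any(!is.finite(age) | age < 0)) {
    stop("ages must be finite and non-negative", call. = FALSE)
  }
  idx <- findInterval(age, .stratum_lo)
  factor(age_stratum_labels()[idx], levels = age_stratum_labels())
}

#' Build an age-strata table
#'
#' Assembles and validates the per-stratum population and female-fraction
#' table consumed by [run_cascade()].
#'
#' @param population Numeric vector of 10 non-negative population counts,
#'   named by stratum label or given in canonical order.
#' @param female_fraction Numeric vector of 10 fractions in `[0,1]` (recycled
#'   if length 1).
#' @return Data frame with columns `label`, `lo`, `hi`, `population`,
#'   `female_fraction`.
#' @export
age_strata <- function(population, female_fraction = 0.5) {
  labs <- age_stratum_labels()
  if (!is.null(names(population))) {
    if (!setequal(names(population), labs)) {
      stop("population names must be exactly the ten canonical stratum labels",
           call. = FALSE)
    }
    population <- population[labs]
  }
  if (length(population) != 10L || any(population < 0)) {
    stop("population must give ten non-negative counts", call. = FALSE)
  }
  female_fraction <- rep_len(female_fraction, 10L)
  if (any(female_fraction < 0 | female_fraction > 1)) {
    stop("female_fraction must lie in [0,1]", call. = FALSE)
  }
  out <- age_stratum_bounds()
  out$population <- as.numeric(population)
  out$female_fraction <- as.numeric(female_fraction)
  out
}
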