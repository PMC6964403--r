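#' Regional multi-year mean concentration
#'
#' Zonal statistic on a gridded pollutant surface: for each region, the mean
#' over the requested years of the (optionally area-weighted) mean over the
#' region's grid cells within each year. Averaging is cell-within-year
#' first, then across years; a missing cell-year is an input error, not
#' imputed.
#'
#' @param surface Long-format grid: data frame with columns `cell_id`,
#'   `region_id`, `pollutant`, `year`, `concentration` and optionally
#'   `area_weight`.
#' @param pollutant Pollutant name to select.
#' @param years Years to average over.
#' @return Named numeric vector of regional means (names = region ids).
#' @examples
#' s <- data.frame(cell_id = 1, region_id = "A", pollutant = "pm25",
#'                 year = 2010:2012, concentration = c(8, 10, 12))
#' regional_multiyear_mean(s, "pm25", 2010:2012)  # 10
#' @export
regional_multiyear_mean <- function(surface, pollutant, years) {
  s <- surface[surface$pollutant == pollutant & surface$year %in% years, ]
  missing_years <- setdiff(years, unique(s$year))
  if (length(missing_years)) {
    stop("surface lacks years: ", paste(missing_years, collapse = ", "),
         call. = FALSE)
  }
  if (any(s$concentration < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  w <- if ("area_weight" %in% names(s) && !all(is.na(s$area_weight))) {
    s$area_weight
  } else rep(1, nrow(s))
  key <- paste(s$region_id, s$year, sep = "\r")
  yearly <- tapply(s$concentration * w, key, sum) / tapply(w, key, sum)
  reg <- sub("\r.*$", "", names(yearly))
  out <- tapply(yearly, reg, mean)
  all_regions <- sort(unique(as.character(surface$region_id)))
  absent <- setdiff(all_regions, names(out))
  if (length(absent)) {
    stop("region(s) with no cells for ", pollutant, " in requested years: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out[all_regions]
}

#' Assign quartile labels
#'
#' Splits regions into quartiles of a value (susceptibility percent or
#' pollutant concentration). Thresholds are the 25th/50th/75th percentiles
#' under the linear-interpolation-of-order-statistics convention
#' (`stats::quantile` type 7); a value `v` gets label 1 if `v <= Q25`, 2 if
#' `v <= Q50`, 3 if `v <= Q75`, else 4, so ties straddling a threshold all
#' take the lower label. Labels are invariant under strictly increasing
#' transforms of the values.
#'
#' @param values Named numeric vector (one value per region), `n >= 4`.
#' @return Integer vector of labels in `1:4`, same names as `values`. If all
#'   values are identical the quartiles are degenerate: everything is
#'   labelled 1 with a warning.
#' @examples
#' assign_quartiles(setNames(1:4, letters[1:4]))
#' @export
assign_quartiles <- function(values) {
  if (length(values) < 4L) stop("need at least 4 regions for quartiles",
                                call. = FALSE)
  if (anyNA(values)) stop("values must be complete", call. = FALSE)
  if (max(values) == min(values)) {
    warning("all values identical: degenerate quartiles, labelling all 1")
    return(setNames(rep(1L, length(values)), names(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lab <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  setNames(as.integer(lab), names(values))
}

#' Cross-classify susceptibility and pollutant quartiles
#'
#' Counts regions in each of the 16 cells formed by susceptibility quartile
#' (rows) by pollutant-concentration quartile (columns) -- the heat-map
#' classification from low/low to high/high.
#'
#' @param susc_quartiles,pollutant_quartiles Named integer vectors in `1:4`
#'   over the same region set.
#' @return 4x4 integer matrix of counts (class `table`); margins equal the
#'   quartile size vectors of each input and the grand total is the number
#'   of regions.
#' @export
cross_classify <- function(susc_quartiles, pollutant_quartiles) {
  if (!setequal(names(susc_quartiles), names(pollutant_quartiles)) ||
      length(susc_quartiles) != length(pollutant_quartiles)) {
    stop("quartile labelings must cover the same region set", call. = FALSE)
  }
  pollutant_quartiles <- pollutant_quartiles[names(susc_quartiles)]
  table(susceptibility = factor(susc_quartiles, levels = 1:4),
        pollutant = factor(pollutant_quartiles, levels = 1:4))
}

#' Identify priority (double-jeopardy) regions
#'
#' A region is a priority region if it is in the highest quartile of
#' susceptibility under either criteria set AND in the highest quartile of
#' either pollutant's concentration -- i.e. high susceptibility co-occurring
#' with high exposure.
#'
#' @param restrictive_q,inclusive_q,o3_q,pm25_q Named quartile labelings
#'   (`1:4`) over the same region set.
#' @return Data frame, one row per priority region, with the region id and
#'   logical flags `high_restrictive`, `high_inclusive`, `high_o3`,
#'   `high_pm25` recording which disjuncts fired.
#' @export
priority_regions <- function(restrictive_q, inclusive_q, o3_q, pm25_q) {
  ids <- names(restrictive_q)
  for (v in list(inclusive_q, o3_q, pm25_q)) {
    if (!setequal(names(v), ids)) {
      stop("quartile labelings must cover the same region set", call. = FALSE)
    }
  }
  inclusive_q <- inclusive_q[ids]; o3_q <- o3_q[ids]; pm25_q <- pm25_q[ids]
  susc <- restrictive_q == 4L | inclusive_q == 4L
  expo <- o3_q == 4L | pm25_q == 4L
  sel <- susc & expo
  data.frame(region_id = ids[sel],
             high_restrictive = unname(restrictive_q[sel] == 4L),
             high_inclusive = unname(inclusive_q[sel] == 4L),
             high_o3 = unname(o3_q[sel] == 4L),
             high_pm25 = unname(pm25_q[sel] == 4L),
             stringsAsFactors = FALSE)
}

#' Averaging-window stability check
#'
#' Squared Pearson correlation, across regions, between regional means
#' computed over a short averaging window (e.g. 3 years) and a long one
#' (e.g. 10 years). Values near 1 indicate the short window is stable
#' relative to anomalous single years.
#'
#' @param surface Gridded surface (see [regional_multiyear_mean()]).
#' @param pollutant Pollutant name.
#' @param short_years,long_years The two year sets.
#' @return Squared Pearson correlation (scalar).
#' @export
stability_check <- function(surface, pollutant, short_years, long_years) {
  a <- regional_multiyear_mean(surface, pollutant, short_years)
  b <- regional_multiyear_mean(surface, pollutant, long_years)
  if (length(a) < 3L) stop("stability check needs at least 3 regions",
                           call. = FALSE)
  stats::cor(a, b[names(a)])^2
}
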