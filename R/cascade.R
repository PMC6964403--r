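#' Sequential risk-factor decomposition (arithmetic core)
#'
#' Within one age stratum with effective factor prevalences `p[1..K]`
#' (`p = 0` off-scope), factors are applied in order to the fraction of the
#' population not yet flagged: starting from `q0 = 1`, factor `k` claims
#' `c_k = q_{k-1} * p_k` and leaves `q_k = q_{k-1} * (1 - p_k)`. Under the
#' independence assumption the total flagged fraction is
#' `1 - prod(1 - p_k)` -- the inclusion-exclusion union probability -- which
#' is symmetric in the factors, so reordering changes the per-factor
#' decomposition but never the total.
#'
#' @param p Numeric vector (one stratum) or matrix (strata in rows, factors
#'   in columns) of effective prevalences in `[0,1]`.
#' @return List with `contribution` (same shape as `p`), `remaining`
#'   (`prod(1 - p)` per stratum), and `total` (`1 - remaining`).
#' @examples
#' cascade_decompose(c(0.2, 0.5))  # contributions 0.2, 0.4; remaining 0.4
#' @export
cascade_decompose <- function(p) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, nrow = 1L) else as.matrix(p)
  if (any(!is.finite(m) | m < 0 | m > 1)) {
    stop("prevalences must lie in [0,1]", call. = FALSE)
  }
  surv <- t(apply(cbind(1, 1 - m), 1L, cumprod))  # q_0 .. q_K per stratum
  contrib <- surv[, -ncol(surv), drop = FALSE] * m
  dimnames(contrib) <- dimnames(m)
  remaining <- setNames(surv[, ncol(surv)], rownames(m))
  if (vec) contrib <- drop(contrib)
  list(contribution = contrib, remaining = remaining, total = 1 - remaining)
}

# effective (stratum x factor) prevalence matrix for a region under a
# criteria set: wholesale -> 1 in scope, else table lookup; 0 off-scope
.effective_prevalences <- function(strata, prevalences, criteria, region) {
  K <- nrow(criteria)
  P <- matrix(0, nrow = nrow(strata), ncol = K,
              dimnames = list(strata$label, criteria$name))
  missing <- character(0)
  for (k in seq_len(K)) {
    scope <- criteria$age_scope[[k]]
    for (a in match(scope, strata$label)) {
      if (criteria$wholesale[k]) {
        P[a, k] <- 1
      } else {
        v <- prevalence_lookup(prevalences, region, strata$label[a],
                               criteria$name[k])
        if (is.na(v)) {
          missing <- c(missing,
                       sprintf("(%s, %s)", criteria$name[k], strata$label[a]))
        } else P[a, k] <- v
      }
    }
  }
  if (length(missing)) {
    stop("missing in-scope prevalences: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  P
}

#' Run the susceptibility cascade
#'
#' The core estimator: applies the ordered risk factors of a criteria set
#' within each of the ten age strata, removing the flagged fraction at every
#' step so no one is double-counted, and totals the population with at least
#' one risk factor. Pregnancy prevalences in `prevalences` must already be
#' stratum-wide (female prevalence times female fraction;
#' [build_prevalence_table()] does this).
#'
#' @param strata Age-strata table from [age_strata()] (labels, populations,
#'   female fractions).
#' @param prevalences A [prevalence_table()].
#' @param criteria A [criteria_set()] or one of its names
#'   (`"restrictive"`/`"inclusive"`).
#' @param region Region id used for table lookups; defaults to `"NATIONAL"`.
#' @return An object of class `cascade_result` with components
#'   `contribution` (stratum x factor matrix of population fractions),
#'   `remaining` (per-stratum never-flagged fraction), `per_factor_percent`
#'   (percent of the total population attributed to each factor),
#'   `total_percent` (percent with at least one factor), `strata`,
#'   `criteria`, `region`. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' strata <- age_strata(rep(1000, 10))
#' prev <- prevalence_table(data.frame(
#'   scope = "NATIONAL",
#'   stratum = rep(c("10-14", "15", "16-19", "20-24", "25-34", "35-44",
#'                   "45-64", "65-74"), 2),
#'   factor = rep(c("chronic_disease", "pregnancy"), each = 8),
#'   value = rep(c(0.15, 0.005), each = 8)))
#' fit <- run_cascade(strata, prev, "restrictive")
#' coef(fit)
#' @export
run_cascade <- function(strata, prevalences, criteria = "restrictive",
                        region = "NATIONAL") {
  if (is.character(criteria)) criteria <- criteria_set(criteria)
  stopifnot(inherits(criteria, "criteria_set"))
  P <- .effective_prevalences(strata, prevalences, criteria, region)
  dec <- cascade_decompose(P)
  N <- sum(strata$population)
  wt <- if (N > 0) strata$population / N else rep(0, nrow(strata))
  per_factor <- 100 * as.numeric(wt %*% dec$contribution)
  names(per_factor) <- criteria$name
  structure(list(contribution = dec$contribution,
                 remaining = dec$remaining,
                 prevalence = P,
                 per_factor_percent = per_factor,
                 total_percent = sum(per_factor),
                 strata = strata,
                 criteria = criteria,
                 region = region),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("Susceptibility cascade (%s criteria, region %s)\n",
              attr(x$criteria, "criteria"), x$region))
  cat(sprintf("  population: %s in %d age strata\n",
              format(sum(x$strata$population), big.mark = ","),
              nrow(x$strata)))
  cat(sprintf("  more susceptible (>= 1 risk factor): %.1f%%\n",
              x$total_percent))
  invisible(x)
}

#' @export
summary.cascade_result <- function(object, ...) {
  out <- decompose_to_table(object)
  class(out) <- c("summary.cascade_result", "data.frame")
  attr(out, "total_percent") <- object$total_percent
  attr(out, "criteria") <- attr(object$criteria, "criteria")
  out
}

#' @export
print.summary.cascade_result <- function(x, ...) {
  cat(sprintf("Per-factor percent of population (%s criteria):\n",
              attr(x, "criteria")))
  df <- as.data.frame(x)
  df$percent <- round(df$percent, 1)
  print(df, row.names = FALSE)
  cat(sprintf("Total with >= 1 factor: %.1f%%\n", attr(x, "total_percent")))
  invisible(x)
}

#' @export
coef.cascade_result <- function(object, ...) object$per_factor_percent

#' @export
plot.cascade_result <- function(x, ...) {
  # stacked per-stratum decomposition: factor contributions + never-flagged
  m <- rbind(t(x$contribution), remaining = x$remaining)
  cols <- c(grDevices::hcl.colors(nrow(m) - 1L, "Spectral"), "grey85")
  graphics::barplot(m, col = cols, las = 2,
                    ylab = "fraction of stratum population",
                    legend.text = rownames(m),
                    args.legend = list(x = "topright", cex = 0.6, bg = "white"),
                    ...)
  invisible(x)
}

#' Per-factor population percents
#'
#' Converts a cascade decomposition to the population scale: factor `k`'s
#' percent is the population-weighted mean of its per-stratum contribution,
#' and the per-factor percents sum exactly to the total percent with at
#' least one factor.
#'
#' @param result A `cascade_result`.
#' @return Data frame with columns `factor`, `percent`.
#' @export
decompose_to_table <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  data.frame(factor = result$criteria$name,
             percent = unname(result$per_factor_percent),
             stringsAsFactors = FALSE)
}

#' Run the cascade for every region
#'
#' @param regions Region table: one row per region x stratum with columns
#'   `region_id`, `stratum`, `population`, `female_fraction`.
#' @param prevalences A [prevalence_table()].
#' @param criteria A [criteria_set()] or name.
#' @return Data frame: one row per region with `region_id`, `population`,
#'   `total_percent`, and one `pct_<factor>` column per factor.
#' @export
region_cascades <- function(regions, prevalences, criteria = "restrictive") {
  if (is.character(criteria)) criteria <- criteria_set(criteria)
  rids <- unique(regions$region_id)
  rows <- lapply(rids, function(rg) {
    sub <- regions[regions$region_id == rg, ]
    st <- age_strata(setNames(sub$population, sub$stratum),
                     sub$female_fraction[match(age_stratum_labels(),
                                               sub$stratum)])
    fit <- run_cascade(st, prevalences, criteria, region = rg)
    c(population = sum(st$population), total_percent = fit$total_percent,
      setNames(fit$per_factor_percent,
               paste0("pct_", names(fit$per_factor_percent))))
  })
  out <- data.frame(region_id = rids, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' National percent from regional results
#'
#' Population-weighted mean of regional total percents; equals the direct
#' national cascade when all regions share one prevalence table and age
#' structure.
#'
#' @param total_percent Per-region totals (percent).
#' @param population Per-region population counts, `> 0`.
#' @return The national percent.
#' @examples
#' aggregate_regions(c(30, 34), c(1e6, 3e6))  # 33
#' @export
aggregate_regions <- function(total_percent, population) {
  if (any(population <= 0)) stop("region populations must be positive",
                                 call. = FALSE)
  stats::weighted.mean(total_percent, population)
}

#' Regional variability summary
#'
#' Minimum, quartiles, median, mean, and maximum of each factor's percent
#' (and the total) across regions -- the standard regional variability
#' summary for this analysis.
#'
#' @param region_results Output of [region_cascades()].
#' @return Data frame: one row per percent column with the six summary
#'   statistics.
#' @export
region_summary <- function(region_results) {
  cols <- c(grep("^pct_", names(region_results), value = TRUE),
            "total_percent")
  stats_row <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    c(min = min(v), p25 = q[[1]], median = q[[2]], mean = mean(v),
      p75 = q[[3]], max = max(v))
  }
  out <- data.frame(quantity = sub("^pct_", "", cols),
                    t(vapply(region_results[cols], stats_row, numeric(6))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
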