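#' Spearman rank correlation
#'
#' Self-contained rank-correlation estimate: the Pearson correlation of the
#' two variables' average ranks (midranks for ties), with a two-sided
#' p-value from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom. Invariant under strictly increasing
#' transforms of either variable and symmetric in its arguments.
#'
#' For small samples the t approximation is coarse, so with
#' `p_method = "auto"` (the default) the p-value is instead computed exactly
#' for `n <= 8` by enumerating all `n!` permutations of one variable's ranks
#' and counting those with `|rho|` at least as large as observed.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`. Pairs with a
#'   missing value in either variable are dropped (pairwise complete).
#' @param p_method `"auto"` (exact enumeration for `n <= 8`, t approximation
#'   otherwise), `"t"`, or `"exact"` (only feasible for small `n`).
#' @return List with `rho`, `p_value`, and `n` (pairs used).
#' @examples
#' spearman_rho(1:10, (1:10)^3)$rho  # 1
#' @export
spearman_rho <- function(x, y, p_method = c("auto", "t", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero rank variance: rho undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (p_method == "auto") p_method <- if (n <= 8L) "exact" else "t"
  p <- if (p_method == "exact") {
    if (n > 9L) stop("exact permutation p-value is infeasible for n > 9",
                     call. = FALSE)
    pm <- .permutations(n)
    rhos <- apply(pm, 1L, function(idx) stats::cor(rx, ry[idx]))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

# all permutations of 1..n, one per row
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Correlation report over regional indicators
#'
#' Rank correlations between the regional susceptibility, rurality, and
#' concentration indicators: restrictive vs inclusive percent, inclusive
#' percent vs rural percent, each pollutant vs each susceptibility percent,
#' and each pollutant vs urban percent. Degenerate pairs (zero rank
#' variance) are reported as `NA` rather than aborting the report; dropped
#' (incomplete) regions are counted per pair.
#'
#' @param frame Data frame with one row per region and columns
#'   `restrictive_pct`, `inclusive_pct`, `urban_pct`, `rural_pct`,
#'   `pm25_mean`, `o3_mean`.
#' @return Data frame with columns `pair`, `rho`, `p_value`, `n`.
#' @export
correlation_report <- function(frame) {
  pairs <- list(
    c("restrictive_pct", "inclusive_pct"),
    c("inclusive_pct", "rural_pct"),
    c("pm25_mean", "restrictive_pct"),
    c("pm25_mean", "inclusive_pct"),
    c("o3_mean", "restrictive_pct"),
    c("o3_mean", "inclusive_pct"),
    c("pm25_mean", "urban_pct"),
    c("o3_mean", "urban_pct"))
  need <- unique(unlist(pairs))
  miss <- setdiff(need, names(frame))
  if (length(miss)) stop("indicator frame missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(pairs, function(pr) {
    res <- tryCatch(spearman_rho(frame[[pr[1]]], frame[[pr[2]]]),
                    error = function(e) list(rho = NA_real_,
                                             p_value = NA_real_,
                                             n = sum(stats::complete.cases(
                                               frame[pr]))))
    data.frame(pair = paste(pr, collapse = " ~ "), rho = res$rho,
               p_value = res$p_value, n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dropped <- nrow(frame) - out$n
  if (any(dropped > 0)) {
    message("correlation_report: dropped incomplete regions per pair: ",
            paste(paste0(out$pair, "=", dropped)[dropped > 0], collapse = "; "))
  }
  out
}
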