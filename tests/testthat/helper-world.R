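# small fixture builders used across test files; everything is generated in
# code, nothing is read from disk

# a tiny but fully specified world: fast enough for per-test regeneration
tiny_config <- function(seed = 42, ...) {
  generator_config(n_regions = 6, n_respondents_per_region = 400,
                   seed = seed, ...)
}

# one-stratum strata table with unit population
one_stratum <- function(label = "25-34", population = 1000,
                        female_fraction = 0.5) {
  pop <- setNames(rep(0, 10), age_stratum_labels())
  pop[label] <- population
  age_strata(pop, female_fraction)
}

# uniform strata table (equal population in all ten bands)
flat_strata <- function(population = 1000, female_fraction = 0.5) {
  age_strata(rep(population, 10), female_fraction)
}

# national prevalence table from a named list: factor -> named stratum vector
make_prev_table <- function(values, scope = "NATIONAL") {
  rows <- lapply(names(values), function(fct) {
    v <- values[[fct]]
    data.frame(scope = scope, stratum = names(v), factor = fct,
               value = unname(v), stringsAsFactors = FALSE)
  })
  prevalence_table(do.call(rbind, rows))
}

# independent oracle: exact enumeration of K independent Bernoulli factors.
# returns the sequential decomposition (contribution of factor k = mass of
# outcomes whose lowest-index positive factor is k) and the union total
enum_cascade <- function(p) {
  K <- length(p)
  contrib <- numeric(K); total <- 0
  for (m in 0:(2^K - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(K)]
    pr <- prod(ifelse(bits == 1, p, 1 - p))
    first <- which(bits == 1)[1]
    if (!is.na(first)) {
      contrib[first] <- contrib[first] + pr
      total <- total + pr
    }
  }
  list(contribution = contrib, total = total)
}

# independent oracle for Spearman's rho on distinct values: the classical
# 6*sum(d^2) formula (no ties), distinct from the Pearson-of-ranks route
rho_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# all permutations of 1..n (independent of the package's internal helper)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}
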