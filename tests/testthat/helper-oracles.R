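# Independent oracles used across the suite. Deliberately naive: exhaustive
# enumeration and direct pair counting, sharing no code with the package
# internals they check.

# zeta by exhaustive enumeration of all site combinations of each size
zeta_brute <- function(inc, max_order = nrow(inc)) {
  n <- nrow(inc)
  vapply(seq_len(max_order), function(i) {
    combos <- utils::combn(n, i, simplify = FALSE)
    mean(vapply(combos, function(rows) {
      sum(colSums(inc[rows, , drop = FALSE]) == i)
    }, numeric(1)))
  }, numeric(1))
}

# OLS + Gaussian AIC through stats::lm / stats::AIC (independent route)
fit_oracle <- function(orders, zeta) {
  fe <- stats::lm(log(zeta) ~ orders)
  fp <- stats::lm(log(zeta) ~ log(orders))
  list(aic_exp = stats::AIC(fe), aic_pow = stats::AIC(fp),
       coef_exp = stats::coef(fe), coef_pow = stats::coef(fp))
}

# C-score by direct counting over site pairs of species pairs
c_score_brute <- function(inc) {
  s <- ncol(inc)
  vals <- c()
  for (i in seq_len(s - 1)) for (j in (i + 1):s) {
    ri <- sum(inc[, i]); rj <- sum(inc[, j])
    sh <- sum(inc[, i] == 1 & inc[, j] == 1)
    vals <- c(vals, (ri - sh) * (rj - sh))
  }
  mean(vals)
}

# PIE by direct probability that two sampled individuals differ in species
pie_brute <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  same <- sum(counts * (counts - 1)) / (N * (N - 1))
  1 - same
}

# Morisita by direct conspecific pair counting within samples
morisita_brute <- function(counts) {
  N <- sum(counts)
  pairs_same_sample <- sum(counts * (counts - 1))
  length(counts) * pairs_same_sample / (N * (N - 1))
}

random_incidence <- function(n, s, p = 0.5) {
  matrix(stats::rbinom(n * s, 1L, p), n, s)
}
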