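#' Probability of interspecific encounter (PIE)
#'
#' Hurlbert's bias-corrected evenness statistic: the probability that two
#' individuals drawn at random (without replacement) from an assemblage
#' belong to different species,
#' PIE = (N/(N-1)) * (1 - sum (n_i/N)^2).
#'
#' @param counts integer vector of abundances (one assemblage).
#' @return PIE in [0, 1]; NA with a warning when fewer than 2 individuals.
#' @export
pie_index <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 2) {
    warning("PIE undefined for fewer than 2 individuals")
    return(NA_real_)
  }
  (N / (N - 1)) * (1 - sum((counts / N)^2))
}

#' Morisita index of conspecific aggregation
#'
#' For one species counted across Q samples,
#' I = Q * sum_j n_j (n_j - 1) / (N (N - 1)):
#' the probability that two conspecific individuals drawn at random fall in
#' the same sample, scaled so 1 is random placement, Q maximal aggregation
#' and 0 a maximally even spread.
#'
#' @param counts integer vector: one species' counts across the Q samples.
#' @param Q number of samples (default \code{length(counts)}).
#' @return the index; NA with a warning when the species has fewer than 2
#'   individuals.
#' @export
morisita_index <- function(counts, Q = length(counts)) {
  N <- sum(counts)
  if (N < 2) {
    warning("Morisita index undefined for species with fewer than 2 individuals")
    return(NA_real_)
  }
  Q * sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Select focal (most abundant) species
#'
#' Ranks species by pooled abundance; ties are broken by occupancy and then
#' by column order, making the selection deterministic.
#'
#' @param x abundance matrix, sites x species.
#' @param rule "top4" (the default four most abundant), "top_quartile"
#'   (floor(S/4), at least 4) or "above_median".
#' @return character vector of species names (column names).
#' @export
select_focal_species <- function(x, rule = c("top4", "top_quartile",
                                             "above_median")) {
  rule <- match.arg(rule)
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  tot <- colSums(m)
  occ <- colSums(m > 0)
  ord <- order(-tot, -occ, seq_len(ncol(m)))
  k <- switch(rule,
    top4 = {
      if (ncol(m) < 4L) stop("top4 rule needs at least 4 species")
      4L
    },
    top_quartile = max(4L, floor(0.25 * ncol(m))),
    above_median = sum(tot > stats::median(tot)))
  if (k < 2L) stop("focal rule selected fewer than 2 species")
  colnames(m)[ord[seq_len(min(k, ncol(m)))]]
}

#' Mean pairwise Spearman association of focal species
#'
#' Average of Spearman's rank correlation (average ranks for ties) between
#' the untransformed abundance vectors of all pairs of focal species.
#' Pairs involving a zero-variance vector are skipped with a warning.
#'
#' @param x abundance matrix, sites x species.
#' @param focal species names or indices (default: the four most abundant).
#' @export
mean_spearman_association <- function(x, focal = select_focal_species(x)) {
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  sub <- m[, focal, drop = FALSE]
  if (ncol(sub) < 2L) stop("need at least 2 focal species")
  if (nrow(sub) < 3L) stop("need at least 3 sites")
  rho <- c()
  skipped <- 0L
  for (i in seq_len(ncol(sub) - 1L)) for (j in (i + 1L):ncol(sub)) {
    if (stats::sd(sub[, i]) == 0 || stats::sd(sub[, j]) == 0) {
      skipped <- skipped + 1L
      next
    }
    rho <- c(rho, stats::cor(sub[, i], sub[, j], method = "spearman"))
  }
  if (skipped) warning(skipped, " zero-variance pairs skipped")
  if (!length(rho)) return(NA_real_)
  mean(rho)
}

#' Singleton proportion and matrix fill
#'
#' The proportion of species present at exactly one site, and the matrix
#' fill (total presences over sites x species, equal to mean alpha diversity
#' divided by gamma diversity).
#'
#' @param x incidence or abundance matrix.
#' @return named numeric: \code{singleton_proportion}, \code{fill}.
#' @export
singleton_and_fill <- function(x) {
  inc <- as_incidence(x, quiet = TRUE)
  occ <- colSums(inc)
  c(singleton_proportion = mean(occ == 1L),
    fill = sum(inc) / length(inc))
}

#' Null model: random table with fixed row and column totals
#'
#' Draws a random contingency table with the same row (site) and column
#' (species) totals as the observed count matrix, under the uniform
#' fixed-margins (multiple hypergeometric) law via [stats::r2dtable()].
#' This is the reference distribution for the Morisita index.
#'
#' @param x integer abundance matrix.
#' @param n number of tables (default 1).
#' @param seed optional integer seed.
#' @return a matrix (n = 1) or list of matrices.
#' @export
null_fixed_margins_table <- function(x, n = 1L, seed = NULL) {
  m <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  tabs <- stats::r2dtable(n, rowSums(m), colSums(m))
  tabs <- lapply(tabs, function(t) {
    dimnames(t) <- dimnames(m)
    t
  })
  if (n == 1L) tabs[[1]] else tabs
}

#' Null model: quantitative shuffle (c0_both)
#'
#' Individual-based shuffle that preserves, for every species, the total
#' number of individuals and the number of occupied sites, while redrawing
#' which sites are occupied and how the individuals are split among them.
#' Row (site) totals are free. This removes interspecific abundance
#' correlation and is the reference distribution for the Spearman
#' association. Uses the "c0_both" algorithm of \pkg{vegan}.
#'
#' @inheritParams null_fixed_margins_table
#' @export
null_quantitative_shuffle <- function(x, n = 1L, seed = NULL) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  sims <- vegan_sims(m, "c0_both", n, seed)
  if (n == 1L) sims[[1]] else sims
}

#' Null model: curveball swaps on a binary matrix
#'
#' Binary null model preserving all row and column sums through curveball
#' trades (random pairs of species exchange members of their non-shared
#' site sets). Reference distribution for the C-score. Uses the
#' "curveball" algorithm of \pkg{vegan}; each returned matrix is taken
#' after \code{n_swaps} trades of burn-in (default 5 x number of species).
#'
#' @inheritParams null_fixed_margins_table
#' @param n_swaps trades between the start and each returned matrix.
#' @export
null_curveball <- function(x, n = 1L, seed = NULL, n_swaps = 5L * ncol(x)) {
  inc <- as_incidence(x, quiet = TRUE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  sims <- vegan_sims(inc, "curveball", n, seed, burnin = n_swaps,
                     thin = n_swaps)
  if (n == 1L) sims[[1]] else sims
}

vegan_sims <- function(m, method, n, seed, ...) {
  nm <- vegan::nullmodel(m, method)
  arr <- stats::simulate(nm, nsim = n, seed = seed, ...)
  lapply(seq_len(n), function(i) {
    s <- arr[, , i]
    dimnames(s) <- dimnames(m)
    s
  })
}

#' Standardized effect size against a null ensemble
#'
#' SES = (observed - mean(null)) / sd(null), with the sample (n-1) standard
#' deviation. When the null ensemble is constant the SES is undefined and
#' flagged.
#'
#' @param observed observed statistic.
#' @param nulls numeric vector of the statistic over null matrices (>= 2).
#' @return list of class \code{ses_result}: observed, null_mean, null_sd,
#'   ses, n_null, undefined.
#' @export
standardized_effect_size <- function(observed, nulls) {
  nulls <- nulls[is.finite(nulls)]
  if (length(nulls) < 2L) stop("need at least 2 finite null values")
  mu <- mean(nulls)
  sd0 <- stats::sd(nulls)
  undefined <- sd0 == 0
  structure(list(observed = observed, null_mean = mu, null_sd = sd0,
                 ses = if (undefined) NA_real_ else (observed - mu) / sd0,
                 n_null = length(nulls), undefined = undefined),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, digits = 4, ...) {
  cat("SES = ", if (x$undefined) "undefined (constant null)" else
    signif(x$ses, digits),
    "  (obs ", signif(x$observed, digits), ", null ",
    signif(x$null_mean, digits), " +/- ", signif(x$null_sd, digits),
    ", n = ", x$n_null, ")\n", sep = "")
  invisible(x)
}

#' Community biodiversity property battery
#'
#' Computes, for one site-by-species abundance matrix, the property set used
#' to contrast exponential and power-law communities: pooled and mean
#' per-site PIE (evenness), mean Morisita index of the focal species
#' (conspecific aggregation, SES against fixed-margin tables), mean pairwise
#' Spearman association of the focal species (SES against the quantitative
#' shuffle), the C-score of the focal species (SES against curveball), the
#' singleton proportion and the matrix fill.
#'
#' @param x integer abundance matrix, sites x species.
#' @param focal_rule passed to [select_focal_species()].
#' @param n_null null matrices per SES (default 999).
#' @param seed integer seed for the null ensembles.
#' @param c_score_full also compute the full-matrix C-score SES (default
#'   FALSE; the battery uses the focal submatrix).
#' @return list of class \code{property_set}.
#' @export
community_properties <- function(x, focal_rule = "top4", n_null = 999L,
                                 seed = NULL, c_score_full = FALSE) {
  m <- as.matrix(x)
  if (any(m < 0) || any(m != round(m)))
    stop("abundance matrix must contain non-negative integers")
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  focal <- select_focal_species(m, rule = focal_rule)
  Q <- nrow(m)

  mor_mean <- function(mm) {
    vals <- suppressWarnings(
      vapply(focal, function(sp) morisita_index(mm[, sp], Q), numeric(1)))
    mean(vals, na.rm = TRUE)
  }
  sp_mean <- function(mm) suppressWarnings(
    mean_spearman_association(mm, focal = focal))

  obs_mor <- mor_mean(m)
  obs_sp <- sp_mean(m)
  inc_focal <- (m[, focal, drop = FALSE] > 0) + 0L
  obs_cs <- c_score(inc_focal)

  nulls_fm <- null_fixed_margins_table(m, n = n_null, seed = seed)
  ses_mor <- standardized_effect_size(
    obs_mor, vapply(nulls_fm, mor_mean, numeric(1)))
  nulls_qs <- null_quantitative_shuffle(m, n = n_null, seed = seed + 1L)
  ses_sp <- standardized_effect_size(
    obs_sp, vapply(nulls_qs, sp_mean, numeric(1)))
  nulls_cb <- null_curveball(inc_focal, n = n_null, seed = seed + 2L)
  ses_cs <- standardized_effect_size(
    obs_cs, vapply(nulls_cb, c_score, numeric(1)))

  site_pies <- suppressWarnings(apply(m, 1, pie_index))
  sf <- singleton_and_fill(m)
  structure(list(
    pie_pooled = pie_index(colSums(m)),
    pie_sample_mean = mean(site_pies, na.rm = TRUE),
    morisita_mean = obs_mor, morisita_ses = ses_mor,
    spearman_mean = obs_sp, spearman_ses = ses_sp,
    c_score = obs_cs, c_score_ses = ses_cs,
    c_score_full = if (c_score_full) c_score(m) else NULL,
    singleton_proportion = unname(sf["singleton_proportion"]),
    matrix_fill = unname(sf["fill"]),
    focal_species = focal, n_null = n_null, seed = seed),
    class = "property_set")
}

#' @export
print.property_set <- function(x, digits = 3, ...) {
  cat("Community biodiversity properties (focal:",
      paste(x$focal_species, collapse = ", "), ")\n")
  cat("  PIE pooled / sample mean: ", signif(x$pie_pooled, digits), " / ",
      signif(x$pie_sample_mean, digits), "\n", sep = "")
  cat("  Morisita mean: ", signif(x$morisita_mean, digits), "  (SES ",
      signif(x$morisita_ses$ses, digits), ")\n", sep = "")
  cat("  Spearman mean: ", signif(x$spearman_mean, digits), "  (SES ",
      signif(x$spearman_ses$ses, digits), ")\n", sep = "")
  cat("  C-score: ", signif(x$c_score, digits), "  (SES ",
      signif(x$c_score_ses$ses, digits), ")\n", sep = "")
  cat("  singletons: ", signif(x$singleton_proportion, digits),
      "   fill: ", signif(x$matrix_fill, digits), "\n", sep = "")
  invisible(x)
}
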