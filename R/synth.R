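#' Specification for a synthetic community matrix
#'
#' Describes a CESTES-like site-by-species abundance matrix with knobs that
#' map directly onto the three community biodiversity properties: the
#' relative abundance distribution (evenness), the negative-binomial
#' dispersion of within-species counts across sites (conspecific
#' aggregation), the association mode (interspecific spatial pattern) and
#' the occupancy fraction of the most widespread species (p1), which drives
#' the form of zeta decline.
#'
#' @param n_sites number of sites (15-100 is typical).
#' @param n_species number of species (10-160 is typical).
#' @param rad_shape "logseries", "lognormal" or "brokenstick".
#' @param sigma_log lognormal evenness parameter (smaller = more even).
#' @param k_agg negative-binomial dispersion of counts across sites
#'   (small = aggregated, large = near-Poisson).
#' @param association_mode "random" (one species pool shared by all sites),
#'   "gradient" (species turn over along a site gradient) or "compartment"
#'   (two disjoint pools on two site blocks, \code{n_shared} species in both).
#' @param p1_target occupancy fraction forced on the most widespread species.
#' @param site_total_mean Poisson mean of individuals per site.
#' @param n_shared shared species under "compartment" (default 2).
#' @param seed integer seed.
#' @param study_id study label (multiple datasets may share one).
#' @return list of class \code{community_spec}.
#' @export
community_spec <- function(n_sites = 30L, n_species = 40L,
                           rad_shape = "lognormal", sigma_log = 1.5,
                           k_agg = 1, association_mode = c("random",
                                                           "gradient",
                                                           "compartment"),
                           p1_target = 0.9, site_total_mean = 40,
                           n_shared = 2L, seed = 1L, study_id = "study1") {
  association_mode <- match.arg(association_mode)
  if (p1_target <= 0 || p1_target > 1) stop("p1_target must be in (0, 1]")
  if (round(p1_target * n_sites) < 1)
    stop("p1_target infeasible for this number of sites")
  structure(list(n_sites = as.integer(n_sites),
                 n_species = as.integer(n_species),
                 rad_shape = rad_shape, sigma_log = sigma_log, k_agg = k_agg,
                 association_mode = association_mode, p1_target = p1_target,
                 site_total_mean = site_total_mean,
                 n_shared = as.integer(n_shared),
                 seed = as.integer(seed), study_id = study_id),
            class = "community_spec")
}

#' Generate a synthetic community abundance matrix
#'
#' Site totals are Poisson; individuals are allocated to species by
#' probability vectors shaped by the association mode; per-species,
#' per-site gamma multipliers with shape \code{k_agg} over-disperse the
#' counts (negative-binomial mixing, small k = aggregated). The occupancy
#' of the most widespread species is then forced to \code{p1_target} by
#' thinning or augmenting its presences (and capping any other species at
#' that occupancy), which slightly perturbs column totals.
#'
#' @param spec a \code{community_spec}.
#' @return integer abundance matrix (sites x species) with attributes
#'   \code{spec} and \code{study_id}.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n <- spec$n_sites; s <- spec$n_species
  base <- generate_rad(spec$rad_shape, S = s,
                       N_total = max(10L * s, 1000L),
                       sigma_log = spec$sigma_log)$abundances
  base <- base / sum(base)
  w <- switch(spec$association_mode,
    random = matrix(base, n, s, byrow = TRUE),
    gradient = {
      pos <- seq(0, 1, length.out = n)
      centers <- seq(0, 1, length.out = s)
      ridge <- outer(pos, centers, function(p, c) stats::dnorm(p, c, 0.25))
      sweep(ridge, 2, base, "*")   # abundance-weighted turnover ridge
    },
    compartment = {
      # abundance ranks alternate between the two compartments so that the
      # most abundant species are split across them (segregated focal pairs)
      half <- n %/% 2L
      own <- s - spec$n_shared
      wt <- matrix(0, n, s)
      for (j in seq_len(own)) {
        rows <- if (j %% 2L == 1L) seq_len(half) else (half + 1L):n
        wt[rows, j] <- base[j]
      }
      if (spec$n_shared > 0L)
        wt[, own + seq_len(spec$n_shared)] <-
          matrix(base[own + seq_len(spec$n_shared)], n, spec$n_shared,
                 byrow = TRUE)
      wt
    })
  # over-dispersion: gamma(k, k) multipliers -> NB mixing of the multinomial
  mult <- matrix(stats::rgamma(n * s, shape = spec$k_agg,
                               rate = spec$k_agg), n, s)
  w <- w * mult
  counts <- matrix(0L, n, s)
  totals <- stats::rpois(n, spec$site_total_mean)
  for (t in seq_len(n)) {
    wt <- w[t, ]
    if (totals[t] > 0 && sum(wt) > 0)
      counts[t, ] <- stats::rmultinom(1, totals[t], wt)
  }
  counts <- force_p1(counts, spec$p1_target)
  dimnames(counts) <- list(paste0("site", seq_len(n)),
                           paste0("sp", seq_len(s)))
  attr(counts, "spec") <- spec
  attr(counts, "study_id") <- spec$study_id
  counts
}

# force the occupancy of the most widespread species to round(p1 * n_sites)
# and cap every other species at that occupancy
force_p1 <- function(counts, p1_target) {
  n <- nrow(counts)
  target <- max(1L, round(p1_target * n))
  occ <- colSums(counts > 0)
  top <- which.max(occ)
  for (j in seq_len(ncol(counts))) {
    limit <- if (j == top) target else target
    oj <- sum(counts[, j] > 0)
    if (oj > limit) {
      drop <- sample(which(counts[, j] > 0), oj - limit)
      counts[drop, j] <- 0L
    }
  }
  # top species raised to the exact target occupancy
  oj <- sum(counts[, top] > 0)
  if (oj < target) {
    absent <- which(counts[, top] == 0L)
    add <- sample(absent, target - oj)
    mean_pos <- max(1L, round(mean(counts[counts[, top] > 0, top])))
    counts[add, top] <- pmax(1L, stats::rpois(length(add), mean_pos))
  }
  counts
}

#' Generate a labelled collection of synthetic studies
#'
#' Builds a mixture of exponential-inducing datasets (compartmented
#' association, moderate p1, strong aggregation) and power-law-inducing
#' datasets (random association, near-saturated most widespread species,
#' weak aggregation) with known ground-truth labels, for end-to-end
#' validation of the classification and property-comparison pipeline.
#' Consecutive datasets share a study id so that the random-intercept term
#' of [compare_forms()] is exercised.
#'
#' @param n_datasets total datasets (>= 2; half per group).
#' @param seed master seed; per-dataset seeds are derived from it and the
#'   dataset id.
#' @param exp_spec,pow_spec named lists overriding the group templates.
#' @param datasets_per_study how many datasets share a study id (default 2).
#' @return list of class \code{study_collection}; each element has
#'   \code{matrix}, \code{truth} ("exponential"/"power"), \code{dataset_id},
#'   \code{study_id}.
#' @export
generate_study_collection <- function(n_datasets = 80L, seed = 1L,
                                      exp_spec = list(), pow_spec = list(),
                                      datasets_per_study = 2L) {
  if (n_datasets < 2L) stop("need at least 2 datasets")
  n_exp <- n_datasets %/% 2L
  template <- function(truth, overrides, i) {
    base <- if (truth == "exponential") {
      list(n_sites = 30L, n_species = 40L, rad_shape = "lognormal",
           sigma_log = 1.5, k_agg = 0.3, association_mode = "compartment",
           p1_target = 0.5, site_total_mean = 40)
    } else {
      list(n_sites = 30L, n_species = 40L, rad_shape = "lognormal",
           sigma_log = 1.5, k_agg = 2, association_mode = "random",
           p1_target = 0.95, site_total_mean = 40)
    }
    base[names(overrides)] <- overrides
    base
  }
  out <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    truth <- if (i <= n_exp) "exponential" else "power"
    ov <- if (truth == "exponential") exp_spec else pow_spec
    id <- sprintf("ds%03d", i)
    study <- sprintf("study%03d", (i - 1L) %/% datasets_per_study + 1L)
    args <- template(truth, ov, i)
    args$seed <- derive_seed(id, seed)
    args$study_id <- study
    spec <- do.call(community_spec, args)
    out[[i]] <- list(matrix = generate_community(spec), truth = truth,
                     dataset_id = id, study_id = study, spec = spec)
  }
  structure(out, class = "study_collection", seed = seed)
}
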