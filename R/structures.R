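#' Simulate archetypal incidence-matrix structures
#'
#' Generates 20 x 20 (by default) site-by-species incidence matrices that
#' encode contrasting interspecific spatial associations, at a matrix fill
#' near 0.5 so that fill itself does not drive the form of zeta decline:
#' \describe{
#'   \item{nested}{fully nested subsets: occupancies decline from n_sites
#'     towards 1 and each species' site set is contained in every more
#'     widespread species' set.}
#'   \item{gradient_even}{equal niche-width ranges with evenly spaced starts
#'     along the site gradient (species sorting).}
#'   \item{turnover_compartmented}{two communities on disjoint site blocks
#'     with exactly 2 species shared between them.}
#'   \item{clementsian_strict}{two fully separated communities, no shared
#'     species.}
#'   \item{continuous}{individual-based: Poisson site totals allocated to
#'     species by a common lognormal probability vector, binarized.}
#'   \item{ecotone}{individual-based sampling across a boundary: species 1-9
#'     and 12-20 follow opposed lognormal gradients, species 10-11 are broad
#'     tolerance generalists present with probability 0.9.}
#'   \item{random}{iid Bernoulli(target_fill) occupancy.}
#' }
#' Fill is exactly controllable for the idealized kinds and approximate for
#' the individual-based ones.
#'
#' @param kind structure name (see above).
#' @param n_sites,n_species matrix dimensions (default 20 x 20).
#' @param target_fill fraction of presences for fill-controlled kinds
#'   (default 0.5).
#' @param seed optional integer seed.
#' @param site_total_mean Poisson mean for individual-based kinds (default 50).
#' @param sigma_log lognormal SD for species probabilities (default 1).
#' @param p_generalist presence probability of the ecotone generalists
#'   (default 0.9).
#' @return an incidence matrix (0/1) with dimnames.
#' @export
simulate_structure <- function(kind = c("nested", "gradient_even",
                                        "turnover_compartmented", "continuous",
                                        "ecotone", "random",
                                        "clementsian_strict"),
                               n_sites = 20L, n_species = 20L,
                               target_fill = 0.5, seed = NULL,
                               site_total_mean = 50, sigma_log = 1,
                               p_generalist = 0.9) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_sites); s <- as.integer(n_species)
  total <- round(target_fill * n * s)
  m <- switch(kind,
    nested = {
      # the most widespread species stays saturated (selective extinction
      # removes species from sites, never the top species from anywhere);
      # the rest decline linearly, adjusted to hit the target fill
      rest <- round_preserve_total(
        seq(n - 1, 1, length.out = s - 1) * (total - n) /
          sum(seq(n - 1, 1, length.out = s - 1)),
        total - n, min_each = 1L)
      occ <- c(n, pmin(sort(rest, decreasing = TRUE), n - 1L))
      # left-aligned ranges: species j present at sites 1..occ[j]
      mat <- matrix(0L, n, s)
      for (j in seq_len(s)) mat[seq_len(occ[j]), j] <- 1L
      mat
    },
    gradient_even = {
      width <- max(1L, round(target_fill * n))
      starts <- round(seq(1, n - width + 1, length.out = s))
      mat <- matrix(0L, n, s)
      for (j in seq_len(s)) mat[starts[j] + seq_len(width) - 1L, j] <- 1L
      mat
    },
    turnover_compartmented = compartment_matrix(n, s, n_shared = 2L),
    clementsian_strict = compartment_matrix(n, s, n_shared = 0L),
    continuous = {
      pr <- sort(stats::rlnorm(s, 0, sigma_log), decreasing = TRUE)
      individual_based(n, s, site_total_mean,
                       matrix(pr / sum(pr), n, s, byrow = TRUE))
    },
    ecotone = {
      if (s < 12L) stop("ecotone structure needs at least 12 species")
      gener <- c(s %/% 2L, s %/% 2L + 1L)      # species 10-11 for s = 20
      guild1 <- seq_len(gener[1] - 1L)
      guild2 <- setdiff(seq_len(s), c(guild1, gener))
      pos <- seq(0.5, n - 0.5, length.out = n)
      w <- matrix(0, n, s)
      centers <- function(k) seq(1, n / 2, length.out = k)
      c1 <- centers(length(guild1)); c2 <- centers(length(guild2))
      for (idx in seq_along(guild1))
        w[, guild1[idx]] <- stats::dlnorm(pos / c1[idx],
                                          meanlog = 0, sdlog = sigma_log)
      for (idx in seq_along(guild2))          # mirrored gradient
        w[, guild2[idx]] <- rev(stats::dlnorm(pos / c2[idx],
                                              meanlog = 0, sdlog = sigma_log))
      w[, gener] <- 1e-12                      # generalists handled below
      w <- w / rowSums(w)
      mat <- individual_based(n, s, site_total_mean, w)
      for (g in gener) mat[, g] <- stats::rbinom(n, 1L, p_generalist)
      mat
    },
    random = matrix(stats::rbinom(n * s, 1L, target_fill), n, s))
  dimnames(m) <- list(paste0("site", seq_len(n)), paste0("sp", seq_len(s)))
  m
}

# two site blocks; n_shared species span both, the rest split between blocks
compartment_matrix <- function(n, s, n_shared) {
  half_sites <- n %/% 2L
  own <- s - n_shared
  n1 <- ceiling(own / 2); n2 <- own - n1
  mat <- matrix(0L, n, s)
  mat[seq_len(half_sites), seq_len(n1)] <- 1L
  mat[(half_sites + 1L):n, n1 + seq_len(n2)] <- 1L
  if (n_shared > 0L) {
    shared <- own + seq_len(n_shared)
    # shared species occupy half of each block, keeping overall fill at ~0.5
    occ_half <- max(1L, half_sites %/% 2L)
    for (j in shared) {
      mat[seq_len(occ_half), j] <- 1L
      mat[half_sites + seq_len(occ_half), j] <- 1L
    }
  }
  mat
}

# Poisson site totals allocated among species by per-site probability rows
individual_based <- function(n, s, site_total_mean, probs) {
  counts <- matrix(0L, n, s)
  totals <- stats::rpois(n, site_total_mean)
  for (t in seq_len(n))
    if (totals[t] > 0)
      counts[t, ] <- stats::rmultinom(1, totals[t], probs[t, ])
  (counts > 0) + 0L
}

#' Append a saturated species to an incidence matrix
#'
#' Adds one species present at every site. A single such cosmopolitan
#' species can flip the classified form of decline from exponential to
#' power law; at every order it contributes exactly 1 shared species.
#'
#' @param x incidence matrix.
#' @export
add_saturated_species <- function(x) {
  inc <- as_incidence(x, quiet = TRUE)
  out <- cbind(inc, saturated = 1L)
  colnames(out) <- c(colnames(inc), "saturated")
  out
}

#' Checkerboard C-score
#'
#' Mean over species pairs of (r_i - S_ij)(r_j - S_ij), where r are species
#' occupancies and S_ij the number of sites shared by the pair. Large values
#' indicate segregated (checkerboard-like) distributions; identical site
#' sets give 0.
#'
#' @param x incidence matrix (abundances are binarized).
#' @param species_subset optional indices or names restricting the pairs
#'   (the empirical battery uses the four most abundant species).
#' @return mean checkerboard units per species pair.
#' @export
c_score <- function(x, species_subset = NULL) {
  inc <- as_incidence(x, quiet = TRUE)
  if (!is.null(species_subset)) inc <- inc[, species_subset, drop = FALSE]
  s <- ncol(inc)
  if (s < 2L) stop("need at least 2 species for the C-score")
  r <- colSums(inc)
  share <- crossprod(inc)                 # S_ij = shared sites per pair
  cb <- (r - share) * t(r - share)        # (r_i - S_ij)(r_j - S_ij)
  sum(cb[upper.tri(cb)]) / (s * (s - 1) / 2)
}

#' One fill-preserving perturbation step
#'
#' Picks a site (row) uniformly at random and moves one presence within it:
#' a presence of a species with at least two occupancies (so no species is
#' lost from the matrix) becomes an absence, and a previously absent species
#' in that site becomes present. Row sums, total fill and the set of species
#' with at least one occupancy are all preserved; column sums are free to
#' change, which progressively randomizes interspecific association.
#' Rows with no feasible swap are redrawn (bounded retries).
#'
#' @param x incidence matrix.
#' @param max_tries retry bound before declaring saturation (default 100).
#' @return the perturbed matrix.
#' @export
perturb_step <- function(x, max_tries = 100L) {
  inc <- x
  n <- nrow(inc)
  occ <- colSums(inc)
  for (try in seq_len(max_tries)) {
    row <- sample.int(n, 1L)
    donors <- which(inc[row, ] == 1L & occ >= 2L)
    absents <- which(inc[row, ] == 0L)
    if (length(donors) && length(absents)) {
      d <- if (length(donors) == 1L) donors else sample(donors, 1L)
      a <- if (length(absents) == 1L) absents else sample(absents, 1L)
      inc[row, d] <- 0L
      inc[row, a] <- 1L
      return(inc)
    }
  }
  stop("no feasible swap found: matrix is saturated or species are all singletons")
}

#' Perturbation experiment: form of decline versus C-score
#'
#' Starting from a structured matrix, repeatedly applies the fill-preserving
#' perturbation of [perturb_step()] and records, at every iteration, the
#' C-score and the exponential Akaike weight of the first-10-order zeta
#' decline fit. The experiment is replicated \code{n_reps} times (fresh
#' structure and perturbation stream per replicate) and the mean trajectory
#' reported alongside the per-replicate records.
#'
#' @param kind structure passed to [simulate_structure()] (or a ready-made
#'   incidence matrix used as the fixed starting point of every replicate).
#' @param n_iter perturbation iterations per replicate (default 100).
#' @param n_reps replicates (default 100).
#' @param seed integer seed controlling the whole experiment.
#' @param n_orders zeta orders used for classification (default 10).
#' @param ... passed to [simulate_structure()].
#' @return list of class \code{perturbation_trajectory}: \code{records}
#'   (data frame: replicate, iteration [0 = unperturbed], c_score,
#'   waic_exponential), \code{mean_trajectory} (per-iteration means),
#'   \code{kind}, \code{seed}.
#' @export
perturbation_experiment <- function(kind, n_iter = 100L, n_reps = 100L,
                                    seed = NULL, n_orders = 10L, ...) {
  if (!is.null(seed)) set.seed(seed)
  fixed <- is.matrix(kind)
  recs <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    m <- if (fixed) kind else simulate_structure(kind, ...)
    cs <- numeric(n_iter + 1L)
    we <- numeric(n_iter + 1L)
    cs[1] <- c_score(m)
    we[1] <- waic_exp_fast(m, n_orders)
    for (it in seq_len(n_iter)) {
      m <- perturb_step(m)
      cs[it + 1L] <- c_score(m)
      we[it + 1L] <- waic_exp_fast(m, n_orders)
    }
    recs[[r]] <- data.frame(replicate = r, iteration = 0:n_iter,
                            c_score = cs, waic_exponential = we)
  }
  records <- do.call(rbind, recs)
  mean_traj <- stats::aggregate(records[c("c_score", "waic_exponential")],
                                by = list(iteration = records$iteration), mean)
  structure(list(records = records, mean_trajectory = mean_traj,
                 kind = if (fixed) "matrix" else kind, seed = seed),
            class = "perturbation_trajectory")
}

#' @export
print.perturbation_trajectory <- function(x, ...) {
  cat("Perturbation experiment (", x$kind, "): ",
      max(x$records$replicate), " replicates x ",
      max(x$records$iteration), " iterations\n", sep = "")
  cat("mean wAIC(exponential): start ",
      round(x$mean_trajectory$waic_exponential[1], 3), " -> end ",
      round(utils::tail(x$mean_trajectory$waic_exponential, 1), 3), "\n",
      sep = "")
  cat("mean C-score: start ", round(x$mean_trajectory$c_score[1], 3),
      " -> end ", round(utils::tail(x$mean_trajectory$c_score, 1), 3), "\n",
      sep = "")
  invisible(x)
}

# fast path used inside simulation loops: exact zeta + log-OLS weights,
# skipping input re-validation
waic_exp_fast <- function(inc, n_orders) {
  n <- nrow(inc)
  o <- colSums(inc)
  ords <- seq_len(min(n_orders, n))
  zeta <- vapply(ords, function(i) sum(exp(lchoose(o, i) - lchoose(n, i))),
                 numeric(1))
  keep <- zeta > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- fit_decline_models(ords[keep], zeta[keep])
  if (fit$degenerate) return(NA_real_)
  fit$waic[["exponential"]]
}

#' Force the occupancy of the most widespread species
#'
#' Sets the occupancy of the currently most widespread species to exactly
#' round(p1 * n_sites) presences (placed at random when augmenting,
#' removed at random when thinning) and caps every other species at that
#' occupancy, so that p1 is the occupancy fraction of the most widespread
#' species in the result.
#'
#' @param x incidence matrix.
#' @param p1 target occupancy fraction in (0, 1].
#' @export
force_top_occupancy <- function(x, p1) {
  inc <- as_incidence(x, quiet = TRUE)
  n <- nrow(inc)
  target <- max(1L, round(p1 * n))
  occ <- colSums(inc)
  top <- which.max(occ)
  for (j in seq_len(ncol(inc))[-top]) {
    if (occ[j] > target) {
      drop <- sample(which(inc[, j] == 1L), occ[j] - target)
      inc[drop, j] <- 0L
    }
  }
  cur <- sum(inc[, top])
  if (cur > target) {
    inc[sample(which(inc[, top] == 1L), cur - target), top] <- 0L
  } else if (cur < target) {
    inc[sample(which(inc[, top] == 0L), target - cur), top] <- 1L
  }
  inc
}

#' Occupancy threshold for the switch to power-law decline
#'
#' Random-fill incidence matrices are generated with the most widespread
#' species forced to an occupancy fraction p1; each matrix is classified by
#' the first-10-order zeta decline fit. As p1 grows the majority
#' classification switches from exponential to power law; the smallest p1
#' on the grid at which power law is the majority is the threshold.
#'
#' @param p1_grid occupancy fractions to scan (default 0.50 to 1.00 by 0.05).
#' @param n_reps replicate matrices per level (default 200).
#' @param n_sites,n_species matrix dimensions (default 20 x 20).
#' @param fill Bernoulli fill probability (default 0.5).
#' @param seed integer seed.
#' @param n_orders orders used in classification (default 10).
#' @return list of class \code{occupancy_threshold}: \code{table} (p1,
#'   prop_power), \code{threshold_p1} (smallest p1 with power majority, NA
#'   if none).
#' @export
occupancy_threshold_experiment <- function(p1_grid = seq(0.5, 1, by = 0.05),
                                           n_reps = 200L, n_sites = 20L,
                                           n_species = 20L, fill = 0.5,
                                           seed = NULL, n_orders = 10L) {
  if (!is.null(seed)) set.seed(seed)
  prop_power <- vapply(p1_grid, function(p1) {
    wins <- vapply(seq_len(n_reps), function(r) {
      m <- matrix(stats::rbinom(n_sites * n_species, 1L, fill),
                  n_sites, n_species)
      m <- force_top_occupancy(m, p1)
      w <- waic_exp_fast(m, n_orders)
      !is.na(w) && w < 0.5
    }, logical(1))
    mean(wins)
  }, numeric(1))
  hit <- which(prop_power > 0.5)
  structure(list(table = data.frame(p1 = p1_grid, prop_power = prop_power),
                 threshold_p1 = if (length(hit)) p1_grid[min(hit)] else
                   NA_real_,
                 n_reps = n_reps, seed = seed),
            class = "occupancy_threshold")
}

#' @export
print.occupancy_threshold <- function(x, ...) {
  cat("Occupancy threshold experiment (", x$n_reps, " reps/level)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("power-law majority from p1 =", x$threshold_p1, "\n")
  invisible(x)
}
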