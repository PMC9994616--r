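#' Coerce a community table to a binary incidence matrix
#'
#' Sites are rows, species are columns. Abundance values are binarized
#' (any count > 0 becomes a presence). Species with zero occupancy are
#' retained (they count towards gamma diversity but contribute nothing
#' to zeta); a message flags them.
#'
#' @param x a matrix or data frame of non-negative numbers, sites in rows.
#' @param quiet suppress the zero-occupancy message.
#' @return an integer 0/1 matrix with site and species dimnames.
#' @export
as_incidence <- function(x, quiet = FALSE) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("community matrix must be numeric")
  if (any(!is.finite(m))) stop("community matrix contains non-finite values")
  if (any(m < 0)) stop("community matrix contains negative values")
  if (nrow(m) < 2L) stop("at least 2 sites are required")
  if (ncol(m) < 1L) stop("at least 1 species is required")
  inc <- (m > 0) + 0L
  if (is.null(rownames(inc))) rownames(inc) <- paste0("site", seq_len(nrow(inc)))
  if (is.null(colnames(inc))) colnames(inc) <- paste0("sp", seq_len(ncol(inc)))
  empty <- colSums(inc) == 0L
  if (any(empty) && !quiet)
    message(sum(empty), " species have zero occupancy and contribute nothing to zeta")
  inc
}

#' Exact zeta diversity decline
#'
#' Zeta diversity of order i is the expected number of species shared by i
#' sites. The expectation over all C(n, i) site combinations has a closed
#' combinatorial form: a species occupying o sites is present in all members
#' of C(o, i) of those combinations, so
#' zeta_i = sum_s C(o_s, i) / C(n, i).
#' This is evaluated through log-binomial coefficients, without enumerating
#' combinations.
#'
#' @param x incidence (or abundance, binarized) matrix, sites x species.
#' @param max_order largest order to compute (defaults to the number of sites).
#' @return an object of class \code{zeta_decline}: a list with \code{orders},
#'   \code{zeta} and \code{method = "exact"}.
#' @seealso [zeta_sample()] for the Monte-Carlo counterpart,
#'   [fit_decline()] to model the decline.
#' @examples
#' m <- matrix(rbinom(40, 1, 0.5), 5, 8)
#' zeta_exact(m, max_order = 5)
#' @export
zeta_exact <- function(x, max_order = nrow(x)) {
  inc <- as_incidence(x, quiet = TRUE)
  n <- nrow(inc)
  if (max_order < 1L || max_order > n)
    stop("max_order must be between 1 and the number of sites (", n, ")")
  o <- colSums(inc)
  orders <- seq_len(max_order)
  zeta <- vapply(orders, function(i) {
    sum(exp(lchoose(o, i) - lchoose(n, i)))
  }, numeric(1))
  new_zeta_decline(orders, zeta, method = "exact")
}

#' Monte-Carlo zeta diversity decline
#'
#' Estimates zeta_i as the mean number of shared species over random draws of
#' i sites (without replacement). Converges to [zeta_exact()] as
#' \code{n_draws} grows; provided for validation rather than routine use.
#'
#' @inheritParams zeta_exact
#' @param n_draws number of random site combinations per order.
#' @param seed optional integer seed for reproducibility.
#' @export
zeta_sample <- function(x, max_order = nrow(x), n_draws = 1000L, seed = NULL) {
  inc <- as_incidence(x, quiet = TRUE)
  n <- nrow(inc)
  if (max_order < 1L || max_order > n)
    stop("max_order must be between 1 and the number of sites (", n, ")")
  if (n_draws < 1L) stop("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  zeta <- vapply(seq_len(max_order), function(i) {
    shared <- vapply(seq_len(n_draws), function(r) {
      rows <- sample.int(n, i)
      sum(colSums(inc[rows, , drop = FALSE]) == i)
    }, numeric(1))
    mean(shared)
  }, numeric(1))
  z <- new_zeta_decline(seq_len(max_order), zeta, method = "monte-carlo")
  z$n_draws <- n_draws
  z$seed <- seed
  z
}

new_zeta_decline <- function(orders, zeta, method) {
  structure(list(orders = as.integer(orders), zeta = as.numeric(zeta),
                 method = method),
            class = "zeta_decline")
}

#' @export
print.zeta_decline <- function(x, digits = 4, ...) {
  cat("Zeta diversity decline (", x$method, "), orders 1-",
      max(x$orders), "\n", sep = "")
  z <- round(x$zeta, digits)
  names(z) <- x$orders
  print(z)
  invisible(x)
}

#' Maximum usable zeta order for a community
#'
#' The decline can only be informatively modelled up to orders where the
#' most widespread species still has an appreciable chance of co-occurring.
#' With p1 the occupancy fraction of the most widespread species, the order
#' at which its expected contribution falls below 5 percent is
#' ln(0.05)/ln(p1). The usable maximum is the smaller of that and the number
#' of sites the most widespread species occupies, but never fewer than
#' \code{min_orders} orders (and never more than the number of sites). When
#' p1 = 1 all sites can be used.
#'
#' @inheritParams zeta_exact
#' @param min_orders floor on the number of orders (default 5).
#' @return an integer number of orders.
#' @export
select_max_order <- function(x, min_orders = 5L) {
  inc <- as_incidence(x, quiet = TRUE)
  n <- nrow(inc)
  o_max <- max(colSums(inc))
  if (o_max == 0L) stop("matrix has no presences")
  p1 <- o_max / n
  if (p1 >= 1) return(n)
  m <- max(min_orders, min(o_max, floor(log(0.05) / log(p1))))
  as.integer(min(m, n))
}
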