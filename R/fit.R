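#' Fit and compare exponential and power-law models of zeta decline
#'
#' The decline of zeta diversity with order i is modelled under two
#' competing forms:
#' \describe{
#'   \item{exponential}{zeta_i = a * exp(-b * i), linearized as
#'     log(zeta_i) = log(a) - b * i}
#'   \item{power law}{zeta_i = c * i^-d, linearized as
#'     log(zeta_i) = log(c) - d * log(i)}
#' }
#' Both are fitted by ordinary least squares on the log scale, over the same
#' orders. Relative support is expressed as Akaike weights from a Gaussian
#' log-likelihood of the log-scale residuals with 3 parameters per model
#' (intercept, slope, residual variance). The form with the larger weight
#' wins; a difference of less than 2 AIC units is flagged as ambiguous.
#'
#' Orders at which zeta is zero are dropped (the log is undefined there);
#' at least 3 positive orders are required.
#'
#' @param x an incidence/abundance matrix (sites x species) or a
#'   \code{zeta_decline} object.
#' @param n_orders number of zeta orders used in the fit when \code{x} is a
#'   matrix (default 10, the convention used to classify communities). If the
#'   matrix has fewer sites than \code{n_orders} the order count falls back to
#'   [select_max_order()] with a warning.
#' @param min_orders floor passed to [select_max_order()] in the fallback.
#' @return an object of class \code{decline_fit} with components
#'   \code{zeta} (the decline used), \code{orders_used}, \code{models}
#'   (per-form parameters, log-scale RSS, AIC), \code{waic} (named Akaike
#'   weights summing to 1), \code{winner}, \code{delta_aic},
#'   \code{ambiguous} and \code{degenerate} (TRUE when the log-zeta sequence
#'   is constant so the forms cannot be told apart).
#' @examples
#' set.seed(1)
#' m <- matrix(rbinom(400, 1, 0.5), 20, 20)
#' f <- fit_decline(m)
#' f
#' coef(f)
#' @seealso [classify_form()], [akaike_weights()], [zeta_exact()]
#' @export
fit_decline <- function(x, n_orders = 10L, min_orders = 5L) {
  if (inherits(x, "zeta_decline")) {
    z <- x
  } else {
    inc <- as_incidence(x, quiet = TRUE)
    n <- nrow(inc)
    if (n < n_orders) {
      n_orders <- select_max_order(inc, min_orders = min_orders)
      warning("fewer sites than requested orders; using ", n_orders,
              " orders from select_max_order()")
    }
    z <- zeta_exact(inc, max_order = n_orders)
  }
  keep <- z$zeta > 0
  if (any(!keep))
    warning(sum(!keep), " orders with zeta = 0 dropped before log-linear fit")
  orders <- z$orders[keep]
  zeta <- z$zeta[keep]
  if (length(orders) < 3L)
    stop("need at least 3 orders with positive zeta to fit the decline models")
  fit <- fit_decline_models(orders, zeta)
  structure(c(list(zeta = z), fit), class = "decline_fit")
}

# OLS on the log scale for both forms; shared by fit_decline and the
# simulation experiments (which call it in tight loops).
fit_decline_models <- function(orders, zeta) {
  y <- log(zeta)
  m <- length(y)
  ols <- function(pred) {
    xb <- mean(pred); yb <- mean(y)
    sxx <- sum((pred - xb)^2)
    slope <- if (sxx > 0) sum((pred - xb) * (y - yb)) / sxx else 0
    intercept <- yb - slope * xb
    resid <- y - (intercept + slope * pred)
    rss <- sum(resid^2)
    aic <- m * log(2 * pi * max(rss, 1e-300) / m) + m + 2 * 3
    list(intercept = intercept, slope = slope, rss = rss, aic = aic,
         fitted_log = intercept + slope * pred, resid = resid)
  }
  fe <- ols(orders)
  fp <- ols(log(orders))
  degenerate <- stats::var(y) < 1e-20
  aics <- c(exponential = fe$aic, power = fp$aic)
  w <- akaike_weights(aics)
  winner <- names(w)[which.max(w)]
  list(
    orders_used = orders,
    models = list(
      exponential = list(a = exp(fe$intercept), b = -fe$slope,
                         rss_log = fe$rss, aic = fe$aic,
                         fitted_log = fe$fitted_log, resid_log = fe$resid),
      power = list(c = exp(fp$intercept), d = -fp$slope,
                   rss_log = fp$rss, aic = fp$aic,
                   fitted_log = fp$fitted_log, resid_log = fp$resid)),
    waic = w,
    winner = winner,
    delta_aic = abs(diff(aics)),
    ambiguous = abs(diff(aics)) < 2,
    degenerate = degenerate)
}

#' Akaike weights for a set of candidate models
#'
#' The relative likelihood of each model is exp(-0.5 * dAIC) with dAIC the
#' difference from the smallest AIC; weights are these values normalized to
#' sum to 1. A weight of 1 means no support for the alternatives; 0.5 over
#' two models means equal support. Weights are invariant to adding any
#' constant to all AICs.
#'
#' @param aics numeric vector (length >= 2) of finite AIC values.
#' @return numeric vector of weights summing to 1, names preserved.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 2L) stop("need at least 2 AIC values")
  if (any(!is.finite(aics))) stop("AIC values must be finite")
  rel <- exp(-0.5 * (aics - min(aics)))
  rel / sum(rel)
}

#' Classify the form of multisite similarity decline
#'
#' Convenience wrapper around [fit_decline()] using the first
#' \code{n_orders} orders of the exact zeta decline; returns the fitted
#' object, whose \code{$winner} is "exponential" or "power" and whose
#' \code{$waic} holds the Akaike weights.
#'
#' @inheritParams fit_decline
#' @export
classify_form <- function(x, n_orders = 10L, min_orders = 5L) {
  fit_decline(x, n_orders = n_orders, min_orders = min_orders)
}

#' @export
print.decline_fit <- function(x, digits = 4, ...) {
  cat("Multisite similarity (zeta) decline fit\n")
  cat("  orders used: ", paste(range(x$orders_used), collapse = "-"),
      " (", length(x$orders_used), " orders)\n", sep = "")
  cat("  winner: ", x$winner,
      if (x$ambiguous) "  [ambiguous: delta AIC < 2]" else "", "\n", sep = "")
  cat("  wAIC: exponential = ", signif(x$waic[["exponential"]], digits),
      ", power = ", signif(x$waic[["power"]], digits), "\n", sep = "")
  e <- x$models$exponential; p <- x$models$power
  cat("  exponential: a = ", signif(e$a, digits), ", b = ", signif(e$b, digits),
      "  (AIC ", signif(e$aic, digits), ")\n", sep = "")
  cat("  power:       c = ", signif(p$c, digits), ", d = ", signif(p$d, digits),
      "  (AIC ", signif(p$aic, digits), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.decline_fit <- function(object, ...) {
  e <- object$models$exponential; p <- object$models$power
  tab <- data.frame(
    form = c("exponential", "power"),
    par1 = c(e$a, p$c), par2 = c(e$b, p$d),
    rss_log = c(e$rss_log, p$rss_log),
    aic = c(e$aic, p$aic),
    waic = as.numeric(object$waic[c("exponential", "power")]))
  structure(list(table = tab, winner = object$winner,
                 ambiguous = object$ambiguous,
                 degenerate = object$degenerate,
                 orders_used = object$orders_used,
                 zeta = object$zeta),
            class = "summary.decline_fit")
}

#' @export
print.summary.decline_fit <- function(x, digits = 4, ...) {
  cat("Zeta decline over orders", paste(range(x$orders_used), collapse = "-"),
      "\n")
  print(x$table, digits = digits, row.names = FALSE)
  cat("winner:", x$winner, if (x$ambiguous) "(ambiguous)" else "", "\n")
  if (x$degenerate) cat("note: constant zeta; forms indistinguishable\n")
  invisible(x)
}

#' @export
coef.decline_fit <- function(object, form = c("winner", "exponential", "power"),
                             ...) {
  form <- match.arg(form)
  if (form == "winner") form <- object$winner
  if (form == "exponential") {
    e <- object$models$exponential
    c(a = e$a, b = e$b)
  } else {
    p <- object$models$power
    c(c = p$c, d = p$d)
  }
}

#' @export
predict.decline_fit <- function(object, orders = object$orders_used,
                                form = c("winner", "exponential", "power"),
                                ...) {
  form <- match.arg(form)
  if (form == "winner") form <- object$winner
  if (form == "exponential") {
    e <- object$models$exponential
    e$a * exp(-e$b * orders)
  } else {
    p <- object$models$power
    p$c * orders^(-p$d)
  }
}

#' @export
residuals.decline_fit <- function(object,
                                  form = c("winner", "exponential", "power"),
                                  ...) {
  form <- match.arg(form)
  if (form == "winner") form <- object$winner
  object$models[[form]]$resid_log
}

#' @export
fitted.decline_fit <- function(object,
                               form = c("winner", "exponential", "power"),
                               ...) {
  exp(object$models[[if ((f <- match.arg(form)) == "winner") object$winner
                     else f]]$fitted_log)
}

#' Plot a fitted zeta decline
#'
#' Observed zeta against order with the two fitted forms overlaid.
#'
#' @param x a \code{decline_fit} object.
#' @param log2 logical; draw the y axis on the log scale.
#' @param ... passed to [graphics::plot()].
#' @export
plot.decline_fit <- function(x, log2 = FALSE, ...) {
  ord <- x$orders_used
  z <- x$zeta$zeta[match(ord, x$zeta$orders)]
  graphics::plot(ord, z, pch = 19, xlab = "zeta order",
                 ylab = "zeta diversity", log = if (log2) "y" else "", ...)
  grid_ord <- seq(min(ord), max(ord), length.out = 100)
  graphics::lines(grid_ord, predict(x, grid_ord, form = "exponential"),
                  col = "steelblue", lwd = 2)
  graphics::lines(grid_ord, predict(x, grid_ord, form = "power"),
                  col = "firebrick", lwd = 2, lty = 2)
  graphics::legend("topright", bty = "n", lwd = 2, lty = c(1, 2),
                   col = c("steelblue", "firebrick"),
                   legend = sprintf("%s (wAIC %.2f)", c("exponential", "power"),
                                    x$waic[c("exponential", "power")]))
  invisible(x)
}
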