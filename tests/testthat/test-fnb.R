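test_that("expected RADs conserve totals and have their closed-form values", {
  bs <- generate_rad("brokenstick", S = 3, N_total = 18)
  expect_identical(bs$abundances, c(11L, 5L, 2L))
  for (shape in c("logseries", "lognormal", "brokenstick")) {
    r <- generate_rad(shape, S = 40, N_total = 5000)
    expect_identical(sum(r$abundances), 5000L)
    expect_true(all(r$abundances >= 1))
    expect_true(all(diff(r$abundances) <= 0))
  }
  expect_error(generate_rad("logseries", S = 100, N_total = 100))
})

test_that("RAD evenness orders logseries < lognormal < brokenstick", {
  rads <- lapply(c("logseries", "lognormal", "brokenstick"),
                 generate_rad, S = 300, N_total = 211000)
  pies <- vapply(rads, function(r) pie_index(r$abundances), numeric(1))
  expect_true(pies[1] < pies[2] && pies[2] < pies[3])
})

test_that("FNB presence probability has its analytic limits", {
  # sampling the whole extent
  expect_equal(fnb_presence_probability(5, 2, 1), 1)
  # a single individual is present with probability alpha
  for (k in c(0.1, 1, 50)) {
    expect_equal(fnb_presence_probability(1, k, 0.3), 0.3, tolerance = 1e-12)
    expect_equal(fnb_presence_probability(1, k, 0.07), 0.07, tolerance = 1e-12)
  }
  # random placement (binomial) limit at large k
  expect_equal(fnb_presence_probability(10, 1e6, 0.1), 1 - 0.9^10,
               tolerance = 1e-5)
  expect_error(fnb_presence_probability(10, 1, 0), "alpha")
  expect_error(fnb_presence_probability(10, 1, 1.2), "alpha")
})

test_that("log-space evaluation equals direct gamma-function evaluation", {
  for (N in c(1, 3, 7, 20)) for (k in c(0.5, 2, 5)) for (a in c(0.1, 0.4, 0.9)) {
    b <- k / a
    if (b - k <= 0 || b > 50) next
    direct <- 1 - gamma(N + b - k) * gamma(b) / (gamma(N + b) * gamma(b - k))
    expect_equal(fnb_presence_probability(N, k, a), direct,
                 tolerance = 1e-10)
  }
})

test_that("presence probability is monotone in alpha and abundance", {
  alphas <- seq(0.05, 0.95, by = 0.1)
  p_a <- vapply(alphas, function(a)
    fnb_presence_probability(50, 0.94 * 50 * a, a), numeric(1))
  expect_true(all(diff(p_a) >= 0))          # saturates at exactly 1
  expect_true(all(diff(p_a[p_a < 1 - 1e-12]) > 0))
  Ns <- c(1, 2, 5, 10, 50, 200, 1000)
  p_n <- fnb_presence_probability(Ns, 2, 0.1)
  expect_true(all(diff(p_n) > 0))
})

test_that("analytic zeta reduces to S * p^m and matches the random limit", {
  # 100 species, all with presence probability 1/2 in the binomial limit:
  # alpha chosen so 1 - (1 - alpha)^N = 0.5
  N <- 20
  a <- 1 - 0.5^(1 / N)
  sc <- fnb_scenario(grain_m2 = a * 5e5, k_factor = 1e6, n_orders = 3)
  z <- zeta_fnb(rep(N, 100), sc)
  expect_equal(z$zeta[3], 100 * 0.5^3, tolerance = 1e-3)
  # k -> infinity equals the random placement model for a whole RAD
  rad <- generate_rad("brokenstick", S = 20, N_total = 2000)
  sc8 <- fnb_scenario(grain_m2 = 0.02 * 5e5, k_factor = 1e8 / 2000 / 0.02,
                      n_orders = 8)
  # k_factor chosen so k_i ~ 1e8 * N_i/2000: all k_i >= 1e6
  z8 <- zeta_fnb(rad, sc8)
  p_rp <- 1 - (1 - 0.02)^rad$abundances
  z_rp <- vapply(1:8, function(m) sum(p_rp^m), numeric(1))
  expect_equal(z8$zeta, z_rp, tolerance = 1e-6)
})

test_that("analytic zeta is non-increasing and agrees with Bernoulli simulation", {
  rad <- generate_rad("brokenstick", S = 300, N_total = 211000)
  sc <- fnb_scenario(grain_m2 = 100, n_orders = 10)
  z <- zeta_fnb(rad, sc)
  expect_true(all(diff(z$zeta) < 0))
  expect_equal(z$zeta[1], sum(z$p))
  # independence assumption: zeta_m = sum p_i^m against direct Bernoulli
  # simulation of m-sample co-occurrence
  set.seed(99)
  n_rep <- 3000
  m_ord <- 5
  sims <- replicate(n_rep, {
    pres <- matrix(stats::rbinom(length(z$p) * m_ord, 1, z$p),
                   nrow = length(z$p))
    sum(rowSums(pres) == m_ord)
  })
  se <- stats::sd(sims) / sqrt(n_rep)
  expect_lt(abs(mean(sims) - z$zeta[m_ord]), 3 * se + 1e-9)
})

test_that("expected gamma and fill have their closed forms", {
  # a single species with p = 0.5 over 2 sites (alpha in the binomial limit)
  a <- 0.5
  sc <- fnb_scenario(grain_m2 = a * 5e5, k_factor = 1e8, n_orders = 2)
  gf <- expected_gamma_and_fill(1, sc, n_sites = 2)
  expect_equal(unname(gf["gamma"]), 0.75, tolerance = 1e-6)
  expect_equal(unname(gf["fill"]), 2 / 3, tolerance = 1e-6)
})

test_that("grain experiment reproduces the grain and evenness effects", {
  rads <- lapply(c("logseries", "lognormal", "brokenstick"),
                 generate_rad, S = 300, N_total = 211000)
  ge <- grain_experiment(rads)
  expect_identical(nrow(ge), 30L)
  # beyond 400 m^2 no scenario supports the exponential form
  big <- ge[ge$grain_m2 > 400 & !ge$degenerate, ]
  expect_true(all(big$waic_exponential < 0.5))
  # at 100 m^2 support rises with evenness: logseries < lognormal < brokenstick
  g100 <- ge[ge$grain_m2 == 100, ]
  w <- g100$waic_exponential[match(c("logseries", "lognormal", "brokenstick"),
                                   g100$rad)]
  expect_true(all(diff(w) > 0))
  # exponential support exists at fine grain for the even RAD
  expect_gt(max(ge$waic_exponential[ge$grain_m2 <= 100], na.rm = TRUE), 0.5)
  # exponential scenarios have lower expected fill than power scenarios
  ok <- ge[!ge$degenerate, ]
  expect_lt(mean(ok$fill[ok$winner == "exponential"]),
            mean(ok$fill[ok$winner == "power"]))
})

test_that("grain equal to the extent is degenerate and flagged", {
  rad <- generate_rad("brokenstick", S = 50, N_total = 5000)
  ge <- grain_experiment(list(rad), grains_m2 = 5e5)
  expect_true(ge$degenerate[1])
  expect_true(is.na(ge$waic_exponential[1]))
})

test_that("aggregation experiment: strong aggregation favours the exponential form", {
  rads <- lapply(c("logseries", "lognormal", "brokenstick"),
                 generate_rad, S = 300, N_total = 211000)
  ae <- aggregation_experiment(rads, k_grid = c(0.1, 0.5, 2, 10))
  expect_identical(nrow(ae), 12L)
  for (shape in unique(ae$rad)) {
    w <- ae$waic_exponential[ae$rad == shape]
    k <- ae$k[ae$rad == shape]
    # k = 0.1 (aggregated) beats k = 10 (near-random placement)
    expect_gt(w[k == 0.1], w[k == 10])
    # approaching random placement support declines from the best level
    expect_lt(w[k == 10], max(w))
  }
})
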