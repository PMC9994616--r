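kinds_controlled <- c("nested", "gradient_even", "turnover_compartmented",
                      "random", "clementsian_strict")

test_that("generators hit target dimensions and (where controllable) fill 0.5", {
  for (k in c(kinds_controlled, "continuous", "ecotone")) {
    m <- simulate_structure(k, seed = 1)
    expect_identical(dim(m), c(20L, 20L))
    expect_true(all(m %in% c(0L, 1L)))
  }
  for (k in setdiff(kinds_controlled, "random")) {
    m <- simulate_structure(k, seed = 2)
    expect_lt(abs(mean(m) - 0.5), 0.05)
  }
})

test_that("nested structure is fully nested with descending occupancies", {
  m <- simulate_structure("nested")
  occ <- colSums(m)
  expect_true(all(diff(occ) <= 0))
  expect_equal(occ[[1]], 20)          # most widespread species saturated
  sets <- apply(m, 2, function(col) which(col == 1))
  for (i in 1:19) for (j in (i + 1):20)
    expect_true(all(sets[[j]] %in% sets[[i]]))
})

test_that("compartmented structures share exactly the stated species count", {
  m <- simulate_structure("turnover_compartmented")
  in_both <- colSums(m[1:10, ] > 0) > 0 & colSums(m[11:20, ] > 0) > 0
  expect_identical(sum(in_both), 2L)
  mc <- simulate_structure("clementsian_strict")
  in_both_c <- colSums(mc[1:10, ] > 0) > 0 & colSums(mc[11:20, ] > 0) > 0
  expect_identical(sum(in_both_c), 0L)
})

test_that("starting structures classify to their expected forms", {
  classify_majority <- function(kind, n = 50) {
    wins <- vapply(seq_len(n), function(r) {
      m <- simulate_structure(kind, seed = r)
      suppressWarnings(classify_form(m)$winner)
    }, character(1))
    names(sort(table(wins), decreasing = TRUE))[1]
  }
  expect_identical(classify_majority("random"), "exponential")
  expect_identical(classify_majority("clementsian_strict"), "exponential")
  expect_identical(classify_majority("turnover_compartmented"), "exponential")
  expect_identical(classify_majority("nested"), "power")
  expect_identical(classify_majority("continuous"), "power")
  # equal-width evenly spaced ranges decline hypergeometrically -- faster
  # than exponential -- so the exponential form wins decisively
  expect_identical(classify_majority("gradient_even"), "exponential")
})

test_that("a saturated species adds exactly one shared species at every order", {
  set.seed(21)
  m <- random_incidence(10, 8, 0.4)
  m2 <- add_saturated_species(m)
  expect_identical(dim(m2), c(10L, 9L))
  expect_equal(unname(colSums(m2)[9]), 10)
  expect_equal(zeta_exact(m2)$zeta, zeta_exact(m)$zeta + 1, tolerance = 1e-12)
})

test_that("C-score matches direct pair counting and its closed forms", {
  # perfect checkerboard on 2 sites
  cb <- cbind(c(1, 0), c(0, 1))
  expect_equal(c_score(cb), 1)
  # identical site sets share everything
  same <- cbind(c(1, 1, 0), c(1, 1, 0))
  expect_equal(c_score(same), 0)
  set.seed(31)
  for (rep in 1:10) {
    m <- random_incidence(sample(4:10, 1), sample(3:8, 1), runif(1, 0.2, 0.8))
    expect_equal(c_score(m), c_score_brute(m), tolerance = 1e-12)
    # permutation invariance
    expect_equal(c_score(m[sample(nrow(m)), sample(ncol(m))]), c_score(m))
  }
})

test_that("perturbation conserves row sums, fill and species count every step", {
  set.seed(41)
  m <- simulate_structure("nested", seed = 41)
  rs <- rowSums(m); fill <- sum(m); nsp <- sum(colSums(m) > 0)
  for (it in 1:50) {
    m <- perturb_step(m)
    expect_identical(rowSums(m), rs)
    expect_identical(sum(m), fill)
    expect_identical(sum(colSums(m) > 0), nsp)
  }
})

test_that("perturbation fails cleanly on saturated matrices", {
  expect_error(perturb_step(matrix(1L, 4, 4)), "saturated")
})

test_that("perturbation experiment is seeded and shows the expected trends", {
  p1 <- perturbation_experiment("nested", n_iter = 40, n_reps = 8, seed = 7)
  p2 <- perturbation_experiment("nested", n_iter = 40, n_reps = 8, seed = 7)
  expect_identical(p1$records, p2$records)
  # power-law start: exponential support and C-score rise together under
  # perturbation (interspecific association weakens toward the random level)
  tr <- p1$mean_trajectory
  expect_lt(tr$waic_exponential[1], 0.5)
  expect_gt(tr$waic_exponential[nrow(tr)], 0.5)
  expect_gt(stats::cor(tr$waic_exponential, tr$c_score), 0.5)
  # random start: exponential support stays near 1 throughout
  pr <- perturbation_experiment("random", n_iter = 40, n_reps = 8, seed = 7)
  expect_true(all(pr$mean_trajectory$waic_exponential > 0.9))
})

test_that("forcing top occupancy hits the target exactly", {
  set.seed(51)
  for (p1 in c(0.5, 0.75, 0.95)) {
    m <- force_top_occupancy(random_incidence(20, 20, 0.5), p1)
    expect_equal(max(colSums(m)), round(p1 * 20))
  }
})

test_that("the occupancy threshold experiment is reproducible and monotone-ish", {
  oc1 <- occupancy_threshold_experiment(p1_grid = c(0.6, 0.8, 0.95),
                                        n_reps = 40, seed = 13)
  oc2 <- occupancy_threshold_experiment(p1_grid = c(0.6, 0.8, 0.95),
                                        n_reps = 40, seed = 13)
  expect_identical(oc1$table, oc2$table)
  # power support grows with forced occupancy
  expect_true(oc1$table$prop_power[3] > oc1$table$prop_power[1])
})
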