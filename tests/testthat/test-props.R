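test_that("PIE matches direct pair probability and its limits", {
  expect_equal(pie_index(c(10, 0, 0)), 0)
  expect_equal(pie_index(c(5, 5)), (10 / 9) * 0.5, tolerance = 1e-12)
  set.seed(61)
  for (rep in 1:10) {
    counts <- rpois(sample(3:10, 1), 5) + 1
    # the bias-corrected PIE equals the probability that two individuals
    # drawn without replacement belong to different species
    expect_equal(pie_index(counts), pie_brute(counts), tolerance = 1e-12)
  }
  # S equal species approaches 1 - 1/S
  expect_equal(pie_index(rep(1e6, 4)), 1 - 1 / 4, tolerance = 1e-5)
  expect_warning(expect_true(is.na(pie_index(c(1, 0)))), "undefined")
})

test_that("Morisita index matches direct pair counting and its anchors", {
  expect_equal(morisita_index(c(2, 0)), 2)
  expect_equal(morisita_index(c(1, 1)), 0)
  c_big <- rep(500, 6)
  expect_equal(morisita_index(c_big), (6 * 500 - 6) / (6 * 500 - 1) * 1,
               tolerance = 1e-3)
  set.seed(62)
  for (rep in 1:10) {
    counts <- rpois(sample(3:8, 1), 4)
    if (sum(counts) < 2) next
    expect_equal(morisita_index(counts), morisita_brute(counts),
                 tolerance = 1e-12)
  }
  expect_warning(expect_true(is.na(morisita_index(c(1, 0, 0)))), "undefined")
})

test_that("focal species selection is deterministic with documented tie rules", {
  m <- cbind(a = c(10, 0, 0), b = c(9, 0, 0), c = c(8, 0, 0), d = c(7, 0, 0),
             e = c(6, 0, 0))
  expect_identical(select_focal_species(m), c("a", "b", "c", "d"))
  # tie at rank 4 broken by occupancy
  m2 <- cbind(a = c(10, 0, 0), b = c(9, 0, 0), c = c(8, 0, 0),
              d = c(7, 0, 0), e = c(3, 2, 2))
  m2[1, "d"] <- 7
  # d: total 7 occupancy 1; e: total 7 occupancy 3 -> e wins rank 4
  expect_identical(select_focal_species(m2)[4], "e")
  m3 <- matrix(rpois(60, 3), 3, 20)
  expect_length(select_focal_species(m3, "top_quartile"), 5)
  expect_error(select_focal_species(m[, 1:3, drop = FALSE]), "at least 4")
})

test_that("mean Spearman association has its closed-form values", {
  m <- cbind(a = 1:4, b = 1:4)
  expect_equal(mean_spearman_association(m, focal = c("a", "b")), 1)
  m2 <- cbind(a = 1:4, b = 4:1)
  expect_equal(mean_spearman_association(m2, focal = c("a", "b")), -1)
  m3 <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  expect_equal(mean_spearman_association(m3, focal = c("a", "b")), 0.8)
  m4 <- cbind(a = 1:4, b = rep(2, 4), c = 4:1)
  expect_warning(r <- mean_spearman_association(m4, focal = c("a", "b", "c")),
                 "zero-variance")
  expect_equal(r, -1)
})

test_that("singleton proportion and fill have their counting definitions", {
  expect_equal(unname(singleton_and_fill(diag(5))),
               c(1, 0.2))
  expect_equal(unname(singleton_and_fill(matrix(1, 3, 4))), c(0, 1))
  m <- cbind(c(1, 1, 1, 1), c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 0))
  expect_equal(unname(singleton_and_fill(m)), c(0.25, 9 / 16))
})

test_that("fixed-margins tables conserve both margins and follow the hypergeometric law", {
  set.seed(71)
  m <- matrix(rpois(20, 3), 4, 5)
  tabs <- null_fixed_margins_table(m, n = 50, seed = 7)
  for (t in tabs) {
    expect_identical(rowSums(t), rowSums(m))
    expect_identical(colSums(t), colSums(m))
  }
  expect_identical(null_fixed_margins_table(m, seed = 3),
                   null_fixed_margins_table(m, seed = 3))
  # 2x2 margins (3,3)x(3,3): cell (1,1) is hypergeometric
  m22 <- matrix(c(3, 0, 0, 3), 2, 2)
  draws <- vapply(null_fixed_margins_table(m22, n = 4000, seed = 11),
                  function(t) t[1, 1], numeric(1))
  expected <- stats::dhyper(0:3, 3, 3, 3)
  obs <- tabulate(draws + 1, nbins = 4)
  chi <- suppressWarnings(stats::chisq.test(obs, p = expected))
  expect_gt(chi$p.value, 0.01)
})

test_that("quantitative shuffle conserves species totals and occupancies", {
  set.seed(72)
  m <- matrix(rpois(30, 2), 5, 6)
  m[1, ] <- m[1, ] + 1L
  sims <- null_quantitative_shuffle(m, n = 30, seed = 5)
  for (s in sims) {
    expect_identical(colSums(s), colSums(m))
    expect_identical(unname(colSums(s > 0)), unname(colSums(m > 0)))
  }
  # single-species feasibility: counts (3,2,0) keeps 2 occupied sites, total 5
  m1 <- matrix(c(3L, 2L, 0L), 3, 1)
  s1 <- null_quantitative_shuffle(m1, n = 20, seed = 6)
  for (s in s1) {
    expect_identical(sum(s), 5L)
    expect_identical(sum(s > 0), 2L)
    expect_true(all(s[s > 0] >= 1))
  }
})

test_that("curveball conserves margins and mixes only within the checkerboard class", {
  set.seed(73)
  m <- random_incidence(6, 6, 0.5)
  sims <- null_curveball(m, n = 30, seed = 9)
  for (s in sims) {
    expect_identical(unname(rowSums(s)), unname(rowSums(m)))
    expect_identical(unname(colSums(s)), unname(colSums(m)))
  }
  # 2x2 checkerboard: the only matrices with margins (1,1)x(1,1) are the two
  # checkerboards, and both occur
  cb <- cbind(c(1L, 0L), c(0L, 1L))
  states <- vapply(null_curveball(cb, n = 60, seed = 10),
                   function(s) paste(s, collapse = ""), character(1))
  expect_true(all(states %in% c("1001", "0110")))
  expect_identical(length(unique(states)), 2L)
})

test_that("SES follows its definition and flags degenerate null ensembles", {
  r <- standardized_effect_size(5, c(1, 2, 3))
  expect_equal(r$ses, (5 - 2) / 1)
  r0 <- standardized_effect_size(2, c(1, 2, 3))
  expect_equal(r0$ses, 0)
  rd <- standardized_effect_size(4, c(2, 2, 2))
  expect_true(rd$undefined)
  expect_true(is.na(rd$ses))
  expect_error(standardized_effect_size(1, numeric(0)), "at least 2")
})

test_that("SES of data drawn from its own null model is centred near zero", {
  set.seed(74)
  # base matrix, then treat one null draw as 'observed' and score it against
  # fresh draws of the same null
  base <- matrix(rpois(12 * 10, 2), 12, 10)
  base[1, ] <- base[1, ] + 1L
  ses_vals <- vapply(1:25, function(r) {
    obs <- null_quantitative_shuffle(base, seed = 1000 + r)
    foc <- select_focal_species(obs)
    nulls <- null_quantitative_shuffle(obs, n = 60, seed = 2000 + r)
    stat <- function(mm) suppressWarnings(
      mean_spearman_association(mm, focal = foc))
    standardized_effect_size(stat(obs), vapply(nulls, stat, numeric(1)))$ses
  }, numeric(1))
  expect_lt(abs(mean(ses_vals, na.rm = TRUE)), 0.5)
})

test_that("the property battery is permutation-invariant to site order", {
  set.seed(75)
  m <- matrix(rpois(20 * 15, 2), 20, 15)
  m[, 1] <- m[, 1] + 2L
  p1 <- community_properties(m, n_null = 29, seed = 4)
  p2 <- community_properties(m[sample(nrow(m)), ], n_null = 29, seed = 4)
  for (f in c("pie_pooled", "pie_sample_mean", "morisita_mean",
              "spearman_mean", "c_score", "singleton_proportion",
              "matrix_fill"))
    expect_equal(p1[[f]], p2[[f]], tolerance = 1e-12)
})
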