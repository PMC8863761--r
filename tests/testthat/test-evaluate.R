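test_that("factor congruence behaves at its anchor points", {
  x <- c(.8, .6, .4, .2)
  expect_equal(factor_congruence(x, x), 1)
  expect_equal(factor_congruence(x, -x), -1)
  expect_equal(factor_congruence(c(1, 0), c(0, 1)), 0)
  expect_error(factor_congruence(c(0, 0), x[1:2]),
               class = "pafgrid_zero_vector")
})

test_that("alignment undoes column swaps and sign flips", {
  set.seed(12)
  ref <- matrix(runif(15 * 3, -1, 1), 15, 3)
  fitted <- ref[, c(3, 1, 2)]
  al <- align_factors(fitted, ref)
  expect_equal(apply_alignment(fitted, al), ref)
  expect_equal(al$signs, rep(1, 3))

  fitted2 <- ref
  fitted2[, 2] <- -fitted2[, 2]
  al2 <- align_factors(fitted2, ref)
  expect_equal(al2$signs[2], -1)
  expect_equal(apply_alignment(fitted2, al2), ref)
})

test_that("alignment equals the exhaustive search oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    fitted <- matrix(runif(18 * 3, -1, 1), 18, 3)
    ref <- matrix(runif(18 * 3, -1, 1), 18, 3)
    al <- align_factors(fitted, ref)
    score <- sum(vapply(1:3, function(j)
      abs(factor_congruence(fitted[, al$permutation[j]], ref[, j])),
      numeric(1)))
    expect_equal(score, brute_force_alignment_score(fitted, ref),
                 tolerance = 1e-12)
  }
})

test_that("rmse reproduces its analytic cases", {
  L <- matrix(runif(18 * 3), 18, 3)
  expect_equal(rmse_loadings(L, L), 0)
  expect_equal(rmse_loadings(L, L + 0.1, align = FALSE), 0.1)
  L2 <- L
  L2[4, 2] <- L2[4, 2] + 0.6
  expect_equal(rmse_loadings(L, L2, align = FALSE), sqrt(0.36 / 54))
})

test_that("aligned rmse is invariant to simultaneous permutation and sign flips", {
  set.seed(13)
  ref <- matrix(runif(18 * 3, -1, 1), 18, 3)
  fitted <- ref + matrix(rnorm(54, sd = .02), 18, 3)
  base <- rmse_loadings(ref, fitted, align = TRUE)
  perm <- c(2, 3, 1)
  s <- c(-1, 1, -1)
  ref_p <- sweep(ref[, perm], 2, s, `*`)
  fit_p <- sweep(fitted[, perm], 2, s, `*`)
  expect_equal(rmse_loadings(ref_p, fit_p, align = TRUE), base,
               tolerance = 1e-10)
})

test_that("Heywood detection triggers exactly at the threshold", {
  sol <- list(communalities = c(.5, .5, .5), loadings = matrix(.7, 3, 1))
  expect_false(heywood_check(sol))
  sol$communalities[1] <- .998
  expect_true(heywood_check(sol))
  sol$communalities[1] <- .99799
  expect_false(heywood_check(sol))
  sol$loadings[2, 1] <- -.999
  expect_true(heywood_check(sol))
})

test_that("salience respects the .20 threshold in absolute value", {
  pat <- matrix(c(.19, .20, -.25, .6, 0, .1), 3, 2)
  m <- salient_map(pat)
  expect_identical(m[[1]], 2L)          # .19 not salient, .6 is
  expect_identical(m[[2]], 1L)          # exactly .20 is salient
  expect_identical(m[[3]], 1L)          # -.25 counts through |.|
})

test_that("correspondence differences count set changes after relabelling", {
  a <- list(1L, 2L, integer(0))
  expect_identical(correspondence_diff(a, a), 0L)
  b <- list(1L, 2L, 1L)                 # salient in b only
  expect_identical(correspondence_diff(a, b), 1L)
  c_ <- list(2L, 2L, integer(0))        # moved factors
  expect_identical(correspondence_diff(a, c_), 1L)
  ## alignment relabels the fitted side before comparing
  al <- structure(list(permutation = c(2L, 1L), signs = c(1, 1)),
                  class = "factor_alignment")
  swapped <- list(2L, 1L, integer(0))
  expect_identical(correspondence_diff(swapped, a, alignment = al), 0L)
})

test_that("admissibility needs two salient loadings per factor and no Heywood case", {
  paf_ok <- list(communalities = rep(.5, 6), loadings = matrix(.6, 6, 2))
  clean <- list(pattern = matrix(c(.6, .6, .6, 0, 0, 0,
                                   0, 0, 0, .6, .6, .6), 6, 2))
  expect_true(is_admissible(clean, paf_ok))
  lonely <- clean
  lonely$pattern[c(5, 6), 2] <- 0       # one salient loading on factor 2
  expect_false(is_admissible(lonely, paf_ok))
  paf_bad <- paf_ok
  paf_bad$communalities[1] <- .999
  expect_false(is_admissible(clean, paf_bad))
})

test_that("solution comparison reports diffs, congruence and correspondence", {
  set.seed(14)
  A <- matrix(runif(18 * 3, .3, .8), 18, 3)
  same <- compare_solutions(A, A, stage = "promax")
  expect_equal(same$abs_diff_mean, 0)
  expect_equal(same$congruence_mean, 1)
  expect_identical(same$correspondence_diff_count, 0L)

  ## one entry pushed across the salience boundary
  B <- A
  B[7, 2] <- 0.19
  A[7, 2] <- 0.21
  cmp <- compare_solutions(A, B, stage = "promax")
  expect_identical(cmp$correspondence_diff_count, 1L)

  ## bounded noise gives bounded diffs, symmetrically
  set.seed(15)
  Bn <- A + matrix(runif(54, 0, .01), 18, 3)
  cmp_ab <- compare_solutions(A, Bn, stage = "varimax")
  expect_lte(cmp_ab$abs_diff_max, 0.0101)
  cmp_ba <- compare_solutions(Bn, A, stage = "varimax")
  expect_equal(cmp_ab$abs_diff_mean, cmp_ba$abs_diff_mean, tolerance = 1e-10)
  expect_equal(cmp_ab$congruence_min, cmp_ba$congruence_min, tolerance = 1e-10)
})
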