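perfect_cluster <- matrix(c(.8, .8, 0, 0, 0, 0, .8, .8), 4, 2)
fortyfive <- matrix(c(.6, .6, .6, .6, .6, .6, -.6, -.6), 4, 2)

test_that("varimax leaves simple structure alone and undoes a 45-degree mix", {
  for (type in c("kaiser", "svd")) {
    v <- rotate_varimax(perfect_cluster, type, normalize = FALSE)
    al <- align_factors(v$loadings, perfect_cluster)
    expect_lt(max(abs(apply_alignment(v$loadings, al) - perfect_cluster)),
              1e-8)
  }
  ## analytic 45-degree case: .6 * sqrt(2) = .8485 cluster structure
  target <- matrix(c(.6 * sqrt(2), .6 * sqrt(2), 0, 0,
                     0, 0, .6 * sqrt(2), .6 * sqrt(2)), 4, 2)
  v <- rotate_varimax(fortyfive, "kaiser", normalize = FALSE)
  al <- align_factors(v$loadings, target)
  expect_lt(max(abs(apply_alignment(v$loadings, al) - target)), 1e-6)
})

test_that("one factor passes through both rotations unchanged", {
  L <- matrix(c(.7, .6, .5), 3, 1)
  v <- rotate_varimax(L, "kaiser")
  expect_equal(v$loadings, L)
  expect_equal(v$rotmat, matrix(1, 1, 1))
  pm <- rotate_promax(L)
  expect_equal(pm$pattern, L)
  expect_equal(pm$structure, L)
  expect_equal(pm$phi, matrix(1, 1, 1))
})

test_that("varimax rotations are orthogonal and preserve communalities", {
  set.seed(5)
  for (type in c("kaiser", "svd")) {
    for (normalize in c(TRUE, FALSE)) {
      L <- matrix(runif(21 * 3, -1, 1) * 0.7, 21, 3)
      v <- rotate_varimax(L, type, normalize = normalize)
      expect_lt(max(abs(crossprod(v$rotmat) - diag(3))), 1e-8)
      expect_equal(rowSums(v$loadings^2), rowSums(L^2), tolerance = 1e-8)
    }
  }
})

test_that("the kaiser-variant criterion never decreases across sweeps", {
  set.seed(6)
  for (i in 1:3) {
    L <- matrix(runif(15 * 3, -1, 1) * 0.7, 15, 3)
    v <- rotate_varimax(L, "kaiser", normalize = TRUE)
    expect_true(all(diff(v$criterion_path) >= -1e-12))
  }
})

test_that("the svd variant reproduces the reference varimax implementation", {
  set.seed(3)
  L <- matrix(runif(18 * 3, -1, 1) * 0.7, 18, 3)
  ours <- rotate_varimax(L, "svd", normalize = TRUE, tol = 1e-12)
  ref <- stats::varimax(L, normalize = TRUE, eps = 1e-12)
  al <- align_factors(ours$loadings, unclass(ref$loadings))
  expect_lt(max(abs(apply_alignment(ours$loadings, al) -
                      unclass(ref$loadings))), 1e-10)
})

test_that("Kaiser normalization rejects zero-communality rows", {
  L <- rbind(perfect_cluster, c(0, 0))
  expect_error(rotate_varimax(L, "kaiser", normalize = TRUE),
               class = "pafgrid_degenerate_row")
})

test_that("promax with k = 1 and an unnormalized target is the identity transform", {
  v <- rotate_varimax(perfect_cluster, "kaiser", normalize = FALSE)
  pm <- rotate_promax(v$loadings, v$rotmat,
                      rotation_settings(p_type = "unnorm", k = 1))
  expect_equal(pm$pattern, v$loadings, tolerance = 1e-10)
  expect_equal(pm$phi, diag(2), tolerance = 1e-10)
})

test_that("promax satisfies its structural identities", {
  set.seed(7)
  pf <- paf_extract(population_correlation(population_model("18|3|46", "low")),
                    3, paf_settings())
  for (p_type in c("unnorm", "norm")) {
    for (k in c(2, 3, 4)) {
      st <- rotation_settings(p_type = p_type, k = k)
      vm <- rotate_varimax(pf$loadings, st$varimax_type)
      pm <- rotate_promax(vm$loadings, vm$rotmat, st)
      ## structure = pattern . phi
      expect_equal(pm$structure, pm$pattern %*% pm$phi, tolerance = 1e-10)
      ## phi symmetric PSD with unit diagonal
      expect_equal(pm$phi, t(pm$phi), tolerance = 1e-12)
      expect_equal(unname(diag(pm$phi)), rep(1, 3))
      expect_gte(min(eigen(pm$phi, only.values = TRUE)$values), -1e-10)
      ## oblique transformation does not change the fitted common variance
      expect_lt(max(abs(pm$pattern %*% pm$phi %*% t(pm$pattern) -
                          tcrossprod(pf$loadings))), 1e-8)
    }
  }
})

test_that("our promax algebra matches the reference implementation", {
  set.seed(3)
  L <- matrix(runif(18 * 3, -1, 1) * 0.7, 18, 3)
  vm <- stats::varimax(L, normalize = TRUE, eps = 1e-5)
  ours <- rotate_promax(unclass(vm$loadings), vm$rotmat,
                        rotation_settings(p_type = "unnorm", k = 4))
  ref <- stats::promax(L, m = 4)
  al <- align_factors(ours$pattern, unclass(ref$loadings))
  expect_lt(max(abs(apply_alignment(ours$pattern, al) -
                      unclass(ref$loadings))), 1e-10)
})

test_that("an orthogonal population yields a near-orthogonal promax solution", {
  m <- population_model("18|3|6", "zero")
  X <- sample_data(population_correlation(m), 10000, seed = 42)
  sol <- efa(cor_from_raw(X), 3, preset("best"))
  offdiag <- sol$rotation$phi[upper.tri(sol$rotation$phi)]
  expect_lt(mean(abs(offdiag)), 0.05)
  al <- align_factors(sol$rotation$pattern, m$Lambda)
  expect_lt(max(abs(apply_alignment(sol$rotation$pattern, al) - m$Lambda)),
            0.1)
})
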