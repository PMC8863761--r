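test_that("the model-code grammar parses its documented forms", {
  sk <- parse_model_code("18|3|6")
  expect_identical(sk[c("p", "m")], list(p = 18L, m = 3L))
  expect_equal(sk$loadings, 0.6)
  expect_false(sk$wb)
  expect_identical(sk$n_cross, 0L)

  sk2 <- parse_model_code("18|6|369wb")
  expect_equal(sk2$loadings, c(0.3, 0.6, 0.9))
  expect_true(sk2$wb)

  sk3 <- parse_model_code("18|3|46|3c")
  expect_identical(sk3$n_cross, 3L)
  expect_equal(sk3$loadings, c(0.4, 0.6))

  expect_error(parse_model_code("18|3"), class = "pafgrid_parse_error")
  expect_error(parse_model_code("18|3|x6"), class = "pafgrid_parse_error")
  expect_error(parse_model_code("18|3|46|3"), class = "pafgrid_parse_error")
})

test_that("pattern construction follows the block layout rules", {
  L <- build_pattern(parse_model_code("18|3|6"))
  expect_equal(dim(L), c(18L, 3L))
  for (f in 1:3)
    expect_equal(unname(L[((f - 1) * 6 + 1):(f * 6), f]), rep(0.6, 6))
  expect_equal(sum(L != 0), 18)

  L2 <- build_pattern(parse_model_code("6|3|6"))
  expect_equal(colSums(L2 != 0), c(F1 = 2L, F2 = 2L, F3 = 2L))

  ## multi-value loadings without wb: constant within factor, cycled between
  L3 <- build_pattern(parse_model_code("18|3|46"))
  expect_equal(unname(unique(L3[1:6, 1])), 0.4)
  expect_equal(unname(unique(L3[7:12, 2])), 0.6)
  expect_equal(unname(unique(L3[13:18, 3])), 0.4)

  ## wb cycles within each factor
  L4 <- build_pattern(parse_model_code("18|3|369wb"))
  expect_equal(unname(L4[1:6, 1]), rep(c(0.3, 0.6, 0.9), 2))

  ## cross-loadings: smallest value on the adjacent factor
  L5 <- build_pattern(parse_model_code("18|3|46|3c"))
  expect_equal(unname(L5[1:3, 2]), rep(0.4, 3))
  expect_equal(sum(L5 != 0), 18 + 3)

  expect_error(build_pattern(parse_model_code("10|3|6")),
               class = "pafgrid_invalid_input")
})

test_that("codes round-trip through the pattern builder", {
  for (code in default_manifest()$code) {
    sk <- parse_model_code(code)
    L <- build_pattern(sk)
    expect_equal(dim(L), c(sk$p, sk$m))
    ## the multiset of distinct non-zero values survives construction
    expect_setequal(unique(L[L != 0]),
                    unique(c(sk$loadings,
                             if (sk$n_cross > 0) min(sk$loadings))))
    expect_identical(model_code(population_model(code)), code)
  }
})

test_that("population correlations follow the factor-model arithmetic", {
  ## one factor, loading .6
  m1 <- population_model("4|1|6")
  R1 <- population_correlation(m1)
  expect_equal(unname(unclass(R1)[1, 2]), 0.36)
  expect_equal(unname(diag(unclass(R1))), rep(1, 4))

  ## two factors, loading .6, phi = .7: between-factor r = .6 * .7 * .6
  m2 <- population_model("4|2|6", 0.7)
  R2 <- population_correlation(m2)
  expect_equal(unname(unclass(R2)[1, 3]), 0.252)
  expect_equal(unname(unclass(R2)[1, 2]), 0.36)

  ## orthogonal block model: exactly lambda^2 within, 0 between
  m3 <- population_model("18|3|6", "zero")
  R3 <- unclass(population_correlation(m3))
  expect_equal(unname(R3[1, 2]), 0.36)
  expect_equal(unname(R3[1, 7]), 0)

  ## an impossible model is rejected
  expect_error(population_correlation(population_model("4|2|9|2c")),
               class = "pafgrid_invalid_model")
})

test_that("every default model implies a valid positive definite correlation matrix", {
  models <- manifest_models()
  expect_length(models, 108)
  for (mo in models[seq(1, 108, by = 9)]) {
    R <- population_correlation(mo)
    expect_true(is_positive_definite(R))
  }
})

test_that("sampling is seeded, standardized, and matches the population", {
  R <- population_correlation(population_model("4|2|6", 0.7))
  X1 <- sample_data(R, 100, seed = 9)
  X2 <- sample_data(R, 100, seed = 9)
  expect_identical(X1, X2)

  X3 <- sample_data(R, 10000, seed = 10)
  expect_true(all(abs(apply(X3, 2, sd) - 1) < 0.05))

  X4 <- sample_data(R, 100000, seed = 11)
  expect_lt(abs(cor(X4[, 1], X4[, 3]) - 0.252), 0.01)

  expect_error(sample_data(equicorr(3, -0.6), 10),
               class = "pafgrid_not_positive_definite")
})

test_that("the implementation grid enumerates correctly", {
  grid <- enumerate_grid()
  expect_length(grid, 192)
  labels <- vapply(grid, `[[`, character(1), "label")
  expect_identical(anyDuplicated(labels), 0L)
  expect_length(enumerate_grid(init_comm = "smc"), 64)
  ## each preset occupies exactly one grid cell
  for (nm in c("psych_smc", "psych_unity", "spss", "best")) {
    expect_identical(sum(labels == grid_label(preset(nm))), 1L,
                     info = nm)
  }
  ## the tataryn k rule resolves to 3 for unnormalized, 2 for normalized
  tat <- enumerate_grid(init_comm = "smc", abs_eigen = TRUE,
                        criterion_type = "sum", criterion = 1e-3,
                        varimax_type = "kaiser", k_rule = "tataryn")
  ks <- vapply(tat, function(s) s$rot$k, integer(1))
  ps <- vapply(tat, function(s) s$rot$p_type, character(1))
  expect_identical(ks[ps == "unnorm"], 3L)
  expect_identical(ks[ps == "norm"], 2L)
})

test_that("simulation bookkeeping, reproducibility and aggregation work", {
  model <- population_model("6|3|6", "zero")
  specs <- list(preset("best"), preset("psych_smc"), preset("spss"))
  recs <- run_simulation(model, 180, 2, specs, seed = 3)
  expect_identical(nrow(recs), 6L)

  ## bit-identical re-run under the same master seed
  recs2 <- run_simulation(model, 180, 2, specs, seed = 3)
  expect_identical(recs, recs2)

  ## a prefix subset re-runs identically (counter-based per-record seeds)
  both <- run_simulation(list(model, population_model("6|3|6", "high")),
                         180, 2, list(preset("best")), seed = 3)
  solo <- run_simulation(model, 180, 2, list(preset("best")), seed = 3)
  expect_identical(both[both$phi == "zero", ], solo)

  agg <- aggregate_simulation(recs)
  expect_identical(nrow(agg), 3L)
  expect_true(all(agg$n_records == 2L))
  ## equal-MRMSE ties are broken alphabetically by label
  tied <- recs
  tied$rmse <- 0
  tied$heywood <- FALSE
  agg_tied <- aggregate_simulation(tied)
  expect_identical(agg_tied$implementation_label,
                   sort(vapply(specs, `[[`, character(1), "label")))
  expect_true(all(agg_tied$MRMSE == 0))

  ## proportions: 3 of 10 Heywood records
  fake <- recs[rep(1, 10), ]
  fake$replicate <- 1:10
  fake$heywood <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(aggregate_simulation(fake)$prop_heywood, 0.3)
})

test_that("the full design enumerates 216,000 dataset specifications", {
  expect_identical(design_size(108, c(180, 450), 1000), 216000L)
})
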