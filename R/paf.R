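#' Settings for iterative principal axis factoring
#'
#' Bundles every PAF setting that differs across the programs emulated here:
#' the initial communality estimate (unity, maximum absolute correlation, or
#' squared multiple correlations), whether eigenvalue magnitudes are taken as
#' absolute values before the square root, whether convergence is judged on
#' the change in the *sum* of communalities or on the *maximum* change in any
#' single communality, and the convergence criterion itself (1e-3 by default
#' in the emulated programs; 1e-6 as the stricter alternative).
#'
#' `smc_fail_fallback` controls what happens when SMC seeding fails because
#' one of the m largest eigenvalues turns negative while `abs_eigen = FALSE`:
#' `"error"` surfaces the failure (so simulation runs can count it),
#' `"unity"` and `"mac"` rerun extraction with that seed instead.
#'
#' @param init_comm one of `"unity"`, `"mac"`, `"smc"`.
#' @param abs_eigen take absolute eigenvalue magnitudes (avoids negative
#'   eigenvalues during iteration).
#' @param criterion_type `"sum"` or `"max_individual"`.
#' @param criterion positive convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param smc_fail_fallback `"error"`, `"unity"`, or `"mac"`.
#' @return object of class `paf_settings`.
#' @export
paf_settings <- function(init_comm = c("smc", "unity", "mac"),
                         abs_eigen = TRUE,
                         criterion_type = c("sum", "max_individual"),
                         criterion = 1e-3,
                         max_iter = 5000L,
                         smc_fail_fallback = c("error", "unity", "mac")) {
  init_comm <- match.arg(init_comm)
  criterion_type <- match.arg(criterion_type)
  smc_fail_fallback <- match.arg(smc_fail_fallback)
  if (!is.numeric(criterion) || length(criterion) != 1L || criterion <= 0)
    pafgrid_error("'criterion' must be a positive number", "pafgrid_invalid_input")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    pafgrid_error("'max_iter' must be >= 1", "pafgrid_invalid_input")
  structure(
    list(init_comm = init_comm, abs_eigen = isTRUE(abs_eigen),
         criterion_type = criterion_type, criterion = criterion,
         max_iter = max_iter, smc_fail_fallback = smc_fail_fallback),
    class = "paf_settings")
}

#' @export
print.paf_settings <- function(x, ...) {
  cat("paf_settings: init =", x$init_comm,
      "| abs_eigen =", x$abs_eigen,
      "| criterion =", format(x$criterion), paste0("(", x$criterion_type, ")"),
      "| fallback =", x$smc_fail_fallback, "\n")
  invisible(x)
}

#' Initial communality estimates
#'
#' @param R a [cor_matrix()].
#' @param method `"unity"` (all ones), `"mac"` ([mac()]), or `"smc"`
#'   ([smc()]; requires an invertible matrix).
#' @return numeric p-vector.
#' @export
initial_communalities <- function(R, method = c("smc", "unity", "mac")) {
  method <- match.arg(method)
  R <- as_cor_matrix(R)
  switch(method,
         unity = stats::setNames(rep(1, nrow(R)), colnames(R)),
         mac = mac(R),
         smc = smc(R))
}

## one full PAF iteration loop for a fixed initial communality vector;
## returns the solution list or a classed negative-eigenvalue condition
paf_iterate <- function(R, m, h0, settings) {
  p <- nrow(R)
  W <- unclass(R)
  h <- h0
  converged <- FALSE
  iterations <- 0L
  loadings <- NULL
  eig_vals <- NULL
  neg_seen <- FALSE
  for (it in seq_len(settings$max_iter)) {
    iterations <- it
    diag(W) <- h
    e <- eigen(W, symmetric = TRUE)
    ## eigen() returns descending order; take the m largest raw eigenvalues
    idx <- seq_len(m)
    vals <- e$values[idx]
    if (any(vals < 0)) {
      neg_seen <- TRUE
      if (!settings$abs_eigen) {
        cond <- structure(
          class = c("pafgrid_negative_eigenvalue", "pafgrid_error",
                    "error", "condition"),
          list(message = paste0(
            "negative eigenvalue among the ", m,
            " largest at iteration ", it,
            "; SMC-style seeding failed (abs_eigen = FALSE)"),
            call = NULL, iteration = it))
        stop(cond)
      }
    }
    mag <- if (settings$abs_eigen) abs(vals) else vals
    loadings <- e$vectors[, idx, drop = FALSE] %*%
      diag(sqrt(mag), m)
    eig_vals <- vals
    h_new <- rowSums(loadings^2)
    delta <- if (settings$criterion_type == "sum")
      abs(sum(h_new) - sum(h)) else max(abs(h_new - h))
    h <- h_new
    if (delta < settings$criterion) {
      converged <- TRUE
      break
    }
  }
  flips <- column_sign_flips(loadings)
  loadings <- apply_column_signs(loadings, flips)
  dimnames(loadings) <- list(colnames(R), paste0("F", seq_len(m)))
  list(loadings = loadings, communalities = stats::setNames(h, colnames(R)),
       iterations = iterations, converged = converged,
       eigenvalues_final = eig_vals,
       negative_eigenvalue_encountered = neg_seen)
}

#' Iterative principal axis factoring
#'
#' Repeatedly replaces the diagonal of the correlation matrix with the
#' current communality estimates, eigendecomposes, forms loadings from the m
#' leading eigenpairs (`sqrt(|lambda|)` when `abs_eigen`, `sqrt(lambda)`
#' otherwise), and updates communalities as row sums of squared loadings
#' until the convergence criterion is met or `max_iter` is reached. Column
#' signs are normalized so each column's largest-magnitude loading is
#' positive.
#'
#' When `abs_eigen = FALSE` and any of the m largest eigenvalues turns
#' negative during iteration the extraction cannot proceed; depending on
#' `settings$smc_fail_fallback` this raises a classed error
#' (`pafgrid_negative_eigenvalue`) or restarts with unity/MAC seeds.
#'
#' @param R a positive definite (or pre-smoothed) [cor_matrix()].
#' @param m number of factors, `1 <= m < p`.
#' @param settings a [paf_settings()] object.
#' @return object of class `paf_solution` with elements `loadings` (p x m),
#'   `communalities`, `initial_communalities`, `iterations`, `converged`,
#'   `eigenvalues_final`, `negative_eigenvalue_encountered`, `fallback_used`
#'   (`NA` or the seed actually used after an SMC failure), `settings_used`.
#' @export
paf_extract <- function(R, m, settings = paf_settings()) {
  R <- as_cor_matrix(R)
  p <- nrow(R)
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m >= p)
    pafgrid_error("'m' must satisfy 1 <= m < p", "pafgrid_invalid_input")
  if (!inherits(settings, "paf_settings"))
    pafgrid_error("'settings' must be a paf_settings object",
                  "pafgrid_invalid_input")
  ## near-degenerate eigenvalue ties (e.g., identity input) make the
  ## retained subspace arbitrary; keep the decomposition's order but warn
  ev0 <- eigen(unclass(R), symmetric = TRUE, only.values = TRUE)$values
  if (m < p && abs(ev0[m] - ev0[m + 1]) < 1e-10 * max(abs(ev0)))
    pafgrid_warn("eigenvalue tie at the retained/discarded boundary; factor order is arbitrary",
                 "pafgrid_eigen_tie")

  h0 <- initial_communalities(R, settings$init_comm)
  fallback_used <- NA_character_
  res <- tryCatch(
    paf_iterate(R, m, h0, settings),
    pafgrid_negative_eigenvalue = function(cond) cond)
  if (inherits(res, "condition")) {
    if (settings$smc_fail_fallback == "error") stop(res)
    fallback_used <- settings$smc_fail_fallback
    h0 <- initial_communalities(R, fallback_used)
    res <- paf_iterate(R, m, h0, settings)  # may legitimately fail again
    res$negative_eigenvalue_encountered <- TRUE
  }
  structure(
    c(res,
      list(initial_communalities = h0,
           fallback_used = fallback_used,
           settings_used = settings)),
    class = "paf_solution")
}

#' @export
print.paf_solution <- function(x, digits = 3, ...) {
  cat("paf_solution:", nrow(x$loadings), "indicators,",
      ncol(x$loadings), "factor(s);",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iteration(s)\n")
  print(round(x$loadings, digits))
  cat("communalities:\n")
  print(round(x$communalities, digits))
  invisible(x)
}
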