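#' Parallel analysis on SMC-reduced correlation matrices
#'
#' Eigenvalues are computed on the correlation matrix with its diagonal
#' replaced by squared multiple correlations, for the empirical data and
#' for each of `n_datasets` random standard-normal data sets of the same
#' dimensions. The retained factor count follows the decision rule of
#' testing the first empirical eigenvalue against the 95th percentile of
#' the first random eigenvalues and each subsequent eigenvalue against the
#' corresponding random mean, stopping at the first failure.
#'
#' @param data n x p raw data matrix; alternatively supply `R` and `n`.
#' @param R correlation matrix (used with `n` when `data` is missing).
#' @param n sample size (required with `R`).
#' @param n_datasets number of random comparison data sets (default 1000).
#' @param percentile percentile used for the first factor (default .95).
#' @param seed optional seed.
#' @return object of class `parallel_analysis` with
#'   `empirical_eigenvalues`, `random_eigenvalue_p95_first`,
#'   `random_eigenvalue_means`, `n_factors`, `n_datasets`.
#' @export
parallel_analysis <- function(data = NULL, R = NULL, n = NULL,
                              n_datasets = 1000L, percentile = 0.95,
                              seed = NULL) {
  if (!is.null(data)) {
    data <- as.matrix(data)
    R <- cor_from_raw(data)
    n <- nrow(data)
  }
  if (is.null(R) || is.null(n))
    pafgrid_error("supply 'data' or both 'R' and 'n'", "pafgrid_invalid_input")
  R <- as_cor_matrix(R)
  p <- nrow(R)
  reduced_eigen <- function(M) {
    W <- unclass(as_cor_matrix(M))
    diag(W) <- smc(M)
    sort(eigen(W, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }
  emp <- reduced_eigen(R)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rand <- matrix(NA_real_, n_datasets, p)
  for (i in seq_len(n_datasets)) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    rand[i, ] <- reduced_eigen(cor_from_raw(Z))
  }
  p95_first <- as.numeric(stats::quantile(rand[, 1], percentile))
  means <- colMeans(rand)
  k <- 0L
  if (emp[1] > p95_first) {
    k <- 1L
    while (k < p && emp[k + 1L] > means[k + 1L]) k <- k + 1L
  }
  structure(
    list(empirical_eigenvalues = emp,
         random_eigenvalue_p95_first = p95_first,
         random_eigenvalue_means = means,
         n_factors = k, n_datasets = as.integer(n_datasets),
         percentile = percentile),
    class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, digits = 3, ...) {
  cat("parallel_analysis:", x$n_factors, "factor(s) retained (",
      x$n_datasets, "random data sets )\n")
  tab <- cbind(empirical = x$empirical_eigenvalues,
               random_mean = x$random_eigenvalue_means)
  print(round(utils::head(tab, 10), digits))
  invisible(x)
}

#' Admissibility-driven downward factor-number search
#'
#' Starting from `n_start` factors, runs both implementations, checks
#' admissibility of both promax solutions (no Heywood cases, at least two
#' salient pattern coefficients per factor), and decrements the factor
#' count until both are admissible at the same number, or no factor count
#' works. The trace also records each implementation's own first admissible
#' count.
#'
#' @param R correlation matrix of the data.
#' @param n_start initial (largest) number of factors to try.
#' @param spec_a,spec_b two [implementation_spec()]s.
#' @param threshold salience threshold.
#' @return list with `n_final` (0 when nothing was admissible),
#'   `solution_a`, `solution_b` (at `n_final`, or `NULL`),
#'   `first_admissible_a`, `first_admissible_b`, `all_inadmissible` flag,
#'   and a per-step `trace` data frame.
#' @export
find_admissible <- function(R, n_start, spec_a, spec_b, threshold = 0.20) {
  if (n_start < 1L)
    pafgrid_error("n_start >= 1 required", "pafgrid_invalid_input")
  R <- as_cor_matrix(R)
  trace <- list()
  n_final <- 0L
  sol_a_final <- sol_b_final <- NULL
  first_a <- first_b <- NA_integer_
  for (nf in seq(n_start, 1L)) {
    fit <- function(spec) {
      tryCatch(suppressWarnings(efa(R, nf, spec)),
               pafgrid_error = function(e) NULL)
    }
    sa <- fit(spec_a)
    sb <- fit(spec_b)
    adm_a <- !is.null(sa) && is_admissible(sa$rotation, sa$paf, threshold)
    adm_b <- !is.null(sb) && is_admissible(sb$rotation, sb$paf, threshold)
    if (adm_a && is.na(first_a)) first_a <- nf
    if (adm_b && is.na(first_b)) first_b <- nf
    trace[[length(trace) + 1L]] <-
      data.frame(n_factors = nf, admissible_a = adm_a, admissible_b = adm_b)
    if (adm_a && adm_b) {
      n_final <- nf
      sol_a_final <- sa
      sol_b_final <- sb
      break
    }
  }
  list(n_final = n_final,
       solution_a = sol_a_final, solution_b = sol_b_final,
       first_admissible_a = first_a, first_admissible_b = first_b,
       all_inadmissible = n_final == 0L,
       trace = do.call(rbind, trace))
}

#' Run a parallel analysis from a CSV input
#'
#' @param input CSV path (correlation or raw data; correlation input
#'   requires `n`).
#' @param n sample size when the input is a correlation matrix.
#' @param n_datasets,seed passed to [parallel_analysis()].
#' @param out optional CSV path for the eigenvalue table.
#' @return the `parallel_analysis` object.
#' @export
run_pa <- function(input, n = NULL, n_datasets = 1000L, seed = NULL,
                   out = NULL) {
  inp <- read_efa_input(input)
  pa <- if (!is.null(inp$raw))
    parallel_analysis(data = inp$raw, n_datasets = n_datasets, seed = seed)
  else
    parallel_analysis(R = inp$R, n = n, n_datasets = n_datasets, seed = seed)
  if (!is.null(out)) {
    tab <- data.frame(
      component = seq_along(pa$empirical_eigenvalues),
      empirical = signif(pa$empirical_eigenvalues, 10),
      random_mean = signif(pa$random_eigenvalue_means, 10))
    utils::write.csv(tab, out, row.names = FALSE)
  }
  pa
}
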