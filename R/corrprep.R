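#' Construct a validated correlation matrix
#'
#' A `cor_matrix` is a symmetric numeric matrix with unit diagonal and all
#' off-diagonal entries in \[-1, 1\]; it is the input to principal axis
#' factoring and to the population-model machinery. Construction enforces
#' symmetry to within 1e-12, resets the diagonal to exactly 1 (entries must
#' already be within 1e-8 of 1), and requires at least two indicators.
#'
#' @param values square numeric matrix of correlations.
#' @param indicator_names optional character vector of indicator names;
#'   defaults to existing dimnames or `V1..Vp`.
#' @return a matrix of class `cor_matrix`.
#' @export
#' @examples
#' cor_matrix(matrix(c(1, .5, .5, 1), 2))
cor_matrix <- function(values, indicator_names = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    pafgrid_error("'values' must be a numeric matrix", "pafgrid_invalid_input")
  p <- nrow(values)
  if (p < 2L || ncol(values) != p)
    pafgrid_error("a correlation matrix must be square with p >= 2",
                  "pafgrid_invalid_input")
  if (anyNA(values))
    pafgrid_error("correlation matrix contains missing values",
                  "pafgrid_invalid_input")
  if (max(abs(values - t(values))) > 1e-12)
    pafgrid_error("correlation matrix is not symmetric (tolerance 1e-12)",
                  "pafgrid_asymmetric")
  if (max(abs(diag(values) - 1)) > 1e-8)
    pafgrid_error("correlation matrix diagonal must be 1",
                  "pafgrid_invalid_diagonal")
  off <- values[upper.tri(values)]
  if (any(abs(off) > 1 + 1e-12))
    pafgrid_error("off-diagonal correlations must lie in [-1, 1]",
                  "pafgrid_out_of_range")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  nm <- indicator_names %||% colnames(values) %||% paste0("V", seq_len(p))
  if (length(nm) != p)
    pafgrid_error("indicator_names length must equal p", "pafgrid_invalid_input")
  dimnames(values) <- list(nm, nm)
  class(values) <- c("cor_matrix", class(matrix()))
  values
}

#' @export
print.cor_matrix <- function(x, digits = 3, ...) {
  cat("cor_matrix:", nrow(x), "indicators\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Test for a cor_matrix
#' @param x object to test.
#' @return logical flag.
#' @export
is_cor_matrix <- function(x) inherits(x, "cor_matrix")

as_cor_matrix <- function(x) {
  if (is_cor_matrix(x)) x else cor_matrix(as.matrix(x))
}

#' Pearson correlations from a raw data matrix
#'
#' @param data numeric matrix or data frame, observations in rows and
#'   indicators in columns; at least 3 rows.
#' @return a [cor_matrix()].
#' @export
cor_from_raw <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data))
    pafgrid_error("'data' must be numeric", "pafgrid_invalid_input")
  if (nrow(data) < 3L)
    pafgrid_error("at least 3 observations are required", "pafgrid_invalid_input")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(data)[sds == 0] %||% which(sds == 0)
    pafgrid_error(
      paste0("zero-variance column(s): ", paste(bad, collapse = ", ")),
      "pafgrid_degenerate_input")
  }
  R <- stats::cor(data, use = "pairwise.complete.obs")
  ## perfect collinearity can leave tiny asymmetries / diag drift
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R[R > 1] <- 1
  R[R < -1] <- -1
  cor_matrix(R, colnames(data))
}

#' Positive definiteness of a correlation matrix
#'
#' A matrix counts as positive definite when its smallest eigenvalue exceeds
#' `tol` (default 1e-8), separating genuine indefiniteness from
#' floating-point noise.
#'
#' @param R a [cor_matrix()] or coercible matrix.
#' @param tol eigenvalue tolerance.
#' @return logical flag.
#' @export
is_positive_definite <- function(R, tol = 1e-8) {
  R <- as_cor_matrix(R)
  ev <- eigen(unclass(R), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}

#' Smooth a correlation matrix to positive definiteness
#'
#' Eigenvalue smoothing: eigenvalues are floored at a small positive fraction
#' of the largest eigenvalue, the matrix is reconstructed and rescaled back
#' to unit diagonal, repeating until the smallest eigenvalue clears the
#' positive-definiteness tolerance. A matrix that is already positive
#' definite is returned unchanged, which makes the operation idempotent.
#' `mode = "abort"` instead raises an error on non-positive definite input,
#' mirroring programs that refuse such matrices.
#'
#' @param R a [cor_matrix()].
#' @param mode `"smooth"` to repair, `"abort"` to error on non-PD input.
#' @param tol positive-definiteness tolerance passed to
#'   [is_positive_definite()].
#' @return a positive definite [cor_matrix()].
#' @export
smooth_to_pd <- function(R, mode = c("smooth", "abort"), tol = 1e-8) {
  mode <- match.arg(mode)
  R <- as_cor_matrix(R)
  if (is_positive_definite(R, tol)) return(R)
  if (mode == "abort")
    pafgrid_error("correlation matrix is not positive definite",
                  "pafgrid_not_positive_definite")
  nm <- colnames(R)
  M <- unclass(R)
  for (pass in 1:100) {
    e <- eigen(M, symmetric = TRUE)
    floor_val <- 1e-7 * max(e$values)
    vals <- pmax(e$values, floor_val)
    M <- e$vectors %*% diag(vals, nrow(M)) %*% t(e$vectors)
    d <- sqrt(diag(M))
    M <- M / tcrossprod(d)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > tol) break
  }
  cor_matrix(M, nm)
}

#' Squared multiple correlations
#'
#' SMC of indicator i is the R-squared from regressing it on all other
#' indicators, computed as `1 - 1/solve(R)[i,i]`. A standard initial
#' communality estimate.
#'
#' @param R an invertible [cor_matrix()].
#' @return numeric p-vector in \[0, 1).
#' @export
smc <- function(R) {
  R <- as_cor_matrix(R)
  Rinv <- tryCatch(solve(unclass(R)),
                   error = function(e) pafgrid_error(
                     "correlation matrix is singular; consider smooth_to_pd()",
                     "pafgrid_singular_matrix"))
  out <- 1 - 1 / diag(Rinv)
  names(out) <- colnames(R)
  out
}

#' Maximum absolute correlations
#'
#' MAC of indicator i is the largest absolute correlation it has with any
#' other indicator; a fallback communality seed.
#'
#' @param R a [cor_matrix()].
#' @return numeric p-vector in \[0, 1\].
#' @export
mac <- function(R) {
  R <- as_cor_matrix(R)
  A <- abs(unclass(R))
  diag(A) <- 0
  out <- apply(A, 1, max)
  names(out) <- colnames(R)
  out
}

#' Read a correlation matrix from CSV
#'
#' Expects a square numeric matrix with a header row of indicator names and
#' the indicator names in the first column; symmetry is checked strictly.
#'
#' @param path CSV file path.
#' @return a [cor_matrix()].
#' @export
read_correlation_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  cor_matrix(m, colnames(m))
}

#' Read a raw data matrix from CSV
#'
#' Header row gives indicator names; one observation per row.
#'
#' @param path CSV file path.
#' @return numeric matrix.
#' @export
read_raw_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}
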