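#' Settings for varimax/promax rotation
#'
#' Collects the rotation settings that differ across the emulated programs:
#' the varimax algorithm (`"kaiser"` = classic pairwise planar rotations
#' maximizing the normal-varimax criterion; `"svd"` = iterative
#' gradient-projection scheme using singular value decomposition with the
#' sum of singular values as criterion), Kaiser normalization of loading
#' rows, whether the promax target matrix is built from the raw
#' (`"unnorm"`) or row-normalized (`"norm"`) varimax loadings, and the
#' promax power `k` (default 4 in the emulated programs; 3/2 recommended
#' for unnormalized/normalized targets respectively).
#'
#' @param varimax_type `"kaiser"` or `"svd"`.
#' @param kaiser_normalize divide loading rows by sqrt(communality) before
#'   varimax and re-multiply after (default `TRUE`).
#' @param p_type promax target construction: `"unnorm"` or `"norm"`.
#' @param k positive integer promax power.
#' @param rotate_tol convergence tolerance of the varimax iterations.
#' @param rotate_max_iter iteration/sweep cap for varimax.
#' @return object of class `rotation_settings`.
#' @export
rotation_settings <- function(varimax_type = c("kaiser", "svd"),
                              kaiser_normalize = TRUE,
                              p_type = c("unnorm", "norm"),
                              k = 4L,
                              rotate_tol = 1e-10,
                              rotate_max_iter = 1000L) {
  varimax_type <- match.arg(varimax_type)
  p_type <- match.arg(p_type)
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    pafgrid_error("'k' must be a positive integer", "pafgrid_invalid_input")
  if (rotate_tol <= 0 || rotate_max_iter < 1)
    pafgrid_error("invalid rotation tolerance or iteration cap",
                  "pafgrid_invalid_input")
  structure(
    list(varimax_type = varimax_type,
         kaiser_normalize = isTRUE(kaiser_normalize),
         p_type = p_type, k = k,
         rotate_tol = rotate_tol,
         rotate_max_iter = as.integer(rotate_max_iter)),
    class = "rotation_settings")
}

#' @export
print.rotation_settings <- function(x, ...) {
  cat("rotation_settings: varimax =", x$varimax_type,
      "| kaiser_normalize =", x$kaiser_normalize,
      "| target =", x$p_type, "| k =", x$k, "\n")
  invisible(x)
}

## normal-varimax criterion of a loadings matrix
varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(apply(L^2, 2, function(s) (p * sum(s^2) - sum(s)^2) / p^2))
}

## classic pairwise planar-rotation varimax; returns loadings + rotation
varimax_kaiser <- function(L, tol, max_iter) {
  p <- nrow(L)
  m <- ncol(L)
  Tm <- diag(m)
  history <- varimax_criterion(L)
  for (sweep_i in seq_len(max_iter)) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        x <- L[, i]; y <- L[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        theta <- atan2(num, den) / 4
        if (abs(theta) > 1e-15) {
          G <- matrix(c(cos(theta), sin(theta),
                        -sin(theta), cos(theta)), 2, 2)
          L[, c(i, j)] <- L[, c(i, j)] %*% G
          Tm[, c(i, j)] <- Tm[, c(i, j)] %*% G
        }
      }
    }
    crit_new <- varimax_criterion(L)
    crit_old <- history[length(history)]
    history <- c(history, crit_new)
    ## criterion is non-decreasing across sweeps; stop on relative stall
    if (crit_new - crit_old < tol * max(crit_old, .Machine$double.eps)) break
  }
  list(loadings = L, rotmat = Tm, criterion_path = history)
}

## gradient-projection varimax using SVD, sum of singular values as criterion
varimax_svd <- function(L, tol, max_iter) {
  p <- nrow(L)
  m <- ncol(L)
  Tm <- diag(m)
  d_old <- 0
  for (it in seq_len(max_iter)) {
    B <- L %*% Tm
    G <- t(L) %*% (B^3 - B %*% diag(drop(rep(1, p) %*% B^2) / p, m))
    s <- La.svd(G)
    Tm <- s$u %*% s$vt
    d <- sum(s$d)
    if (d < d_old * (1 + tol)) break
    d_old <- d
  }
  list(loadings = L %*% Tm, rotmat = Tm, criterion_path = NULL)
}

#' Varimax rotation (two algorithmic variants)
#'
#' @param loadings p x m unrotated loadings.
#' @param type `"kaiser"` (pairwise planar rotations) or `"svd"`
#'   (gradient projection via singular value decomposition).
#' @param normalize Kaiser-normalize rows before rotating.
#' @param tol,max_iter convergence control.
#' @return list with elements `loadings` (rotated, column signs normalized)
#'   and `rotmat` (m x m orthogonal rotation).
#' @export
rotate_varimax <- function(loadings, type = c("kaiser", "svd"),
                           normalize = TRUE, tol = 1e-10, max_iter = 1000L) {
  type <- match.arg(type)
  L <- as.matrix(loadings)
  m <- ncol(L)
  if (m < 1L) pafgrid_error("m >= 1 required", "pafgrid_invalid_input")
  if (m == 1L)
    return(list(loadings = L, rotmat = matrix(1, 1, 1)))
  sc <- rep(1, nrow(L))
  if (normalize) {
    sc <- sqrt(rowSums(L^2))
    if (any(sc < 1e-12))
      pafgrid_error("zero-communality row: cannot Kaiser-normalize",
                    "pafgrid_degenerate_row")
    L <- L / sc
  }
  res <- switch(type,
                kaiser = varimax_kaiser(L, tol, max_iter),
                svd = varimax_svd(L, tol, max_iter))
  out <- res$loadings * sc
  flips <- column_sign_flips(out)
  out <- apply_column_signs(out, flips)
  rot <- apply_column_signs(res$rotmat, flips)
  dimnames(out) <- dimnames(loadings)
  list(loadings = out, rotmat = rot, criterion_path = res$criterion_path)
}

#' Promax rotation from a varimax solution
#'
#' Builds the promax target by raising the (optionally row-normalized)
#' varimax loadings element-wise to the power `k` while preserving signs,
#' fits the oblique transformation by least squares against the
#' unnormalized varimax loadings, rescales it so the implied factors have
#' unit variance, and returns pattern, structure and factor
#' intercorrelation matrices. With one factor the oblique step is undefined
#' and the varimax loadings pass through with `phi = 1`.
#'
#' @param varimax_loadings p x m varimax-rotated loadings (unnormalized
#'   scale).
#' @param rotation m x m orthogonal rotation that produced them.
#' @param settings a [rotation_settings()] object (uses `p_type` and `k`).
#' @return object of class `rotated_solution` with `varimax_loadings`,
#'   `rotation_matrix`, `pattern`, `structure`, `phi`, `transformation`,
#'   `settings_used`.
#' @export
rotate_promax <- function(varimax_loadings, rotation = diag(ncol(varimax_loadings)),
                          settings = rotation_settings()) {
  A <- as.matrix(varimax_loadings)
  m <- ncol(A)
  if (m == 1L) {
    return(structure(
      list(varimax_loadings = A, rotation_matrix = as.matrix(rotation),
           pattern = A, structure = A, phi = matrix(1, 1, 1),
           transformation = matrix(1, 1, 1), settings_used = settings),
      class = "rotated_solution"))
  }
  Astar <- A
  if (settings$p_type == "norm") {
    rn <- sqrt(rowSums(A^2))
    rn[rn < 1e-12] <- 1  # leave all-zero rows untouched
    Astar <- A / rn
  }
  Q <- sign(Astar) * abs(Astar)^settings$k
  AtA <- crossprod(A)
  U <- tryCatch(solve(AtA, crossprod(A, Q)),
                error = function(e) pafgrid_error(
                  "collinear factors: least-squares target fit is singular",
                  "pafgrid_collinear_factors"))
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), m)
  pattern <- A %*% U
  ## deterministic column signs; propagate flips to U and phi
  flips <- column_sign_flips(pattern)
  pattern <- apply_column_signs(pattern, flips)
  U <- apply_column_signs(U, flips)
  phi <- solve(crossprod(U))
  phi <- (phi + t(phi)) / 2
  diag(phi) <- 1
  if (!is.null(colnames(A)))
    dimnames(phi) <- list(colnames(A), colnames(A))
  str_mat <- pattern %*% phi
  dimnames(pattern) <- dimnames(A)
  dimnames(str_mat) <- dimnames(A)
  structure(
    list(varimax_loadings = A, rotation_matrix = as.matrix(rotation),
         pattern = pattern, structure = str_mat, phi = phi,
         transformation = U, settings_used = settings),
    class = "rotated_solution")
}

#' Varimax followed by promax in one call
#'
#' @param paf_sol a `paf_solution` from [paf_extract()].
#' @param settings a [rotation_settings()].
#' @return a `rotated_solution`.
#' @export
rotate_solution <- function(paf_sol, settings = rotation_settings()) {
  vm <- rotate_varimax(paf_sol$loadings, type = settings$varimax_type,
                       normalize = settings$kaiser_normalize,
                       tol = settings$rotate_tol,
                       max_iter = settings$rotate_max_iter)
  rotate_promax(vm$loadings, vm$rotmat, settings)
}

#' @export
print.rotated_solution <- function(x, digits = 3, ...) {
  cat("rotated_solution:", nrow(x$pattern), "indicators,",
      ncol(x$pattern), "factor(s)\n")
  cat("pattern:\n"); print(round(x$pattern, digits))
  cat("phi:\n"); print(round(x$phi, digits))
  invisible(x)
}
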