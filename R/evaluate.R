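#' Tucker/Burt factor congruence of two loading columns
#'
#' Cosine-type similarity `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` in
#' \[-1, 1\]. Values of .85-.94 are conventionally read as fair similarity
#' and .95 or above as good similarity.
#'
#' @param x,y numeric vectors of equal length, not all zero.
#' @return scalar in \[-1, 1\].
#' @export
factor_congruence <- function(x, y) {
  if (length(x) != length(y))
    pafgrid_error("vectors must have equal length", "pafgrid_invalid_input")
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0)
    pafgrid_error("congruence undefined for a zero vector",
                  "pafgrid_zero_vector")
  max(-1, min(1, sum(x * y) / sqrt(nx * ny)))
}

## m x m matrix of congruences between columns of fitted (rows) and
## reference (cols)
congruence_matrix <- function(fitted, reference) {
  m <- ncol(fitted)
  outer(seq_len(m), seq_len(m),
        Vectorize(function(i, j) factor_congruence(fitted[, i], reference[, j])))
}

all_permutations <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(m)) {
    for (rest in all_permutations(m - 1L)) {
      out[[length(out) + 1L]] <- c(i, ifelse(rest >= i, rest + 1L, rest))
    }
  }
  out
}

#' Match fitted factor columns to reference columns
#'
#' Finds the column permutation and sign flips that maximize the sum of
#' absolute congruences over matched pairs — exhaustively over all m!
#' permutations for m <= 6, greedily for larger m. `permutation[j]` is the
#' fitted column assigned to reference column j; applying
#' `fitted[, permutation] * signs` (columnwise) aligns the fitted matrix
#' with the reference.
#'
#' @param fitted,reference p x m loading (or pattern) matrices.
#' @return object of class `factor_alignment` with `permutation`, `signs`,
#'   `mean_congruence_after` (mean signed congruence of the aligned pairs).
#' @export
align_factors <- function(fitted, reference) {
  fitted <- as.matrix(fitted); reference <- as.matrix(reference)
  if (!all(dim(fitted) == dim(reference)))
    pafgrid_error("shape mismatch between fitted and reference",
                  "pafgrid_invalid_input")
  m <- ncol(fitted)
  C <- congruence_matrix(fitted, reference)
  if (m <= 6L) {
    best <- NULL; best_score <- -Inf
    for (perm in all_permutations(m)) {
      score <- sum(abs(C[cbind(perm, seq_len(m))]))
      if (score > best_score) {
        best_score <- score
        best <- perm
      }
    }
    perm <- best
  } else {
    ## greedy: repeatedly take the largest remaining |congruence|
    perm <- integer(m)
    A <- abs(C)
    for (step in seq_len(m)) {
      idx <- which(A == max(A), arr.ind = TRUE)[1, ]
      perm[idx[2]] <- idx[1]
      A[idx[1], ] <- -Inf
      A[, idx[2]] <- -Inf
    }
  }
  signs <- vapply(seq_len(m), function(j) {
    s <- sign(C[perm[j], j])
    if (s == 0) 1 else s
  }, numeric(1))
  structure(
    list(permutation = as.integer(perm), signs = signs,
         mean_congruence_after = mean(abs(C[cbind(perm, seq_len(m))]))),
    class = "factor_alignment")
}

#' Apply a factor alignment to a matrix
#' @param x p x m matrix (fitted-side).
#' @param alignment a [align_factors()] result.
#' @return aligned p x m matrix in reference column order.
#' @export
apply_alignment <- function(x, alignment) {
  out <- as.matrix(x)[, alignment$permutation, drop = FALSE]
  apply_column_signs(out, alignment$signs)
}

#' Root mean squared error between loading matrices
#'
#' `sqrt(trace((L - Lhat)' (L - Lhat)) / (p * m))`, i.e. the element-wise
#' RMSE between a reference (population) and a fitted matrix. With
#' `align = TRUE` the fitted matrix is first matched to the reference with
#' [align_factors()].
#'
#' @param reference,fitted p x m matrices.
#' @param align match columns and signs first (default `TRUE`).
#' @return non-negative scalar.
#' @export
rmse_loadings <- function(reference, fitted, align = TRUE) {
  reference <- as.matrix(reference); fitted <- as.matrix(fitted)
  if (!all(dim(fitted) == dim(reference)))
    pafgrid_error("shape mismatch", "pafgrid_invalid_input")
  if (align) fitted <- apply_alignment(fitted, align_factors(fitted, reference))
  D <- reference - fitted
  sqrt(sum(D^2) / prod(dim(reference)))
}

#' Heywood-case detection
#'
#' A solution is a Heywood case when any communality or any absolute
#' unrotated loading reaches .998.
#'
#' @param sol a `paf_solution`, or any list with `communalities` and
#'   `loadings`.
#' @param threshold detection threshold (default .998).
#' @return logical flag.
#' @export
heywood_check <- function(sol, threshold = 0.998) {
  any(sol$communalities >= threshold) || any(abs(sol$loadings) >= threshold)
}

#' Salient indicator-to-factor map
#'
#' Maps each indicator to the set of factors on which its pattern
#' coefficient is salient, i.e. `|pattern[i, j]| >= threshold`.
#'
#' @param pattern p x m pattern matrix.
#' @param threshold salience threshold (default .20).
#' @return list of length p of integer factor-index vectors.
#' @export
salient_map <- function(pattern, threshold = 0.20) {
  pattern <- as.matrix(pattern)
  if (threshold <= 0)
    pafgrid_error("'threshold' must be positive", "pafgrid_invalid_input")
  out <- lapply(seq_len(nrow(pattern)),
                function(i) which(abs(pattern[i, ]) >= threshold))
  names(out) <- rownames(pattern)
  out
}

#' Count indicator-to-factor correspondence differences
#'
#' An indicator counts as different when its salient-factor sets differ
#' between two solutions: it loads saliently onto different factors, or is
#' salient in one solution only. If `alignment` is supplied, the factor
#' labels of `map_a` (fitted side) are first translated into the reference
#' labelling of `map_b`.
#'
#' @param map_a,map_b salient maps from [salient_map()] over the same
#'   indicators.
#' @param alignment optional [align_factors()] result (fitted = a side).
#' @return integer count in `0..p`.
#' @export
correspondence_diff <- function(map_a, map_b, alignment = NULL) {
  if (length(map_a) != length(map_b))
    pafgrid_error("maps must cover the same indicators", "pafgrid_invalid_input")
  if (!is.null(alignment)) {
    relabel <- order(alignment$permutation)  # fitted factor f -> reference label
    map_a <- lapply(map_a, function(f) sort(relabel[f]))
  }
  sum(vapply(seq_along(map_a), function(i) {
    !setequal(map_a[[i]], map_b[[i]])
  }, logical(1)))
}

#' Admissibility of a rotated solution
#'
#' Admissible means no Heywood case in the extraction and at least two
#' salient pattern coefficients on every factor.
#'
#' @param sol a `rotated_solution`.
#' @param paf the `paf_solution` it was rotated from.
#' @param threshold salience threshold (default .20).
#' @return logical flag.
#' @export
is_admissible <- function(sol, paf, threshold = 0.20) {
  if (heywood_check(paf)) return(FALSE)
  counts <- colSums(abs(as.matrix(sol$pattern)) >= threshold)
  all(counts >= 2)
}

#' Compare two factor solutions at a given analysis stage
#'
#' After aligning the two solutions' columns, computes element-wise mean and
#' maximum absolute differences, column-wise mean and minimum congruence,
#' and the number of indicator-to-factor correspondence differences.
#' Stage `"unrotated"` compares unrotated loadings, `"varimax"` the varimax
#' loadings, `"promax"` the promax pattern coefficients.
#'
#' @param a,b `efa_solution` objects from [efa()], or plain p x m matrices.
#' @param stage `"unrotated"`, `"varimax"`, or `"promax"`.
#' @param threshold salience threshold for the correspondence count.
#' @return object of class `solution_comparison`: `stage`, `abs_diff_mean`,
#'   `abs_diff_max`, `congruence_mean`, `congruence_min`,
#'   `correspondence_diff_count`.
#' @export
compare_solutions <- function(a, b, stage = c("promax", "varimax", "unrotated"),
                              threshold = 0.20) {
  stage <- match.arg(stage)
  pick <- function(x) {
    if (is.matrix(x)) return(as.matrix(x))
    switch(stage,
           unrotated = x$paf$loadings,
           varimax = x$rotation$varimax_loadings,
           promax = x$rotation$pattern)
  }
  A <- pick(a); B <- pick(b)
  if (!all(dim(A) == dim(B)))
    pafgrid_error("dimension mismatch", "pafgrid_invalid_input")
  al <- align_factors(A, B)
  A_al <- apply_alignment(A, al)
  diffs <- abs(A_al - B)
  congr <- vapply(seq_len(ncol(B)),
                  function(j) factor_congruence(A_al[, j], B[, j]), numeric(1))
  cdiff <- correspondence_diff(salient_map(A, threshold),
                               salient_map(B, threshold), alignment = al)
  structure(
    list(stage = stage,
         abs_diff_mean = mean(diffs),
         abs_diff_max = max(diffs),
         congruence_mean = mean(congr),
         congruence_min = min(congr),
         correspondence_diff_count = as.integer(cdiff)),
    class = "solution_comparison")
}

#' @export
print.solution_comparison <- function(x, ...) {
  cat(sprintf(
    "solution_comparison [%s]: |diff| mean %.4f max %.4f | congruence mean %.4f min %.4f | correspondence diffs %d\n",
    x$stage, x$abs_diff_mean, x$abs_diff_max,
    x$congruence_mean, x$congruence_min, x$correspondence_diff_count))
  invisible(x)
}
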