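#' Parse a population-model code
#'
#' Population pattern matrices are written as `p|m|lambda[|Nc]`: `p`
#' indicators, `m` factors, and `lambda` the set of unique non-zero pattern
#' coefficients with the period dropped (digits 1-9 read as .1-.9). An
#' optional `wb` suffix on the lambda field marks loadings mixed *within
#' and between* factors; an optional fourth field `Nc` gives the number of
#' cross-loadings. Examples: `18|3|6`, `18|6|369wb`, `18|3|46|3c`.
#'
#' @param code model code string.
#' @return list with `p`, `m`, `loadings` (numeric vector), `wb` flag,
#'   `n_cross`.
#' @export
parse_model_code <- function(code) {
  parts <- strsplit(code, "|", fixed = TRUE)[[1]]
  if (length(parts) < 3L || length(parts) > 4L)
    pafgrid_error(paste0("malformed model code: '", code, "'"),
                  "pafgrid_parse_error")
  p <- suppressWarnings(as.integer(parts[1]))
  m <- suppressWarnings(as.integer(parts[2]))
  if (is.na(p) || is.na(m) || p < 2L || m < 1L)
    pafgrid_error(paste0("malformed p or m in code: '", code, "'"),
                  "pafgrid_parse_error")
  lam_tok <- parts[3]
  wb <- grepl("wb$", lam_tok)
  lam_digits <- sub("wb$", "", lam_tok)
  if (!grepl("^[1-9]+$", lam_digits))
    pafgrid_error(paste0("malformed loading field '", lam_tok,
                         "' in code: '", code, "'"),
                  "pafgrid_parse_error")
  loadings <- as.numeric(strsplit(lam_digits, "")[[1]]) / 10
  n_cross <- 0L
  if (length(parts) == 4L) {
    if (!grepl("^[0-9]+c$", parts[4]))
      pafgrid_error(paste0("malformed cross-loading field '", parts[4],
                           "' in code: '", code, "'"),
                    "pafgrid_parse_error")
    n_cross <- as.integer(sub("c$", "", parts[4]))
  }
  list(p = p, m = m, loadings = loadings, wb = wb, n_cross = n_cross)
}

#' Build a block pattern matrix from a parsed model code
#'
#' Indicators are split into m contiguous blocks of p/m per factor. A single
#' loading value fills every non-zero entry; multiple values without `wb`
#' are held constant within a factor and cycled between factors; with `wb`
#' the values are cycled across the indicators within each factor.
#' Cross-loadings assign the smallest loading value to the next factor
#' (cyclically) for the first `n_cross` indicators.
#'
#' @param skeleton list from [parse_model_code()].
#' @return p x m pattern matrix.
#' @export
build_pattern <- function(skeleton) {
  p <- skeleton$p; m <- skeleton$m
  if (p %% m != 0L)
    pafgrid_error("p must be divisible by m for block designs",
                  "pafgrid_invalid_input")
  per <- p %/% m
  lam <- skeleton$loadings
  L <- matrix(0, p, m)
  for (f in seq_len(m)) {
    rows <- ((f - 1L) * per + 1L):(f * per)
    vals <- if (skeleton$wb)
      rep_len(lam, per)
    else
      rep(lam[((f - 1L) %% length(lam)) + 1L], per)
    L[rows, f] <- vals
  }
  if (skeleton$n_cross > 0L) {
    cross_val <- min(lam)
    for (i in seq_len(skeleton$n_cross)) {
      own <- ((i - 1L) %/% per) + 1L
      nxt <- (own %% m) + 1L
      L[i, nxt] <- cross_val
    }
  }
  dimnames(L) <- list(paste0("V", seq_len(p)), paste0("F", seq_len(m)))
  L
}

#' Default factor intercorrelation matrix
#'
#' The four levels used in the default simulation design: `"zero"`
#' (orthogonal factors), `"low"` (all intercorrelations .3), `"high"`
#' (all .7), `"mixed"` (off-diagonals cycled through .3, .5, .7).
#'
#' @param m number of factors.
#' @param level one of `"zero"`, `"low"`, `"high"`, `"mixed"`, or a single
#'   numeric intercorrelation.
#' @return m x m symmetric unit-diagonal matrix.
#' @export
phi_matrix <- function(m, level = c("zero", "low", "high", "mixed")) {
  if (is.numeric(level)) {
    phi_val <- level
    Phi <- matrix(phi_val, m, m)
    diag(Phi) <- 1
    return(Phi)
  }
  level <- match.arg(level)
  Phi <- diag(m)
  if (level == "mixed") {
    ## heterogeneous intercorrelations drawn from {.3, .5, .7}; for m = 3
    ## the three pairs take the three values, for larger m the values decay
    ## with factor distance (banded), which keeps the matrix positive
    ## definite for any m
    if (m == 3L) {
      Phi[1, 2] <- Phi[2, 1] <- 0.3
      Phi[1, 3] <- Phi[3, 1] <- 0.5
      Phi[2, 3] <- Phi[3, 2] <- 0.7
    } else {
      for (i in seq_len(m - 1)) {
        for (j in seq(i + 1, m)) {
          v <- switch(min(j - i, 3L), 0.7, 0.5, 0.3)
          Phi[i, j] <- Phi[j, i] <- v
        }
      }
    }
  } else {
    r <- switch(level, zero = 0, low = 0.3, high = 0.7)
    Phi[] <- r
    diag(Phi) <- 1
  }
  Phi
}

#' Construct a population model
#'
#' A population model is a pattern matrix Lambda (from the model-code
#' grammar) plus a factor intercorrelation matrix Phi; it is the source of
#' simulated data and the ground truth for recovery statistics.
#'
#' @param code model code (see [parse_model_code()]).
#' @param phi a Phi level name/value for [phi_matrix()] or a full m x m
#'   matrix.
#' @return object of class `population_model` with `code`, `phi_label`,
#'   `Lambda`, `Phi`, `p`, `m`, `loading_set`, `n_cross`.
#' @export
population_model <- function(code, phi = "zero") {
  sk <- parse_model_code(code)
  Lambda <- build_pattern(sk)
  if (is.matrix(phi)) {
    Phi <- phi
    phi_label <- "custom"
  } else {
    Phi <- phi_matrix(sk$m, phi)
    phi_label <- as.character(phi)
  }
  if (nrow(Phi) != sk$m || ncol(Phi) != sk$m)
    pafgrid_error("Phi dimension does not match m", "pafgrid_invalid_input")
  if (max(abs(Phi - t(Phi))) > 1e-12 || any(abs(diag(Phi) - 1) > 1e-12))
    pafgrid_error("Phi must be symmetric with unit diagonal",
                  "pafgrid_invalid_input")
  if (min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    pafgrid_error("Phi must be positive semidefinite", "pafgrid_invalid_input")
  structure(
    list(code = code, phi_label = phi_label, Lambda = Lambda, Phi = Phi,
         p = sk$p, m = sk$m, loading_set = sort(unique(sk$loadings)),
         n_cross = sk$n_cross),
    class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("population_model", x$code, "| Phi:", x$phi_label,
      "|", x$p, "indicators,", x$m, "factor(s)\n")
  invisible(x)
}

#' Regenerate the code of a population model
#' @param model a `population_model`.
#' @return the model-code string.
#' @export
model_code <- function(model) model$code

#' Population correlation matrix implied by a model
#'
#' `R = Lambda Phi Lambda'` with the diagonal overwritten to 1.
#'
#' @param model a [population_model()].
#' @return a [cor_matrix()].
#' @export
population_correlation <- function(model) {
  R <- model$Lambda %*% model$Phi %*% t(model$Lambda)
  off <- R[upper.tri(R)]
  if (any(abs(off) > 1))
    pafgrid_error(
      "invalid model: implied off-diagonal correlation outside [-1, 1]",
      "pafgrid_invalid_model")
  diag(R) <- 1
  cor_matrix(R, rownames(model$Lambda))
}

#' Sample multivariate-normal data from a correlation matrix
#'
#' Draws n observations from MVN(0, R) (unit variances) via the Cholesky
#' factor, with an eigendecomposition square root as fallback for matrices
#' that are positive semidefinite but numerically singular.
#'
#' @param R a positive (semi)definite [cor_matrix()].
#' @param n sample size.
#' @param seed optional integer seed for reproducibility.
#' @return n x p numeric matrix.
#' @export
sample_data <- function(R, n, seed = NULL) {
  R <- as_cor_matrix(R)
  p <- nrow(R)
  ev <- eigen(unclass(R), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    pafgrid_error("indefinite correlation matrix; smooth_to_pd() first",
                  "pafgrid_not_positive_definite")
  if (!is.null(seed)) set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n * p), n, p)
  ch <- tryCatch(chol(unclass(R)), error = function(e) NULL)
  X <- if (!is.null(ch)) {
    Z %*% ch
  } else {
    e <- eigen(unclass(R), symmetric = TRUE)
    Z %*% (diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors))
  }
  colnames(X) <- colnames(R)
  X
}

#' Default population-model manifest
#'
#' 27 pattern-matrix codes spanning 3 and 6 factors, indicator-to-factor
#' ratios from 2 to 12, homogeneous and heterogeneous loadings (between
#' factors and `wb` within-and-between), and cross-loading variants.
#' Combined with the four Phi levels of [phi_matrix()] this yields the
#' default set of 108 population models.
#'
#' @return data frame with a `code` column (27 rows).
#' @export
default_manifest <- function() {
  data.frame(code = c(
    ## three factors
    "6|3|3",  "6|3|6",  "6|3|9",
    "9|3|3",  "9|3|6",  "9|3|9",
    "18|3|3", "18|3|6", "18|3|9",
    "18|3|36", "18|3|46", "18|3|369wb",
    "18|3|46|3c", "36|3|6", "36|3|369wb",
    ## six factors
    "12|6|3", "12|6|6", "12|6|9",
    "18|6|3", "18|6|6", "18|6|9",
    "18|6|369wb", "36|6|3", "36|6|6",
    "36|6|369wb", "36|6|46", "36|6|46|6c"
  ), stringsAsFactors = FALSE)
}

#' Expand a manifest into population models
#'
#' @param manifest data frame with a `code` column (default
#'   [default_manifest()]).
#' @param phi_levels character/numeric vector of Phi levels (default the
#'   four standard levels).
#' @return list of [population_model()] objects (codes x levels).
#' @export
manifest_models <- function(manifest = default_manifest(),
                            phi_levels = c("zero", "low", "high", "mixed")) {
  out <- list()
  for (lev in phi_levels) {
    for (code in manifest$code) {
      out[[length(out) + 1L]] <- population_model(code, lev)
    }
  }
  out
}

#' Read a model manifest from YAML or CSV
#'
#' YAML manifests hold a `codes` list and optionally `phi_levels`; CSV
#' manifests hold a `code` column.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.csv`.
#' @return list with `manifest` (data frame) and `phi_levels`.
#' @export
read_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    list(manifest = data.frame(code = unlist(y$codes), stringsAsFactors = FALSE),
         phi_levels = unlist(y$phi_levels) %||% c("zero", "low", "high", "mixed"))
  } else {
    list(manifest = utils::read.csv(path, stringsAsFactors = FALSE),
         phi_levels = c("zero", "low", "high", "mixed"))
  }
}
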