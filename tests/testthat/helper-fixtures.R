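## shared fixtures and independent oracles for the test suite

equicorr <- function(p, r) {
  R <- matrix(r, p, p)
  diag(R) <- 1
  cor_matrix(R)
}

## a generic well-conditioned correlation matrix with distinct structure
random_pd_cor <- function(p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(200 * p), 200, p)
  ## induce mild common structure so correlations are non-trivial
  f <- rnorm(200)
  X <- X + outer(f, runif(p, 0.2, 0.8))
  cor_from_raw(X)
}

## brute-force factor alignment oracle: enumerate all permutations and sign
## patterns, score by sum of |congruence| over matched pairs
brute_force_alignment_score <- function(fitted, reference) {
  m <- ncol(fitted)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in Recall(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  signs_grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  best <- -Inf
  for (perm in perms(seq_len(m))) {
    for (si in seq_len(nrow(signs_grid))) {
      s <- signs_grid[si, ]
      score <- sum(vapply(seq_len(m), function(j) {
        x <- fitted[, perm[j]] * s[j]
        y <- reference[, j]
        abs(sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
      }, numeric(1)))
      if (score > best) best <- score
    }
  }
  best
}

## independent SMC oracle: R-squared of indicator i on the others via the
## normal equations, never via the inverse-diagonal identity
smc_by_regression <- function(R) {
  R <- unclass(R)
  p <- nrow(R)
  vapply(seq_len(p), function(i) {
    S <- R[-i, -i, drop = FALSE]
    c_vec <- R[-i, i]
    drop(crossprod(c_vec, solve(S, c_vec)))
  }, numeric(1))
}
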