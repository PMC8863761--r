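#' @keywords internal
"_PACKAGE"

## classed conditions so callers/tests can distinguish failure modes
pafgrid_error <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pafgrid_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

pafgrid_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "pafgrid_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

## sign convention used for every loading-like matrix in the package:
## the largest-magnitude element of each column is made positive.
## Returns the flip vector so rotation/transformation matrices can follow.
column_sign_flips <- function(L) {
  vapply(seq_len(ncol(L)), function(j) {
    i <- which.max(abs(L[, j]))
    s <- sign(L[i, j])
    if (s == 0) 1 else s
  }, numeric(1))
}

apply_column_signs <- function(L, flips) {
  sweep(L, 2, flips, `*`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## derive a per-record 32-bit seed from a master seed and a counter so that
## any subset of a simulation re-runs identically
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(counter) * 104729) %%
               2147483647)
}
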