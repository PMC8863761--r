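#' Principal axis factoring with promax rotation under one implementation
#'
#' The full pipeline: condition the correlation matrix (smooth or abort on
#' non-positive definite input per the implementation's `non_pd` policy),
#' extract m factors by iterative PAF (with the implementation's fallback
#' policy when SMC-style seeding fails), rotate with the configured varimax
#' variant, and transform obliquely with the configured promax variant.
#'
#' @param R a [cor_matrix()] (or coercible square matrix).
#' @param m number of factors.
#' @param spec an [implementation_spec()] (e.g. from [preset()] or
#'   [enumerate_grid()]).
#' @return object of class `efa_solution`: `paf` (a `paf_solution`),
#'   `rotation` (a `rotated_solution`), `R_used`, `spec`,
#'   `smoothing_applied`, `fallback_used`.
#' @export
efa <- function(R, m, spec = preset("best")) {
  R <- as_cor_matrix(R)
  smoothing_applied <- FALSE
  if (!is_positive_definite(R)) {
    R <- smooth_to_pd(R, mode = spec$non_pd)  # aborts under mode = "abort"
    smoothing_applied <- TRUE
  }
  pf <- paf_extract(R, m, spec$paf)
  rot <- rotate_solution(pf, spec$rot)
  structure(
    list(paf = pf, rotation = rot, R_used = R, spec = spec,
         smoothing_applied = smoothing_applied,
         fallback_used = pf$fallback_used),
    class = "efa_solution")
}

#' @export
print.efa_solution <- function(x, digits = 3, ...) {
  cat("efa_solution [", x$spec$label, "]\n", sep = "")
  print(x$paf, digits = digits)
  print(x$rotation, digits = digits)
  invisible(x)
}

solution_to_list <- function(sol) {
  list(
    implementation = sol$spec$label,
    settings = list(
      paf = unclass(sol$spec$paf),
      rotation = unclass(sol$spec$rot),
      non_pd = sol$spec$non_pd),
    smoothing_applied = sol$smoothing_applied,
    fallback_used = if (is.na(sol$fallback_used)) NULL else sol$fallback_used,
    converged = sol$paf$converged,
    iterations = sol$paf$iterations,
    initial_communalities = as.numeric(sol$paf$initial_communalities),
    communalities = as.numeric(sol$paf$communalities),
    unrotated_loadings = unname(as.matrix(sol$paf$loadings)),
    varimax_loadings = unname(as.matrix(sol$rotation$varimax_loadings)),
    pattern = unname(as.matrix(sol$rotation$pattern)),
    structure = unname(as.matrix(sol$rotation$structure)),
    phi = unname(as.matrix(sol$rotation$phi)),
    indicator_names = rownames(sol$paf$loadings))
}

write_matrix_csv <- function(m, path) {
  df <- as.data.frame(signif(as.matrix(m), 10))
  utils::write.csv(cbind(indicator = rownames(as.matrix(m)) %||%
                           seq_len(nrow(as.matrix(m))), df),
                   path, row.names = FALSE)
}

## auto-detect a correlation vs raw-data CSV: square with matching names
## means correlation input
read_efa_input <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  first_col_names <- is.character(df[[1]]) || is.factor(df[[1]])
  if (first_col_names && nrow(df) == ncol(df) - 1L) {
    return(list(R = read_correlation_csv(path), raw = NULL))
  }
  X <- read_raw_csv(path)
  list(R = cor_from_raw(X), raw = X)
}

#' Run one EFA from a CSV input and serialize the solution
#'
#' Auto-detects whether the input is a square correlation CSV or a raw
#' observations-by-indicators CSV (the latter is correlated first). Writes
#' the full solution bundle (unrotated/varimax loadings, pattern,
#' structure, phi, communalities, convergence metadata, and the complete
#' resolved settings) as JSON, plus one CSV per matrix, under `out` as a
#' path prefix.
#'
#' @param input input CSV path.
#' @param n_factors number of factors to extract.
#' @param spec an [implementation_spec()]; or use `preset_name`.
#' @param preset_name convenience: name understood by [preset()].
#' @param out optional output path prefix; when `NULL` nothing is written.
#' @return the `efa_solution`, invisibly when `out` is given.
#' @export
run_efa <- function(input, n_factors, spec = NULL, preset_name = "best",
                    out = NULL) {
  spec <- spec %||% preset(preset_name)
  R <- read_efa_input(input)$R
  sol <- efa(R, n_factors, spec)
  if (!is.null(out)) {
    jsonlite::write_json(solution_to_list(sol), paste0(out, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_matrix_csv(sol$paf$loadings, paste0(out, "_unrotated.csv"))
    write_matrix_csv(sol$rotation$varimax_loadings, paste0(out, "_varimax.csv"))
    write_matrix_csv(sol$rotation$pattern, paste0(out, "_pattern.csv"))
    write_matrix_csv(sol$rotation$structure, paste0(out, "_structure.csv"))
    write_matrix_csv(sol$rotation$phi, paste0(out, "_phi.csv"))
    return(invisible(sol))
  }
  sol
}

#' Compare two implementations on one data set, stage by stage
#'
#' Runs both implementations and reports the comparison statistics at the
#' three analysis stages (unrotated PAF loadings, varimax loadings, promax
#' pattern coefficients).
#'
#' @param input input CSV path, or a [cor_matrix()].
#' @param n_factors number of factors.
#' @param spec_a,spec_b two [implementation_spec()]s (or preset names).
#' @param out optional CSV path for the stage-by-stage report.
#' @return data frame with one row per stage: `stage`, `abs_diff_mean`,
#'   `abs_diff_max`, `congruence_mean`, `congruence_min`,
#'   `correspondence_diff_count`.
#' @export
run_compare <- function(input, n_factors, spec_a = "psych_smc",
                        spec_b = "spss", out = NULL) {
  if (is.character(spec_a)) spec_a <- preset(spec_a)
  if (is.character(spec_b)) spec_b <- preset(spec_b)
  R <- if (is.character(input)) read_efa_input(input)$R else as_cor_matrix(input)
  sol_a <- efa(R, n_factors, spec_a)
  sol_b <- efa(R, n_factors, spec_b)
  stages <- c("unrotated", "varimax", "promax")
  rows <- lapply(stages, function(st) {
    cmp <- compare_solutions(sol_a, sol_b, stage = st)
    data.frame(stage = st,
               abs_diff_mean = cmp$abs_diff_mean,
               abs_diff_max = cmp$abs_diff_max,
               congruence_mean = cmp$congruence_mean,
               congruence_min = cmp$congruence_min,
               correspondence_diff_count = cmp$correspondence_diff_count,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$implementation_a <- spec_a$label
  report$implementation_b <- spec_b$label
  if (!is.null(out)) utils::write.csv(report, out, row.names = FALSE)
  report
}
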