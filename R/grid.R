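#' Bundle PAF and rotation settings into one implementation
#'
#' @param paf a [paf_settings()] object.
#' @param rot a [rotation_settings()] object.
#' @param label unique label; generated from the settings when omitted.
#' @param non_pd what to do with a non-positive definite input correlation
#'   matrix: `"smooth"` (repair, as psych does) or `"abort"` (refuse, as
#'   SPSS does).
#' @return object of class `implementation_spec`.
#' @export
implementation_spec <- function(paf, rot, label = NULL,
                                non_pd = c("smooth", "abort")) {
  non_pd <- match.arg(non_pd)
  if (!inherits(paf, "paf_settings") || !inherits(rot, "rotation_settings"))
    pafgrid_error("'paf'/'rot' must be paf_settings / rotation_settings",
                  "pafgrid_invalid_input")
  spec <- structure(
    list(paf = paf, rot = rot, label = NULL, non_pd = non_pd),
    class = "implementation_spec")
  spec$label <- label %||% grid_label(spec)
  spec
}

#' Canonical grid label of an implementation's varied settings
#'
#' Encodes the seven settings varied in the implementation grid; presets
#' share a label with the grid member they instantiate.
#'
#' @param spec an [implementation_spec()].
#' @return character label.
#' @export
grid_label <- function(spec) {
  paste(spec$paf$init_comm,
        if (spec$paf$abs_eigen) "abs" else "raw",
        spec$paf$criterion_type,
        formatC(spec$paf$criterion, format = "e", digits = 0),
        spec$rot$varimax_type,
        spec$rot$p_type,
        paste0("k", spec$rot$k),
        sep = "_")
}

#' @export
print.implementation_spec <- function(x, ...) {
  cat("implementation_spec:", x$label, "| non_pd =", x$non_pd, "\n")
  invisible(x)
}

#' Enumerate the implementation grid
#'
#' Cartesian product of the varied settings. The default levels are the
#' ones compared in the emulated study: three initial communality
#' estimates, raw vs absolute eigenvalues, two convergence referents, two
#' convergence criteria, two varimax algorithms, two promax target types,
#' and two k rules (`always4` = 4 throughout; `tataryn` = 3 for
#' unnormalized and 2 for normalized targets). That grid has exactly
#' 3 x 2 x 2 x 2 x 2 x 2 x 2 = 192 members.
#'
#' @param init_comm,abs_eigen,criterion_type,criterion,varimax_type,p_type
#'   levels to cross.
#' @param k_rule subset of `c("always4", "tataryn")`.
#' @return list of [implementation_spec()] objects with unique labels.
#' @export
enumerate_grid <- function(init_comm = c("unity", "mac", "smc"),
                           abs_eigen = c(TRUE, FALSE),
                           criterion_type = c("sum", "max_individual"),
                           criterion = c(1e-3, 1e-6),
                           varimax_type = c("kaiser", "svd"),
                           p_type = c("unnorm", "norm"),
                           k_rule = c("always4", "tataryn")) {
  cells <- expand.grid(init_comm = init_comm, abs_eigen = abs_eigen,
                       criterion_type = criterion_type, criterion = criterion,
                       varimax_type = varimax_type, p_type = p_type,
                       k_rule = k_rule,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  specs <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    k <- if (row$k_rule == "always4") 4L
         else if (row$p_type == "unnorm") 3L else 2L
    implementation_spec(
      paf = paf_settings(init_comm = row$init_comm,
                         abs_eigen = row$abs_eigen,
                         criterion_type = row$criterion_type,
                         criterion = row$criterion,
                         smc_fail_fallback = "error"),
      rot = rotation_settings(varimax_type = row$varimax_type,
                              p_type = row$p_type, k = k))
  })
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    pafgrid_error("duplicate implementation labels in grid",
                  "pafgrid_duplicate_labels")
  specs
}

#' Named implementation presets
#'
#' * `psych_smc` — SMC seeds, sum referent, raw eigenvalues, criterion
#'   1e-3, svd varimax, unnormalized target, k = 4; smooths non-PD input;
#'   falls back to unity seeds when SMC seeding fails.
#' * `psych_unity` — as `psych_smc` but with unity seeds.
#' * `spss` — SMC seeds, max-individual referent, absolute eigenvalues,
#'   criterion 1e-3, kaiser varimax, row-normalized target, k = 4; aborts
#'   on non-PD input; MAC fallback.
#' * `best` — the settings found most accurate on average: SMC seeds, sum
#'   referent, absolute eigenvalues, criterion 1e-3, kaiser varimax,
#'   row-normalized target, k = 4.
#'
#' @param name preset name.
#' @return an [implementation_spec()] whose `label` is the preset name;
#'   `grid_label()` of the returned spec identifies its grid cell.
#' @export
preset <- function(name = c("best", "psych_smc", "psych_unity", "spss")) {
  name <- match.arg(name)
  spec <- switch(name,
    psych_smc = implementation_spec(
      paf_settings(init_comm = "smc", abs_eigen = FALSE,
                   criterion_type = "sum", criterion = 1e-3,
                   smc_fail_fallback = "unity"),
      rotation_settings(varimax_type = "svd", p_type = "unnorm", k = 4L),
      non_pd = "smooth"),
    psych_unity = implementation_spec(
      paf_settings(init_comm = "unity", abs_eigen = FALSE,
                   criterion_type = "sum", criterion = 1e-3,
                   smc_fail_fallback = "unity"),
      rotation_settings(varimax_type = "svd", p_type = "unnorm", k = 4L),
      non_pd = "smooth"),
    spss = implementation_spec(
      paf_settings(init_comm = "smc", abs_eigen = TRUE,
                   criterion_type = "max_individual", criterion = 1e-3,
                   smc_fail_fallback = "mac"),
      rotation_settings(varimax_type = "kaiser", p_type = "norm", k = 4L),
      non_pd = "abort"),
    best = implementation_spec(
      paf_settings(init_comm = "smc", abs_eigen = TRUE,
                   criterion_type = "sum", criterion = 1e-3,
                   smc_fail_fallback = "error"),
      rotation_settings(varimax_type = "kaiser", p_type = "norm", k = 4L),
      non_pd = "smooth"))
  spec$label <- name
  spec
}
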