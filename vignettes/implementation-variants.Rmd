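---
title: "PAF and promax implementation variants: models, settings, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAF and promax implementation variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafgrid)
```

## Why a grid of implementations

Iterative principal axis factoring (PAF) with promax rotation is a single
named procedure with several genuinely different published realizations.
The differences are small in isolation — which communality seed starts the
iteration, whether a negative eigenvalue is truncated or absolute-valued,
which referent decides convergence, which varimax algorithm feeds promax,
whether the promax target is row-normalized — but they interact, and near
decision thresholds (is a pattern coefficient salient or not?) they can
change substantive conclusions. `pafgrid` treats each choice as an
explicit setting so that the induced space of implementations can be
explored systematically rather than inherited silently from a default.

## The extraction model

PAF assumes the common factor model: observed indicator correlations are
generated by m latent factors, `R = Lambda Phi Lambda' + Psi` with
diagonal unique variances `Psi`. The procedure makes no distributional
assumption about the data; normality enters only through the simulation
engine. Extraction iterates on the *reduced* correlation matrix:

1. replace `diag(R)` with current communalities `h`;
2. eigendecompose; take the m leading eigenpairs;
3. loadings `L = V sqrt(mag(lambda))`, where `mag` is the absolute value
   when `abs_eigen = TRUE` and the raw eigenvalue otherwise;
4. `h <- rowSums(L^2)`; stop when the change is below the criterion.

Settings, defaults, and rationale:

* `init_comm` (`smc`, default): squared multiple correlations are the
  standard seed; `mac` and `unity` are the documented alternatives.
  Unity leaves `R` unchanged on the first pass and tends to inflate final
  communalities; MAC is the recommended remedy when SMC seeding fails.
* `abs_eigen` (`TRUE`): with SMCs on the diagonal the reduced matrix is
  usually indefinite. Taking `sqrt(|lambda|)` lets the iteration proceed
  through negative leading eigenvalues; with `abs_eigen = FALSE` such an
  eigenvalue is a hard failure (`pafgrid_negative_eigenvalue`), and the
  `smc_fail_fallback` policy decides whether the run errors (so
  simulations can count failures) or restarts with unity/MAC seeds.
* `criterion` (1e-3) and `criterion_type` (`sum`): the default tolerance
  of the emulated programs; 1e-6 is the stricter documented alternative.
  `sum` tests the change in the total communality, `max_individual` the
  largest single change. On well-behaved inputs both land within an
  order of magnitude of the criterion of each other.
* `max_iter` (5000): no published cap exists; non-convergence is
  reported via `converged = FALSE` rather than an error, because
  simulation runs must record rather than crash.

Numerical conventions: eigenvalues are ranked by raw value (not absolute
value) before the top m are taken, so absolute-valuing changes magnitudes
but never the selected subspace — the selection rule under
absolute-valuing is not documented anywhere we know of, and this choice
keeps the two treatments comparable. Column signs are fixed by making
each column's largest-magnitude loading positive. Eigenvalue ties at the
retained/discarded boundary (e.g. an identity input, or exchangeable
block models) make the retained subspace arbitrary; the decomposition's
ordering is kept and a classed warning (`pafgrid_eigen_tie`) is emitted.

## Rotation

Promax proceeds in two stages. First varimax, in one of two variants:
`kaiser` is the classic sequence of pairwise planar rotations maximizing
the normal-varimax criterion (the per-sweep criterion path is returned,
and is non-decreasing by construction); `svd` is the gradient-projection
iteration that rotates onto the SVD of the criterion gradient and
monitors the sum of singular values. Kaiser normalization (rows scaled to
unit communality before rotation, default on) matches the common
practice of both emulated programs. The two variants converge to the same
optimum on well-conditioned inputs but differ in their stopping behavior;
the `svd` variant reproduces `stats::varimax` to machine precision, which
the test suite uses as an independent cross-check.

Second, the oblique step: the target is the varimax loading matrix —
row-normalized to unit length first when `p_type = "norm"` — powered
element-wise with sign preservation, `q = sign(a) |a|^k`. The
least-squares transformation is always fitted against the *unnormalized*
varimax loadings, then rescaled so implied factors have unit variance;
`phi = (U'U)^-1` then has an exactly unit diagonal, and
`structure = pattern %*% phi` holds by construction. `k = 4` is the
default of the emulated programs; the grid also carries the documented
alternative rule (k = 3 for unnormalized, k = 2 for normalized targets).
With m = 1 both rotations are identity pass-throughs, because one-factor
solutions still flow through the comparison pipeline.

A deliberate consequence of the sign-preserving power: even k keep the
target's signs, which is required for promax to sharpen rather than
destroy simple structure.

## Evaluation statistics

Factor solutions are compared only after alignment, because factor order
and sign are arbitrary. Alignment maximizes the sum of absolute Tucker/
Burt congruences over matched column pairs, exhaustively over all m!
permutations for m <= 6 (the whole design space here) and greedily above.
The alignment objective is congruence, not RMSE, so that column matching
is decoupled from the error metric being reported.

* RMSE: `sqrt(trace((L - Lhat)'(L - Lhat)) / (p m))` after alignment.
* Heywood cases: any communality or absolute unrotated loading >= .998.
* Salience: `|pattern| >= .20` in absolute value — the threshold is
  documented without a sign rule, and the absolute reading is the
  standard one.
* Admissibility: no Heywood case and >= 2 salient pattern coefficients
  per factor.
* Congruence after promax is computed on pattern (not structure)
  coefficients, consistent with pattern coefficients being the compared
  quantity everywhere else.

## The population-model grammar and the default manifest

Models are written `p|m|lambda[|Nc]`. The grammar fixes p, m, the loading
value set, a within/between mixing flag (`wb`), and a cross-loading
count, but not the exact placement of heterogeneous loadings; placement
is therefore a package convention, isolated in `build_pattern()` and
overridable by supplying a custom manifest:

* multiple values without `wb`: constant within a factor, cycled between
  factors;
* with `wb`: cycled across indicators within each factor;
* cross-loadings: the first `Nc` indicators gain the smallest loading
  value on the adjacent factor.

The default manifest holds 27 codes crossing 3 and 6 factors,
indicator-to-factor ratios from 2 to 12, loading sets from weak (.3) to
strong (.9) including heterogeneous and cross-loading designs, and is
crossed with four factor-intercorrelation levels — orthogonal, .3, .7,
and mixed — for 108 population models. The mixed level assigns {.3, .5,
.7} exactly to the three factor pairs when m = 3; for m > 3 a full cyclic
assignment of those values is not positive definite, so the values decay
with factor distance (.7 adjacent, .5 at distance two, .3 beyond), which
is positive definite for any m. Every code in the default manifest was
chosen so that every code-by-Phi combination implies a valid positive
definite population correlation matrix; `population_correlation()`
validates this at construction, and rejects impossible models (implied
correlations outside [-1, 1]).

The sampler draws `MVN(0, R)` via the Cholesky factor (eigendecomposition
square root for PSD-but-singular inputs), with zero means and unit
variances so the covariance equals the correlation matrix.

### What the generator does and does not emulate

It emulates clean common-factor populations observed with sampling error
only. It does not emulate model error (real data are never exactly a
factor model), non-normal or ordinal indicators, missing data, or
sampling designs. Passing recovery tests therefore demonstrates that an
implementation recovers a true factor structure under ideal conditions at
realistic sample sizes — not that it is robust to the additional
distortions of real data.

## Simulation design and seeding

`run_simulation()` crosses models, sample sizes, replicates, and
implementations. The full documented design — 108 models, N in
{180, 450}, 1000 replicates — enumerates 216,000 data sets and is
deliberately only *enumerated* by default (`design_size()`); executed
studies should scale `reps` to their hardware. Each record carries a seed
derived from the master seed and a running dataset counter (a fixed
linear-congruential mix), so any prefix subset of a study re-runs
bit-identically and individual records can be reproduced in isolation.
Failures (negative eigenvalues under `abs_eigen = FALSE` with an `error`
fallback, non-convergence) are recorded per record, never raised.

The test suite and the acceptance script use scaled-down sizes chosen to
make their statistical claims comfortably decidable on one CPU in
minutes: 20 replicates at n = 10,000 for the orthogonal-recovery check
(mean RMSE < .05 with observed values near .008), 100 replicates at
n = 450 for the data-structure contrast (the observed MRMSE gap between
the hard and easy structure is ~.12, an order of magnitude above
replicate noise), and 20 datasets at n = 180 for the divergence check
(every dataset diverges in practice; one suffices to pass).

## Presets

Four named presets instantiate documented implementations as points in
the grid: `psych_smc` and `psych_unity` (sum referent, raw eigenvalues,
svd varimax, unnormalized target, k = 4, smoothing of non-PD inputs,
unity fallback), `spss` (max-individual referent, absolute eigenvalues,
kaiser varimax, row-normalized target, k = 4, abort on non-PD input, MAC
fallback), and `best` (SMC seeds, sum referent, absolute eigenvalues,
criterion 1e-3, kaiser varimax, normalized target, k = 4) — the
combination found most accurate on average in large-scale comparisons.
The kaiser variant here implements the classic normal-varimax algorithm;
the SPSS-internal criterion is known to deviate slightly from the
original publication in ways that are not publicly specified, so the
`spss` preset is "SPSS-like" at the level of documented settings, not
bit-identical output. Correlation-matrix smoothing is likewise specified
only by its goal ("a highly similar positive definite matrix"); the
implementation here floors eigenvalues at 1e-7 of the largest, rescales
to unit diagonal, and repeats until the smallest eigenvalue clears the
positive-definiteness tolerance (1e-8) — the floor is set above the
tolerance precisely so that smoothing is idempotent and its output
passes `is_positive_definite()`.

## Factor retention

`parallel_analysis()` computes eigenvalues of the SMC-reduced correlation
matrix (diagonal replaced by SMCs) for the data and for standard-normal
random data of the same dimensions, retaining factors while the first
empirical eigenvalue exceeds the 95th percentile of the first random
eigenvalues and subsequent ones exceed the corresponding random means.
Random data are drawn from normal distributions (rather than resampled),
matching the reduction applied to the empirical matrix.
`find_admissible()` implements the downward search used in comparative
real-data pipelines: start from a caller-supplied factor count (typically
the larger of the theoretical and parallel-analysis counts), fit two
implementations, and decrement until both solutions are admissible,
recording the per-step trace and each implementation's own first
admissible count.

## Known limitations

* Only PAF extraction and varimax/promax rotation are implemented; ML,
  minres, oblimin, and hierarchical (Schmid-Leiman) transformations are
  out of scope.
* Pearson correlations only; ordinal indicators would need polychoric
  input, which can be supplied as a pre-computed correlation CSV but is
  not computed here.
* The exact heterogeneous-loading and cross-loading placements of
  published simulation designs are not recoverable from their codes; the
  conventions above reproduce the designs' structure, and a custom
  manifest plus explicit `Lambda`/`Phi` matrices can reproduce any exact
  design.
* Exhaustive factor alignment is O(m!); beyond m = 6 the greedy matcher
  is used and is not guaranteed optimal.
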