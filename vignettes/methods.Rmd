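---
title: "Predicting 14-3-3 phosphopeptide binding affinities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 14-3-3 phosphopeptide binding affinities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pep1433)
```

## The problem

The seven human 14-3-3 isoforms bind phosphopeptide motifs
P₋₃P₋₂P₋₁–pS/T–P₊₁P₊₂P₊₃. Fragment-based microarrays measure binding
intensities over two factorial sublibraries, each varying only one side's
residue triple: ten building blocks (R, E, F, L, Q, A, G, V, K, P) at the
positions adjacent to the phospho-center and five (R, E, F, L, P) at the
outermost position, i.e. 5 × 10 × 10 = 500 motifs per terminal. The
modeling task is to regress affinity on sequence so that the full
20 × 20 × 20 space per terminal (16,000 motifs in total) can be scored,
and downstream isoform-specificity questions can be asked of the
predictions.

This vignette documents the model, the numerical choices, and what the
package's synthetic benchmarks do and do not establish.

## Relevance sampling

A single global regression over a combinatorial library mixes chemically
unrelated motifs. Instead, each query gets a *dynamic* training set: a
training motif is retained iff at least one of the three aligned variable
positions carries a residue from the same side-chain category as the
query's residue there. The five categories partition the 20 amino acids:
positive-charged (R, H, K), negative-charged (D, E), polar-uncharged
(S, T, N, Q), hydrophobic (A, I, L, M, F, W, Y, V), special (C, G, P).

Matching is position-wise — a category shared across *different*
positions does not count, because the library design makes only aligned
positions comparable. Over the 500-motif factorial sublibrary with one
motif left out this retains 301.864 candidates on average (exact brute
force over all 500 × 499 ordered pairs), matching the ≈ 300 regime the
experimental library was designed around.

For queries inside a factorial library the filter can never come back
empty (a motif always shares categories with itself and its neighbors);
for arbitrary 20-AA queries it theoretically can, so an empty selection
falls back to the full candidate list with a warning rather than training
on nothing.

## Features

Each motif maps to 54 features.

* **27 positional values.** Nine physicochemical properties per residue —
  hydrophobicity H1, hydrophilicity H2, hydrogen bond H3, side-chain
  volume V, polarity P1, polarizability P2, SASA, net charge index NCI,
  mass — each column standardized to zero mean and unit SD over the 20
  amino acids. The SD divisor is the population form (n = 20): the
  canonical amino acids are the whole population of interest, not a
  sample; the divisor is recorded in the normalized table so the
  alternative is a one-line switch. The shipped property table is kept
  verbatim, including the (likely typographical) duplication of four
  values between Q and R — correcting printed reference data silently
  would be worse than carrying it.
* **27 auto-cross covariance (AC) values.** For property *j* with
  standardized values *x₁, x₂, x₃* at the three variable positions and
  mean *m*: AC(m,n,j) = (xₘ − m)(xₙ − m) for the pairs (1,2), (1,3),
  (2,3). Only same-property AC terms are used (cross-property covariance
  would inflate the feature count far beyond what 300 training motifs
  support). Because the three deviations sum to zero, the three pair
  terms of one property sum to −½ Σᵢ(xᵢ − m)², a non-positive quantity
  that vanishes exactly for property-constant triples — a convenient
  internal consistency check that the test suite exercises on random
  motifs.

AC terms are computed from the *standardized* properties, consistent with
standardizing before any feature is formed; the three positions entering
the mean are the query terminal's own (the opposite terminal is wildcard
and contributes nothing, as does the pS/pT center, which is metadata
only).

## Regression

The affinity model is linear, f(X) = β₀ + Σⱼ Xⱼβⱼ, fitted by the elastic
net:

min over β of RSS + λ Σⱼ [ ½(1 − α)βⱼ² + α|βⱼ| ]

with α = 0 ridge, α = 1 LASSO. Choices that the objective leaves open:

* **Standardization.** Features are z-scored on each training set before
  penalization and the intercept is unpenalized; predictions are returned
  on the intensity scale. Affinities are regressed untransformed — the
  intensities are already a linear readout, and an optional log-normal
  variant lives in the generator, not the fit.
* **λ path.** Per α, a geometric grid of `nlambda` values (default 100)
  from λ_max — the smallest λ with all coefficients zero, computed as
  2·max|Xᵀy|/max(α, 0.001) on the standardized design — down to
  10⁻⁴·λ_max.
* **Selection.** λ minimizes mean 10-fold CV squared error (no
  one-standard-error rule); ties take the larger λ. α is scanned over
  0, 0.1, …, 1 (11 values) and ties take the smaller α — deterministic,
  and ridge-like fits are stabler on correlated features. Folds are
  assigned by seeding a shuffle and dealing round-robin, so the whole
  selection is a deterministic function of the seed.
* **Per-query selection.** Hyperparameters are re-selected for every
  query (the "dynamic model" reading); `en_config(shared_hyperparams =
  TRUE)` instead selects once on the pooled training set, for users who
  prefer one model family per isoform.

The solver is cyclic coordinate descent on the Gram matrix (C++), with
warm starts down the λ path, active-set cycling, and early path
termination once the training RSS improvement falls below `fdev`
(default 10⁻⁵) of the null RSS — the standard lasso-path economies. The
factorial design makes the 54-column Gram numerically rank-deficient, so
the smallest-λ tail would otherwise dominate runtime while changing
nothing the CV curve cares about. CV fits use a loose coordinate
tolerance (`tol`, default 10⁻³ on standardized-scale coefficients; the
response is in intensity units of order 10²–10³), while each final
per-query fit is re-solved at ≤ 10⁻⁶. Correctness of the solver is
certified in the tests by the closed-form ridge solution, ordinary least
squares at λ = 0, subgradient KKT conditions at interior α, and glmnet
agreement at α = 1 under the objective rescaling λ_glmnet = λ/(2N).

Degenerate inputs are defined, not fatal: constant columns keep zero
coefficients, and a constant response with collinear features yields the
flat model (intercept = mean, slopes 0).

## Verification metrics

Following the field's usage, `pcc` is 1 − SSE/SST — a
coefficient-of-determination-type statistic (1 for perfection, 0 for the
constant-mean predictor, negative below that), *not* the product-moment
correlation, despite the name it usually carries in this literature. It
is implemented literally and documented as such; the genuine Pearson r is
reported alongside. RMSE takes the square root (the "root" in the name
and the RMSE = 0 perfect-predictor anchor make the radical unambiguous
even where typography is not). Leave-one-out verification holds each
motif out, re-runs relevance sampling and CV on the remainder, and
computes both metrics per terminal over the held-out predictions.

## Specificity analyses

Top-k extraction breaks affinity ties by the lexicographically smaller
motif string, making every downstream list deterministic. Position
frequency matrices are per-position distributions over the 20 amino
acids, optionally affinity-weighted; positions not covered by the input
terminal are `NA`, never silently zero. The letter-height style display
of scoring matrices on top binders is taken as affinity-weighted
frequency (the convention is not fixed anywhere authoritative, so the
unweighted mode is a flag away). Consensus binders intersect all
isoforms' top-k lists; isoform-specific binders subtract every other
isoform's list. For the 1,000-motif regime k = 100 is conventional, for
the 16,000-motif space k = 500.

The similarity score against a reference binder counts, per aligned
position, 3 for an identical residue, 1 for a same-category residue, 0
otherwise (total ≤ 9). Its randomization test draws motifs
position-uniformly and reports p = #(null ≥ observed)/n_iter, without a
+1 continuity correction, so granularity at 1000 iterations is 0.001.
The null alphabet is a genuine modeling choice — all 20 amino acids or
the library building blocks — and both are provided; the building-block
null is oriented by terminal (outermost-position alphabet first for N,
last for C).

## Synthetic data: what it does and does not show

The measured intensities of the original 1,000-motif arrays are not
deposited anywhere, so the package ships a generator rather than data.
Two truth models:

* **linear-sparse** — affinity = intercept + Xβ* + ε with β* having 8
  nonzero entries of magnitude ~50–150 (drawn reproducibly from a seed)
  on the 54 features, intercept 1000, ε Gaussian. This is the method's
  own structural assumption, so recovery benchmarks measure the
  machinery, not the biology.
* **consensus** — affinity = intercept + per-position residue effects,
  defaulting to +300 for Arg at P₋₃ and +200 for Pro at P₊₂ over an
  intercept of 200: the canonical RXXpSXP-style preference, planted so
  that top-binder summaries should visibly recover Arg/Pro.

Intensities are clipped at zero (non-negative readout); defaults keep
the intercept large enough that clipping is rare, and a strictly positive
log-normal variant exists behind a flag. Noise levels in benchmarks are
stated relative to the signal SD (e.g. "5% noise" = noise SD 0.05 × SD of
the noise-free affinities).

Coefficient-recovery benchmarks run on the full-alphabet design, where
the 54 features are full-rank (condition number ≈ 41), with an intercept
high enough that the noise-free signal never touches the zero clip — on
the building-block sublibrary the feature matrix has rank 49, so
individual coefficients are not identifiable there even though
predictions are unaffected. Prediction benchmarks (leave-one-out PCC and
RMSE) use the 500-motif building-block library, matching the regime the
method was designed for.

What passing benchmarks show: the pipeline recovers linear truths through
relevance sampling, featurization and per-query CV (noiseless LOOCV
PCC ≥ 0.99; ≥ 0.9 at 5% noise on the 500-motif library), and planted
positional preferences surface in the top-50 weight matrix. What they do
*not* show: performance on real microarray intensities, whose noise is
neither Gaussian nor homoscedastic, whose affinity distribution is heavy
tailed, and whose truth is not exactly linear in these 54 descriptors.
Published real-data figures (per-isoform PCC ≈ 0.6–0.9) are therefore not
reproduction targets for this package.

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely from generated data:
the full 500-motif sublibrary for combinatorics, sampling and the
5%-noise LOOCV benchmark (with `nlambda = 30`, CV `tol = 10⁻²`), the
8,000-motif full-alphabet library for coefficient recovery, 10,000
random motifs for the feature identities, and 60–120-motif subsets with
reduced CV settings (4–5 folds, 10–20 λ values, and a shallow
`lambda_min_ratio` for pure-noise nulls, which never favor weak
penalties) for the noisier property-style checks. This keeps the whole
suite in the minutes range while leaving every scientific assertion
intact at full precision where exactness matters (enumeration counts,
the 301.864 sampling mean, similarity scores, metric anchors).

## Known limitations

* Position-wise category matching cannot see cross-position chemistry
  (e.g. charge swaps between P₋₃ and P₋₁).
* The per-query CV re-selection makes predictions for near-identical
  queries slightly non-smooth (different folds can pick different λ);
  `shared_hyperparams = TRUE` trades that for global smoothness.
* The 54 features are rank-deficient on single-terminal factorial
  libraries; coefficients are therefore not individually identifiable at
  small λ (predictions are fine — another reason the package reports
  prediction metrics, not coefficient tables, for real data).
* No modeling of full-length substrate context, phospho-center identity
  (pS vs pT is carried as metadata only), or inter-isoform shared
  structure (each isoform is fitted independently).
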