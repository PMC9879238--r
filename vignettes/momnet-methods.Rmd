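---
title: "momnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{momnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momnet)
```

## What the package does

`momnet` implements a two-part analysis workflow for unbalanced two-group
multi-omic cohorts — the motivating setting is urine metabolomics plus
targeted proteomics from ARDS patients of two etiologies (42 vs 17 samples)
— together with a synthetic cohort generator that plants every quantity the
analysis is supposed to recover. Part one contrasts the two diagnosis groups
molecule by molecule and integrates the hits through a Gaussian graphical
model (GGM); part two associates molecules with clinical manifestations
(AKI, platelet count, PaO2/FiO2 ratio, mortality) within each group and
extracts a fold-change signature.

## Preprocessing model

Raw abundances are assumed lognormal with a per-sample multiplicative
dilution factor — the dominant nuisance in urine, where concentration varies
freely. The chain is fixed, in this order, and the `scale_state` field of
`omics_matrix` makes running it out of order an error:

1. **Missingness filter.** A feature is removed iff its missing fraction is
   *strictly greater than* 25% (`max_missing_frac = 0.25`). The boundary is
   deliberate: at n = 59, 15 missing (25.4%) is removed, 14 (23.7%) is kept.
2. **Probabilistic quotient normalization (PQN).** Reference = per-feature
   median spectrum of the raw data; each sample is divided by the median of
   its feature-wise quotients against the reference. Missing values are
   ignored pairwise (imputation comes later, so PQN must tolerate holes).
   We deliberately skip a preceding total-intensity normalization: the
   median-reference variant is the common default, and it is directly
   testable — on synthetic cohorts with planted dilution
   `exp(N(0, 0.5^2))`, the estimated quotient medians correlate with the
   true dilution factors at r > 0.99 for 500 features.
   PQN against a *fixed* reference is exactly idempotent (every second-pass
   quotient median is 1). If the reference is recomputed from normalized
   data, the result drifts at the ~1% level; `pqn_normalize(reference =)`
   exposes the fixed-reference form, and the tests assert idempotence in
   that exact sense.
3. **log2 transform.**
4. **kNN imputation** in *feature* space (k = 10 by default; k is not pinned
   down by any external constraint, so it is exposed). Distance between two
   feature profiles is the RMS difference over samples observed in both —
   Euclidean distance scaled by the number of shared samples — so sparsely
   shared pairs are not spuriously "close". Observed entries are never
   touched; the suite checks bit-exact preservation and that kNN beats
   per-feature mean imputation in RMSE on held-out MCAR holes.
5. **Duplicate-assay averaging**, arithmetic mean in the current (log2)
   scale. Placing this after log2 means averaging geometric means of raw
   abundances, which is the right call for multiplicative assay noise; a
   pre-log position would be equally defensible and the operation accepts
   any scale. `default_duplicate_proteins()` carries the conventional
   ten-protein Olink duplicate panel.

## Differential analysis

Each molecule is regressed on an intercept plus the outcome by OLS, with
no covariates (age/sex/BMI are severity determinants in this setting, so
adjusting for them would absorb signal). For a 0/1 outcome this is exactly
the pooled-variance two-sample t-test — the suite asserts agreement to
1e-10 — and the coefficient is the log2 fold change. Group coding is
bacterial = 0 / covid = 1 and survivor = 0 / non-survivor = 1, so positive
estimates mean "higher in COVID-19" / "higher in non-survivors".

BH correction is applied per analysis across both omics layers jointly
(`bh_scope = "joint"`); mixed-omics hit counts per analysis only make sense
under joint correction, but `"per_omics"` is available since the choice is
not externally fixed. Significance is strict: `p_adj < 0.05`. Node
annotation uses the signed score `p_score = -log10(p_adj) * d` with
`d = sign(t)`; `p_adj = 0` is an error by design (callers must floor).

The mortality signature takes significant molecules with
`|log2FC| >= 2` — the threshold is inclusive, and configurable because
"larger than 2" vs "larger than or equal to 2" is genuinely ambiguous in
common usage.

## Pathway filtering

No enrichment statistic is computed — pathways are summarized by counting
significant molecules. A pathway is retained if it is *eligible* (a
sub-pathway whose name contains "metabolism", case-insensitively, or a KEGG
pathway whose category is not "Human Diseases") and has at least 3
significant molecules. The KEGG disease categorization is data, not code:
it rides in on the annotation table's `kegg_category` column.

## GGM network inference

With p ≈ 1000 features and n = 59 samples the sample correlation matrix is
singular, so the GGM uses the analytic shrinkage estimator: standardize,
compute R, and shrink toward the identity with
λ\* = Σ Var̂(r_ij) / Σ r_ij², clipped to [0, 1]. This is the documented
estimator of the standard shrinkage-GGM toolchain, and during development
our implementation was checked to agree with it to machine precision.
Partial correlations come from the inverse of the shrunk matrix:
pcor(i, j) = −Ω_ij / √(Ω_ii Ω_jj).

Edge significance models the observed partial correlations as a mixture of
a null component f0(r; κ) ∝ (1 − r²)^((κ−3)/2) — the exact null of a
correlation under κ effective degrees of freedom, so r² ~ Beta(1/2,
(κ−1)/2) — and a uniform alternative. κ (and the null fraction η0) are
fitted by deterministic nested bounded likelihood maximization, κ bracketed
in [3, 1e6]. Two-sided p-values from the fitted null are corrected by BH
(default) or by a tail-area empirical FDR (`method = "efdr"`, the q-value
flavor of classic GGM software); edges are pairs below the threshold. The
two flavors give different edge counts on real data — which is why both are
exposed — but both recover planted structure with precision ≥ 0.9 in the
acceptance checks. When every partial correlation is exactly zero (full
shrinkage), the κ fit is skipped and the edge set is empty by construction.

## Subnetworks

`neighborhood()` is an unweighted BFS ball: nodes within `max_depth` hops
of any seed, seeds included at distance 0. Partial-correlation magnitudes
are ignored for reachability — an edge is an edge once it passed the FDR
cut. `induced_subgraph()` keeps exactly the edges with both endpoints
inside. Seed names resolve exactly, then case-insensitively (erroring on
ambiguity), and unknown seeds report the nearest ids by edit distance.

## The synthetic world

The generator is first-class, tested code, and its defaults are a stated
world, fixed once:

* 42 + 17 samples, mirroring the motivating cohort's imbalance.
* 150 metabolites + 50 proteins by default — a scaled-down stand-in for a
  708 + 266 panel so that the default pipeline runs in seconds; tests that
  need other sizes say so explicitly.
* Sparse precision matrix: Erdős–Rényi edges (density 0.02), entries
  ±strength (0.3), diagonal loading to condition number ≤ 1e3. Loading the
  diagonal preserves the zero pattern, so non-edges have *exactly* zero
  partial correlation — the ground truth is exact, not approximate.
* Group shifts of ±`effect_size_log2` (default 2; acceptance power checks
  use 3) on a random 10% of features. The source study reports no effect
  size distribution for its hits, so this is a free parameter, chosen once.
* Mortality follows a logistic link on 10 planted features (log-odds slope
  `outcome_effect_log2` per SD); AKI, platelets and PaO2/FiO2 are drawn
  without molecular signal, at clinically plausible marginals, so the
  clinical panel has a planted positive and planted nulls.
* Dilution `exp(N(0, 0.5²))`, MCAR missingness at 5% (an optional
  left-censoring mode exists, off by default, because the real missingness
  mechanism is uncharacterized), over-filtered features forced strictly
  above the 25% threshold, duplicate assays as log2-Gaussian copies
  (SD 0.1).

What a green test does **not** establish: the generator has no batch
effects, no platform-specific feature identities, no realistic pathway
structure, and MCAR missingness only — so the suite validates the
*machinery* (estimators, thresholds, graph semantics, recovery under the
stated model), not fidelity to any particular real dataset. Reproducing
the source study's printed counts (220 molecules, 3566 edges, the
66-node/106-edge subnetwork) requires its deposited matrices, which the
offline test environment cannot download; those semantics are documented
at the operations that embody them and exercised through
`run_pipeline(config)` with file inputs.

## Numerical choices and degenerate inputs

* p-values are floored at `.Machine$double.xmin` before BH so that
  `p_score` stays finite.
* Constant molecules yield estimate 0, p = 1, and a `degenerate` flag —
  not an error, since filtered real panels can still contain near-constant
  assays. A constant *outcome* is an error.
* λ\* = 0 with p ≥ n makes the shrunk matrix singular; the error message
  says to use nonzero shrinkage rather than silently pseudo-inverting.
* All randomness flows from explicit integer seeds; `with_seed()` restores
  the caller's RNG state, and two runs of `run_pipeline()` from the same
  config produce byte-identical tables and manifests (manifests omit
  timestamps for exactly this reason).

## Known limitations

* The κ-null mixture assumes a unimodal null around zero; grossly
  non-Gaussian data (heavy clumping, unremoved batch structure) can bias
  κ and hence edge p-values.
* The clinical panel refits each outcome independently; no multivariate or
  survival modeling is attempted.
* GraphML export is static; no layout or interactive view is produced.
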