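---
title: "Methods: profiling and multivariate analysis of soil P-cycling genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling and multivariate analysis of soil P-cycling genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoilcycle)
```

This vignette is the package's own account of its methods: the models and
procedures, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## The gene catalog

Soil microbial P transformation is profiled through a fixed scheme of 40
genes in three functional categories: P-starvation response regulation
(*phoR*, *phoB*, *phoU* — the pho-regulon two-component system), inorganic-P
solubilization and organic-P mineralization (25 genes: *gcd*, alkaline
phosphatases *phoA*/*phoD*, phytase *appA*, acid phosphatases, the
phosphonate-degradation routes and the 11 C-P lyase subunits *phnF–phnP*),
and P uptake and transport (12 genes: *pit*, *pstSCAB*, *ugpBAEC*,
*phnCDE*). Four multi-subunit systems (*ugp*, *phnCDE*, *pst* transporters
and the C-P lyase complex) are additionally aggregated by **averaging** their
member genes' abundances, never summing, so a long operon does not dominate
a figure panel.

The shipped catalog is a *reconstruction*: the gene count, the three
categories and the four group memberships are fixed by the published scheme,
but the full supplementary roster is not printed anywhere, so 37 entries
come from genes named in the main text and figure captions and 3 accessory
entries (*phoN*, *phnX*, *phnA* — a class-A acid phosphatase and the
phosphonatase/phosphonoacetate hydrolysis routes) pad the roster to 40.
KO assignments are best-effort KEGG lookups; users with the authoritative
supplementary table can drop in their own TSV (`load_catalog(path)`), and
`strict = FALSE` relaxes the 40-gene check for custom schemes. KO IDs are
stored as comma-separated lists because KEGG maps some enzymes to several
orthologs; profiling sums reads over a gene's KOs.

## Profiling

**Denominator.** Relative abundance is `100 × gene reads / total annotated
reads` per sample — the *whole* KEGG-annotated read count, carried as a
`__total_annotated__` row in the KO table dialect, not the P-gene subtotal.
A catalog-restricted table therefore yields profiles summing to well under
100%.

**Median normalization** rescales each sample's counts by
`median(totals) / total_s`. Relative abundances are invariant to it (a
tested property); it is retained because the taxon-shift statistic operates
on depth-equalized *absolute* read numbers, mirroring a figure axis defined
as "+input minus −input normalized reads".

**Shift statistic.** `100 × (mean₊ − mean₋)/mean₋`, pooling replicates
across the four sites within a contrast (the published boxed values are
per-group across sites); per-site shifts are exposed via `by_site = TRUE`.
The statistic is scale-invariant, and undefined (an error) when the −group
mean is zero. As a ratio estimator it carries an O(CV²) positive Jensen
bias; at the default desk-scale depth this is well under a percentage point
for category totals but visible for single low-abundance genes.

## Univariate inference

Two-way ANOVA (`input × site`) uses **Type-II** sums of squares via nested
model comparisons; on the balanced designs this equals the classical
decomposition (tested against a closed-form oracle), and the choice only
matters for user data with unbalanced cells. Assumption checks follow the
conventional pair — Shapiro–Wilk on residuals and Levene across cells — and
*warn* rather than abort, since a profiling pipeline should not die on one
skewed gene. Levene defaults to median centering (the Brown–Forsythe
variant, robust to the skewness typical of abundance data); classical mean
centering is an argument. The Bonferroni family for a gene panel is the
number of features tested (`family_size`), an explicit parameter because no
convention fixes it: callers who test 40 genes in one figure panel should
pass 40, and `panel_anova()` does so by default.

Spearman's ρ is the Pearson correlation of average ranks with the two-sided
t-approximation p-value — adequate for n ≥ ~10 and used identically for the
covariate correlations and the network matrices, so edge q-values are
consistent with the reported pairwise tests. BH-FDR is the standard step-up.

## Ordination

Bray–Curtis is computed from the definition; NMDS delegates the monotone
regression engine to `vegan::monoMDS` (a mature implementation there is no
scientific reason to rewrite) wrapped in a seeded best-of-`n_restarts`
(default 20) loop returning Kruskal stress-1 and centered coordinates.
ANOSIM is implemented from ranks with the conservative tie convention
(permuted R ≥ observed counts as an exceedance) and
`p = (1 + exceedances)/(1 + n_perm)`; with two groups an exact mode
enumerates all label splits. DistLM is the **marginal** test — each
predictor alone — reporting `tr(HGH)/tr(G)` on the Gower-centered squared
distances with a permutation pseudo-F; whether the published explained
fractions were marginal or sequential is not stated, so the package
implements and labels the marginal form only. Defaults: 999 permutations,
seed mandatory.

## RMT network threshold

The co-occurrence threshold is chosen where the eigenvalue spacing
statistics of the hard-thresholded correlation matrix cross from the GOE
(Wigner–Dyson) form, characteristic of a random dense matrix, to the
Poisson form, characteristic of modular structure. The cited methodology
leaves the numerics open; the package's choices, all configurable:

* eigenvalues deduplicated at `1e-8` (thresholded matrices are massively
  degenerate: every isolated feature contributes eigenvalue 1);
* unfolding by a cubic smoothing spline (default 10 effective df) fitted to
  the cumulative spectral staircase; negative spacings from spline wiggle
  are clipped and the spacings rescaled to mean 1;
* goodness of fit by Pearson χ² on equal-probability bins (default 20,
  clamped so each bin expects ≥ 2 spacings) against Poisson `e^(−s)` and the
  GOE surmise `(πs/2)e^(−πs²/4)`;
* scan `s ∈ [0.3, 0.99]` in steps of 0.01; the threshold is the smallest
  `s` with Poisson p > 0.05 **and** GOE p < 0.05; no transition is an error
  (the full-analysis pipeline then falls back to 0.8 with a warning, which
  matters for 12-sample groups whose spectra are too rank-deficient for a
  clean transition).

A caveat established while freezing the acceptance fixture: the detector
tracks the *edge of the noise bulk*, which scales as ~1/√n_samples. With 50
samples the null Spearman bulk dies out by s ≈ 0.3, so the detected
threshold sits there — correctly, but below naive expectations. The
acceptance fixture therefore uses 20 samples (null sd ≈ 0.23), where the
noise bulk extends to ≈ 0.45 and detection lands between the background and
the planted ρ = 0.9 blocks.

Edges require **both** `|ρ| ≥ threshold` and BH `q < 0.01`; order is
immaterial as both are per-edge filters. Signs are kept on edges; topology
uses the unsigned skeleton. One network is built per nutrient group
(−P/+P/−N/+N), pooling sites — whether the original networks pooled sites is
unstated, so the pooling is labelled.

## Path analysis

The default model is observed-variable and recursive: N and P input
indicators (0/1, covarying freely) → soil pH and N:P ratio → the three
category totals. For recursive systems with uncorrelated disturbances the
ML solution coincides with per-equation least squares on standardized data;
the model-implied covariance `Σ = (I−B)⁻¹Ψ(I−B)⁻ᵀ` then gives the
likelihood-ratio `χ² = (n−1)·F_ML` against the saturated model, with
`df = p(p+1)/2 − free parameters` (10 for the default model: 28 moments −
10 paths − 3 exogenous (co)variances − 5 disturbances). Coefficient
p-values are the per-equation t-tests. The field-study sample size (n = 36,
12 per contrast arm) is too small for a stable χ² — the honest acceptance
surface is synthetic-data recovery (sign patterns at n = 36; coefficients
at n = 500), not the published coefficients, and the package documents this
rather than pretending otherwise.

## The synthetic generator

`simulation_config()` defaults *are* the emulated study: 4 sites × 3
treatments × 3 replicates (36 samples); each site contributes one −P/+P and
one −N/+N two-treatment comparison (12 samples per contrast arm); ~35
million annotated reads scaled by 10⁻³ for desk-scale testing; +N lowers pH
by U(0.40, 1.57) units; +P lowers the N:P ratio (×U(0.55, 0.80)) and raises
available P, total P and microbial biomass P within their reported ranges.
Effect multipliers default to the reported category shifts (+N: ×0.885 on
solubilization/mineralization, ×0.9514 on uptake/transport, ×1.161 on
*phoR*; +P: ×1.0209, ×1.0627, ×0.893 on *phoR*). Per-gene baselines are
drawn once (log-uniform 0.002–0.06% of reads, a realistic span for single
functional genes in soil metagenomes); counts are negative-binomial
(dispersion 0.05) around lognormally perturbed (σ = 0.15) expectations.
Covariate→abundance couplings default to zero so injected shifts equal the
multipliers exactly; a positive pH coupling on the alkaline-phosphatase
genes is available (and tested) to reproduce the qualitative pH–*phoD*
correlation.

What the generator does **not** emulate: taxonomic composition underlying
the KO counts, compositional closure effects, site-level gene-by-environment
interactions beyond the pH/N:P couplings, and sequencing artifacts. A green
recovery test therefore establishes that the estimators are correct and
calibrated under the stated model — not that the pipeline would reproduce
the original study's numbers from its reads.

## Degenerate inputs and tie-breaks

Zero-variance features are dropped (with a warning) before correlation;
constant responses yield F = 0/p = 1; a zero −group mean makes the shift
statistic an error rather than an Inf; ANOSIM counts ties as exceedances;
the RMSEA is floored at 0; profiles missing catalog genes get 0 with a
warning, but a missing *system-group member* in `aggregate_systems()` is an
error naming the gene, because a subunit average over a partial group would
silently change meaning.

## Known limitations

* The catalog's three padding entries and some KO assignments cannot be
  verified against the unpublished supplementary roster.
* The RMT detector needs ≥ 20 features and enough samples for a GOE regime
  inside the scan range; small groups fall back to a fixed threshold.
* DistLM is marginal only; no sequential/conditional partitioning, no AICc
  model selection.
* Path analysis is observed-variable only: no latent variables, bootstrap
  errors or modification indices.
* The exact ANOSIM mode covers two groups only.
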