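# psoilcycle

Profiling and multivariate analysis of soil microbial phosphorus-cycling
genes from shotgun-metagenomic KO (KEGG Orthology) read-count tables.

## The scientific problem

Soil microorganisms govern phosphorus (P) availability through three groups
of functional genes: the P-starvation response regulators (*phoR*, *phoB*,
*phoU*), genes for inorganic-P solubilization and organic-P mineralization
(PQQ glucose dehydrogenase *gcd*, alkaline phosphatases *phoA*/*phoD*,
phytase *appA*, the C-P lyase *phn* operon, ...), and P uptake and transport
systems (the high-affinity *pstSCAB* and low-affinity *pit* transporters,
the *ugp* and *phnCDE* ABC transporters). Long-term nitrogen and phosphorus
fertilization shifts the relative abundance of these genes — N input mainly
through soil acidification, P input mainly through N:P stoichiometry — and
quantifying those shifts requires a chain of analyses that this package
implements as tested, reusable components:

* a curated **40-gene catalog** (3 functional categories, 4 multi-subunit
  system groups) mapping gene symbols to KO IDs;
* **profiling**: median depth normalization, relative abundance as a percent
  of annotated reads, subunit averaging, category totals, and the treatment
  shift statistic `100 · (mean₊ − mean₋) / mean₋`;
* **inference**: Type-II two-way ANOVA (input × site) with Shapiro–Wilk /
  Levene checks and Bonferroni adjustment; Spearman correlations; BH-FDR;
* **ordination**: Bray–Curtis dissimilarity `Σ|x−y| / Σ(x+y)`, NMDS
  (Kruskal stress-1, seeded restarts), ANOSIM with permutation or exact
  inference, and marginal DistLM (`tr(HGH)/tr(G)` on the Gower-centered
  distance matrix, pseudo-F by permutation);
* **co-occurrence networks**: pairwise Spearman matrices, an edge filter of
  BH-adjusted `q < 0.01` **and** `|ρ| ≥` a threshold chosen by random matrix
  theory (the GOE→Poisson transition of the unfolded eigenvalue
  nearest-neighbour spacing distribution), plus topology reports (average
  degree `2E/N`, density `2E/N(N−1)`, mean local clustering);
* **path analysis**: a recursive observed-variable model
  (N, P inputs → pH, N:P → the three category totals) fitted by maximum
  likelihood, with χ², RMSEA `√(max(0, χ²−df)/(df(n−1)))`, standardized
  coefficients and per-equation r²;
* a **synthetic-study generator** emulating the 4-site × 3-treatment ×
  3-replicate field design with known injected effects, so every stage is
  testable without sequencing data.

## Worked example

```r
library(psoilcycle)

catalog <- load_catalog()                                  # 40 genes
study   <- simulate_study(simulation_config(seed = 7))     # 36 samples
profile <- relative_abundance(median_normalize(study$ko_table), catalog)
cats    <- category_totals(profile, catalog)
round(shift_statistic(cats, study$metadata, "N"), 2)
#>         starvation_regulation solubilization_mineralization
#>                         25.82                         -8.64
#>              uptake_transport
#>                         -0.51
```

The generator injects a ×0.885 multiplier on the solubilization/
mineralization category under +N (a −11.5% shift in expectation): at one
seed with 3 replicates the estimate is −8.6%; averaged over seeds it
converges to the injected value (this is asserted in the acceptance suite).
The regulation category is dominated by *phoR* (injected +16.1%), whose
small baseline makes single-seed estimates noisy.

```r
d  <- bray_curtis(profile)
keep <- study$metadata$sample_id[!is.na(study$metadata$n_contrast)]
an <- anosim(d[keep, keep],
             study$metadata$n_contrast[match(keep, study$metadata$sample_id)],
             n_perm = 999, seed = 7)
sprintf("ANOSIM R = %.3f, p = %.3f", an$R, an$p)
#> [1] "ANOSIM R = -0.004, p = 0.514"

distlm_marginal(d, study$metadata[match(rownames(d), study$metadata$sample_id),
                                  c("pH", "np_ratio")], n_perm = 999, seed = 7)
#>   predictor proportion pseudo_F     p p_bonferroni
#> 1        pH     0.0276    0.964 0.514            1
#> 2  np_ratio     0.0258    0.901 0.600            1
```

(With the default generator the community-level signal is weak by design —
category shifts of ~10% on a 40-gene profile barely move Bray–Curtis — so R
and the explained fractions sit near their null values.)

```r
x   <- simulate_planted_network(60, c(15, 15), n_samples = 20, seed = 7)
cm  <- correlation_matrix(x)
thr <- rmt_threshold(cm$rho)$threshold        # 0.45 for this seed
net <- build_network(cm, thr, alpha = 0.01)
topology(net)[c("average_degree", "graph_density",
                "average_clustering_coefficient")]
#> avg degree 7.10, density 0.120, clustering 0.498
```

A full run (profile TSVs, ANOVA tables, ordination JSON, four GraphML
networks, path-model fit, provenance manifest):

```r
run_full_analysis(run_config(ko_table = "ko.tsv", metadata = "meta.tsv",
                             outdir = "out", seed = 1))
```

or from the shell via the installed script:

```sh
inst/scripts/psoilcycle run-all --ko-table ko.tsv --meta meta.tsv \
    --out out --seed 1
```

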