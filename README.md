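# momnet

Multi-omic differential analysis and partial-correlation networks for
two-group cohort studies.

## The problem

Cohort studies that profile the same samples on several omics layers —
here, untargeted urine metabolomics plus targeted proteomics from ARDS
patients of two etiologies (COVID-19, n = 42, vs bacterial sepsis, n = 17)
— need a reproducible path from raw abundance tables to (i) molecules that
differ between the groups, (ii) a data-driven cross-omics interaction
network, and (iii) within-group associations with clinical manifestations
(AKI, platelet count, PaO2/FiO2, mortality). `momnet` packages that path,
and pairs it with a synthetic cohort generator with planted ground truth so
that every stage is testable without any external data.

## Methods at the core

* **Preprocessing**: features with > 25% missing values removed (strict
  inequality); probabilistic quotient normalization (per-sample median
  quotient against the median reference spectrum) to correct dilution;
  log2; k-nearest-neighbor imputation in feature space (k = 10); averaging
  of duplicated assay copies.
* **Differential analysis**: per molecule, OLS of abundance on the outcome
  (no covariates). For a 0/1 outcome this is the pooled-variance t-test and
  the coefficient is the log2 fold change. Benjamini–Hochberg correction
  per analysis across both omics layers; signed score
  `p_score = −log10(p_adj) · d`, `d = sign(t)`.
* **Pathway filtering**: keep "metabolism" sub-pathways and non-disease
  KEGG pathways with ≥ 3 significant molecules.
* **GGM network**: shrinkage correlation `R* = (1−λ*) R + λ* I` with the
  analytic `λ* = Σ Var̂(r_ij) / Σ r_ij²`; partial correlations
  `−Ω_ij/√(Ω_ii Ω_jj)` from `Ω = (R*)⁻¹`; edge p-values from the null
  `f0(r; κ) ∝ (1−r²)^((κ−3)/2)` with κ fitted by a null + uniform mixture
  likelihood; edges at 5% FDR (BH default, tail-area empirical FDR
  optional).
* **Subnetworks**: BFS ball of radius 2 around seed molecules, then the
  induced subgraph.

## Worked example

```r
library(momnet)

co <- generate_cohort(synthetic_spec(seed = 42, effect_size_log2 = 3,
                                     duplicate_protein_pairs = 3,
                                     n_overfiltered_features = 5))
co$matrix
#> <omics_matrix> 208 features x 59 samples [raw]
#>    metabolite: 155, protein: 53
#>    missing: 745 (6.1%)

pp <- preprocess_pipeline(co$matrix, duplicate_groups = co$truth$duplicate_groups)
pp$matrix
#> <omics_matrix> 200 features x 59 samples [imputed]
#>    metabolite: 150, protein: 50
#>    missing: 0 (0.0%)

res <- fit_association(pp$matrix, co$samples, "group")
sum(res$p_adj < 0.05)
#> [1] 19
head(res[order(res$p_adj), c("molecule_id", "estimate", "t_statistic", "p_adj", "p_score")], 3)
#>    molecule_id estimate t_statistic    p_adj p_score
#> 86     met_086    -3.38       -12.4 1.35e-15   -14.9
#> 12     met_012    -2.49       -11.8 6.88e-15   -14.2
#> 36     met_036    -3.35       -11.6 9.16e-15   -14.0

hits <- res$molecule_id[res$p_adj < 0.05]
truth <- names(co$truth$differential_features)
mean(truth %in% hits)   # sensitivity on the 20 planted features
#> [1] 0.95
sum(!hits %in% truth)   # false discoveries
#> [1] 0

net <- infer_network(pp$matrix, results = res)
net
#> <ggm_network> 200 nodes, 21 edges (FDR < 0.05, bh)
```

Reading the numbers: the generator planted ±3 log2-unit shifts on 20 of
200 features (shifts are applied to the bacterial group, so a feature
raised there shows a negative covid-vs-bacterial fold change, e.g.
`met_086`'s −3.38). The differential stage recovers 19/20 of them with no
false positives at 5% FDR; the network stage finds 21 conditional
dependencies at n = 59, where shrinkage is heavy and only the strongest
planted edges clear the FDR cut.

The full pipeline (simulate → preprocess → associate → pathways → network
→ subnetwork → signature) runs from one config:

```r
run_pipeline(list(synthetic = list(seed = 42), out_dir = "out"))
```

or from the command line:

```sh
Rscript -e 'momnet::momnet_cli()' run-all --config config.json
Rscript -e 'momnet::momnet_cli()' simulate --out sim --seed 7 --effect-size-log2 3
```

Every run writes a `manifest.json` with the config, its hash, and
per-stage counts; reruns from the same config are byte-identical.

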