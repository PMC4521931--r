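# silacdiff

Quantitative analysis of **three-plex SILAC** proteomics experiments:
light/medium/heavy (K0R0 / K4R6 / K8R10) metabolic labelling of three cell
states, peptide-evidence quantification, and z-score based calling of
differentially regulated proteins. The package grew out of the analysis
design used to compare normal bladder epithelium with non-muscle-invasive
and metastatic bladder cancer cell lines, and is aimed at proteomics
analysts who have identified peptide evidence (e.g. a MaxQuant-style
export) and want a transparent, reproducible quantification-and-calling
pipeline with built-in validation data.

## What it computes

For each protein the per-replicate M/L and H/L intensity ratios are the
medians of its peptide intensity ratios; proteins quantified in at least
two replicates are averaged. Ratios are moved to log2 space and each
population (channel x replicate) is standardized with its own mean and
standard deviation:

    z = (log2 r − μ) / σ

Replicate z-scores are averaged, and proteins are assigned two-sided
confidence tiers |z| ≥ 1.960 / 2.576 / 3.291 (95 / 99 / 99.9%), a
direction (up/down), and a direction-free fold change max(r, 1/r).
Around this core the package provides:

- isotope-label mass arithmetic (K4 = 4.025107, K8 = 8.014199,
  R6 = 6.020129, R10 = 10.008269 Da), expected m/z spacings, triplet
  detection in centroided peak lists, label-incorporation efficiency and
  Arg→Pro conversion checks;
- hierarchical clustering of the regulated-protein z-score matrix with
  heat-map, TSV and Newick export;
- annotation-term over-representation with the one-tailed Fisher exact
  test and the jackknifed **EASE score** (pass filters: count ≥ 2,
  EASE < 0.1);
- the qPCR 2^−ΔΔCt fold-change helper;
- a synthetic-data generator (peptide evidence, peak lists, annotation
  tables) with ground-truth manifests, so every stage is testable without
  raw data;
- packaged transcriptions of the source study's summary tables
  (`silac_fixture("table1" | "table2" | "table3")`) for end-to-end
  validation.

## Worked example

```r
library(silacdiff)

cfg <- sim_config(n_proteins = 500, seed = 7)   # synthetic 3-plex study
sim <- simulate_evidence(cfg)
res <- silac_differential(sim$evidence)
res
#> <silac_result>
#>   evidence rows: 5088 (kept after length filter: 5088)
#>   proteins seen: 500; quantified in >= 2 replicate(s): 500 (100.0%)
#>   normalization: per-replicate
#>   regulated at 95%, M/L: 12 up, 12 down
#>   regulated at 95%, H/L: 12 up, 8 down
#>   regulated at 95%, both: 2 up, 3 down
```

12+12 M/L calls out of 500 proteins is the expected yield for the
generator's 6% regulated fraction split across channel patterns. The
record table is a tibble (`tidy(res)`), one row per protein:

```r
tidy(res)[1:3, c("protein", "ml_average", "log2_ml", "z_ml", "tier_ml", "direction_ml")]
#>   protein ml_average log2_ml   z_ml tier_ml direction_ml
#> 1 P00001      25.5     4.67   3.95  99.9    up
#> 2 P00002       0.328  -1.61  -1.37  none    none
#> 3 P00003       0.775  -0.367 -0.374 none    none
```

P00001's M/L average of 25.5 (log2 = 4.67) sits 3.95 population SDs above
the mean — significant beyond the 99.9% tier. Against the packaged
reference tables, the published M/L population parameters
(mean −0.072, SD 1.237) reproduce the printed z-scores, e.g. thymidine
phosphorylase at M/L 39.51:

```r
p <- fixture_norm_params("M/L")
round(zscore(log2_ratio(39.51), p), 2)
#> [1] 4.35
```

`autoplot(res)` draws the two-channel z-score scatter with tier
thresholds; `cluster_zmatrix(zscore_matrix(res))` + `render_heatmap()`
produce the clustered heat map; `enrich()` runs Fisher/EASE
over-representation of the regulated list.

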