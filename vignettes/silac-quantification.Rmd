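---
title: "Three-plex SILAC quantification and z-score differential calling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-plex SILAC quantification and z-score differential calling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacdiff)
```

## The experimental design this package models

In a three-plex SILAC experiment three cell states are cultured in media
carrying different stable-isotope forms of lysine and arginine — K0R0
("light"), K4R6 ("medium"), K8R10 ("heavy") — so that, after mixing the
lysates 1:1:1 and digesting with trypsin, every tryptic peptide appears as
up to three co-eluting isotopic forms. The intensity ratios medium/light
(M/L) and heavy/light (H/L) report the relative abundance of the parent
protein in the two labelled states against the light reference.

The package takes identified peptide evidence (sequence, protein
accession, charge, three channel intensities, replicate id) as its input
and owns everything downstream: label-mass bookkeeping and quality
checks, ratio aggregation, the z-score significance model, clustering and
annotation enrichment. Database search, FDR control and protein-group
inference are upstream concerns and deliberately out of scope — each
evidence row carries a single accession.

## Label-mass arithmetic and spectrum checks

Label mass shifts are fixed monoisotopic constants derived from the
standard isotope mass differences (13C−12C = 1.0033548,
15N−14N = 0.9970349, 2H−1H = 1.0062767 Da): K4 = 4.025107,
K8 = 8.014199, R6 = 6.020129, R10 = 10.008269 Da per labelled residue.
The m/z convention is (neutral monoisotopic mass + charge × 1.0072765) /
charge with water at 18.0105646 Da. All constants live in one scheme
table (`silac_scheme()`) and can be overridden.

`detect_triplets()` scans a centroided peak list for peaks spaced by the
expected M−L and H−L shifts at the peptide's charge. Both spacings must
match within a ppm tolerance (default **10 ppm**, a typical Orbitrap
calibration figure; the original processing tolerance is not recoverable,
so this default is declared, not inferred). Overlapping candidates are
resolved greedily by smallest combined ppm error, each peak used at most
once — a deterministic rule that needs no intensity model.

Two quality checks mirror standard SILAC practice. Incorporation
efficiency is labeled/(light + labeled); incomplete metabolic labelling
(< 98%) leaves residual light signal that would bias ratios of
low-abundance proteins. Arg→Pro conversion transfers label into proline
(13C5 for the medium channel, 13C5 15N1 for the heavy one, i.e.
5.016774 / 6.013809 Da per proline) and is detected as satellite peaks at
+k·Δpro/charge above a channel peak; the conversion flag trips when a
satellite exceeds **5%** of the main-peak intensity. The source analysis
reports only the qualitative absence of conversion, so 5% is our own
threshold: well above centroiding noise, well below a ratio-distorting
contribution.

## From peptide evidence to protein ratios

1. **Length filter.** Peptides shorter than 6 residues are removed —
   the conventional identification floor.
2. **Peptide ratios.** M/L = intensity_m / intensity_l when both are
   present and light > 0; otherwise missing. Missingness propagates,
   never errors.
3. **Protein per replicate.** The protein ratio is the **median** of its
   defined peptide ratios, per channel. The median is robust to the
   single-outlier peptide (mis-assigned or interference-affected) at the
   typical 3–8 peptides per protein; the mean is available via
   `method = "mean"`. A channel ratio requires at least `min_ratio_count`
   (default 1) defined peptide ratios.
4. **Replicate merge.** A channel is reported only for proteins whose
   ratio is defined in at least `required_replicates` (default 2)
   replicates; the reported average is the arithmetic mean of the
   per-replicate ratios. Averaging on the ratio scale matches the
   convention of reporting "M/L average" columns whose log2 is printed
   alongside; geometric (log-scale) averaging is available via
   `average = "log2"`.

## The z-score significance model

Ratios are standardized in log2 space:

$$z_b = \frac{\log_2 r_b - \hat\mu}{\hat\sigma}$$

where $\hat\mu,\hat\sigma$ are the arithmetic mean and the n−1 sample SD
of the log2-ratio population. The model treats the bulk of the proteome
as unregulated, so the population itself estimates the null; no
peptide-count weighting or variance moderation is applied, and no
multiple-testing correction — significance is expressed as two-sided
confidence tiers |z| ≥ 1.960, 2.576, 3.291 (95, 99, 99.9%), the standard
normal critical values. Tier comparison is inclusive, so a printed
z of −1.96 counts at the 95% tier.

**Normalization scope.** The default (`mode = "per-replicate"`) fits
$\hat\mu,\hat\sigma$ separately for each channel in each replicate —
each data set standardized against itself — computes per-replicate
z-scores, and averages them across replicates. This is the faithful
reading of per-data-set normalization and is what the clustering input
uses. A second mode (`mode = "paper-compat"`) standardizes both channels'
merged averages with one shared parameter set: the packaged reference
tables are numerically consistent with exactly this convention (their
printed H/L z-scores back-compute from the M/L population parameters,
mean −0.072, SD 1.237, not from the printed H/L row). The package does
not guess which convention the original authors intended; both are
provided, and the fixture-validation tests use paper-compat with the M/L
parameters.

Records missing a channel get tier "none" for that channel rather than
an error. Fold change is reported as max(r, 1/r), a direction-free
magnitude. The qPCR helper implements
$2^{-\Delta\Delta C_t}$ with
$\Delta\Delta C_t = (C_t^{target,treated} - C_t^{ref,treated}) -
(C_t^{target,control} - C_t^{ref,control})$.

## Clustering

The regulated-protein z-score matrix (rows = proteins significant at the
base tier, columns = channel × replicate) is clustered agglomeratively.
Defaults are **Euclidean distance, average linkage** — the original
figure names neither, so these are declared package defaults, chosen for
being monotone (no inversions) and scale-appropriate for z-scores
already in sigma units. Missing z-values are imputed to 0 σ (the
population mean) for the distance computation only; the stored and
rendered matrix keeps them missing, drawn in a distinct colour. Leaf
order is deterministic given input order; distance ties resolve by
original index. Exports: ggplot2 heat map with a symmetric diverging
scale centred at 0 σ, the reordered matrix as TSV (numbers written with
`%.17g` so the text file round-trips bit-exactly), and Newick trees via
`ape`.

## Enrichment

Over-representation of a regulated list against a background uses the
one-tailed Fisher exact test, $P(X \ge k)$ under the hypergeometric law,
and the **EASE score** — the same tail with the overlap jackknifed by
one, $P(X \ge k-1)$ — which penalizes terms supported by a single
protein. A term passes with overlap count ≥ 2 and EASE < 0.1, the
conventional DAVID/EASE filters. The background is whatever protein
universe the caller supplies (typically the quantified, annotated set);
annotations are a flat accession→term table — no ontology traversal, so
parent terms do not inherit child members. A Benjamini–Hochberg adjusted
EASE column is emitted for convenience, but `passes` uses the raw score,
matching the original filters. Depletion is out of scope.

## The synthetic experiment

`simulate_evidence()` generates the data structure the pipeline assumes,
with known truth. Per protein, true log2 M/L and H/L ratios come from a
Normal(−0.07, 0.8) background; a regulated fraction (default 6%)
receives signed effects of magnitude uniform in 2.3–5.3 log2 units,
applied to M/L only, H/L only, or both channels in the same or opposite
direction — emulating state-specific and shared regulation. Each protein
carries 1 + Poisson(4) peptides; per peptide and replicate, a log-normal
base intensity (median 1e6, geometric SD 4) forms the light channel, and
the labelled channels multiply in 2^(true log2 + replicate shift +
noise) with peptide noise SD 0.3 and protein-level replicate shift
SD 0.05 (log2 units). Channel intensities drop independently at 5%
missingness. These defaults were chosen once to mirror a realistic
two-replicate cell-line experiment of ~2000 quantifiable proteins with a
mixed regulated/background population whose pooled log2 SD lands near
1.2 — the scale the reference tables show.

Under these conditions the pipeline's operating characteristics are
testable: with no regulated proteins, ~5% of proteins exceed the 95%
tier by construction of the z-score; with the default effects, the 95%
tier recovers regulated proteins with sensitivity ≥ 0.9 at specificity
≥ 0.95 (the weakest effects, 2.3 log2 units, sit near the effective
threshold of ≈ 1.96 × pooled SD, so sensitivity is not trivially 1).
With noise, shift and missingness all zero, recovered log2 ratios equal
the truth to floating-point precision — the pipeline adds no bias.

`simulate_peaklist()` plants channel peaks at exact label spacings with
configurable incorporation (residual light = 1 − incorporation),
conversion satellites and uniform noise peaks. `simulate_annotations()`
assigns proteins to terms uniformly, with planted terms oversampling
regulated proteins at weight 1 + strength. Its defaults — 10 terms of
3–10 members over a 2000-protein background — are calibrated so that
with strength 0 the count ≥ 2 & EASE < 0.1 filter passes no term in at
least 93% of seeds: the hypergeometric tail is discrete, so the per-term
null pass probability has a floor of a few per mille regardless of
sizes, and small, few terms keep the experiment-wise null rate inside
that bound. One user seed feeds per-stage derived sub-seeds, so the
evidence, peak-list and annotation generators can be re-run
independently and reproduce byte-identically.

**What the generator does not emulate:** intensity-dependent (MNAR)
missingness, correlated peptide noise within a protein, isotope-envelope
fine structure, chromatographic effects, shared/razor peptides, and
decoy-based identification error. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under the
stated model, not robustness to every pathology of real LC-MS data.

## Numerical and degenerate-input choices

- Sample SD uses the n−1 denominator; fewer than 2 values is an error,
  a constant population (SD 0) is flagged and z-scores refuse to
  compute.
- `fold_change` and `log2_ratio` reject non-positive ratios; missing
  values pass through untouched.
- Empty peak lists yield empty triplet results, not errors; a peptide
  without prolines is vacuously conversion-clean.
- Evidence rows with non-numeric intensities are skipped with a warning
  naming the line numbers (or abort on request); missing values are
  empty strings in the canonical TSV dialect.
- Writers emit UTF-8, LF, fixed column order, so outputs are hashable;
  `write_records(digits = 2)` gives table-compatible 2-decimal output.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at sizes chosen to
make sampling noise negligible relative to the tested tolerances: the
null false-positive rate on 10,000 proteins (binomial SE ≈ 0.002 against
a ±0.01 band), sensitivity/specificity on the default 2,000-protein
configuration, Fisher/EASE against a brute-force log-binomial summation
oracle on 1,000 random margins at 1e-12, normality screens at n = 2,000
over 20 seeds, and the strength-zero enrichment null over 30 seeds with
a one-sided binomial criterion at the stated 93% rate.

## Known limitations

- Protein inference is not performed; evidence rows carrying protein
  groups must be resolved upstream.
- The z-score model ignores peptide support: a one-peptide protein and a
  thirty-peptide protein get equal variance. Moderated-variance models
  (as in limma-style pipelines) are intentionally out of scope.
- The per-replicate and paper-compat normalization modes can disagree
  near tier boundaries; results should state which mode produced them.
- EASE/Fisher results depend strongly on the chosen background; the
  package computes against the supplied universe and makes no attempt
  to reconstruct any external database's background population.
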