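---
title: "Quantitative microbiome profiling of the honeybee gut: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative microbiome profiling of the honeybee gut: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeQMP)
```

## The problem

The adult honeybee gut hosts fewer than a dozen bacterial phylotypes, yet
total bacterial load varies by an order of magnitude between worker-bee
types (foragers, nurses, long-lived winter bees). Relative amplicon
profiles alone cannot distinguish "taxon A increased" from "everything
else decreased", so this package quantifies absolute abundances two ways
and lets them cross-validate each other:

1. **Targeted qPCR** for each phylotype, normalized to a host
   single-copy gene (actin), reported as genome equivalents (GE) per gut.
2. **QMP**: 16S amplicon proportions scaled by a universal 16S qPCR load,
   divided by each taxon's 16S operon number.

## The qPCR quantification chain

For each assay a standard curve on a plasmid dilution series gives
`Cq = intercept + slope * log10(copies/ul)` with efficiency
`E = 10^(-1/slope)`. The chain for a sample is:

```
n_raw = E^(intercept - Cq)                       copies/ul
n_abs = (n_raw / n_actin) * median(n_actin) * 200  copies/gut
n_GE  = n_abs / rrna_loci                        genomes/gut
```

**LOD semantics.** The Cq at `lod_copies` (10 or 100 copies/ul depending on
how far down the assay's dilution series stays linear) is the limit of
detection. A detected Cq beyond it, or no amplification at all, is recorded
as below LOD with all derived quantities exactly zero; zeros never enter
downstream sums, means or diversity values except as true zeros. For log
display and log-scale statistics zeros are replaced by 1 (`log_transform()`),
so a non-detection sits at 0 on the log10 axis.

**Conventions fixed here because the order of operations matters for
reproducibility:**

* Technical replicates are averaged on the Cq scale before inversion
  (conventional qPCR practice; averaging copy numbers instead would weight
  replicates geometrically differently). All-undetected replicate sets stay
  undetected; partial sets average the detected replicates.
* `median(n_actin)` is computed over the batch of samples processed
  together, overridable by `median_actin =` for cross-batch work.
* In input files an undetected reaction is an empty field or `NA`.
* The universal all-bacteria assay is reported as `n_abs`, never as GE:
  no single operon number applies across taxa.
* A sample whose actin assay fails cannot be normalized and is excluded
  with a warning, mirroring standard practice.
* Abundances are kept as reals throughout; nothing is rounded to counts.

## The amplicon-to-QMP chain

`qmp_pipeline()` applies, in a fixed order: off-target removal
(mitochondria, chloroplast, eukaryote reads), the abundance filter,
phylotype collapsing, per-sample proportions, then scaling by
`total_16s / loci`. The order is part of the method — filtering operates on
sequence variants before collapsing, and proportions are renormalized over
the retained community — and the test suite asserts that reordering changes
the result.

The filter keeps taxa *present in at least two samples AND with at least
ten reads in total*. The alternative reading (ten reads in each of two
samples) was considered and rejected: the conjunction of one prevalence
predicate and one total-count predicate is how such filters are
conventionally composed (e.g. `genefilter`-style filter functions), and the
boundary case (5 reads in each of 2 samples) is retained under it.

Per-phylotype 16S operon numbers are configuration (`default_loci()` ships
rrnDB-style placeholder values); they rescale GE per taxon and must be set
from genome data for real assays.

## Diversity and inference

* **Alpha diversity** is the effective number of species `exp(H)`. `H` uses
  the natural log (required so the exponent is a Hill number); abundance
  plots use log10. These are two deliberately distinct conventions.
* **Bray–Curtis** dissimilarities (via `vegan::vegdist`) feed a one-way
  **PERMANOVA** implemented from squared dissimilarities
  (`SS_total = sum d^2 / n`, within-group analogues, pseudo-F). On
  univariate Euclidean input it reproduces the classical ANOVA F to
  1e-9, which the tests assert against `anova(lm(...))` and
  `vegan::adonis2`. Labels are permuted freely (one-way design, no strata)
  since bee type is the only factor tested.
* **Dispersion** embeds the dissimilarity matrix by principal coordinates,
  splitting positive and negative eigenvalues and subtracting squared
  distances in the imaginary axes (Anderson's convention; distances match
  `vegan::betadisper(type = "centroid")`), then tests the group means of
  the centroid distances by a permutation F.
* **Permutation ANOVA / t-tests** randomize the response `B` times
  (default 10,000) and report `p = max(exceed, 1)/B`. The raw proportion
  of exceedances can be zero, which is not a valid p-value; the floor
  makes the smallest reportable value `1/B` (1e-4 at the default B), which
  is also the natural resolution of the procedure. PERMANOVA and the
  dispersion test instead count the observed configuration among the
  permutations (`p = (exceed + 1)/(B + 1)`), the convention usual for
  those tests; both conventions are documented on their functions.
  Two-group permutation tests are two-sided via |Welch t| — direction is
  reported separately by the estimates. Permutations are sampled with
  replacement from the permutation group (plain Monte Carlo).
* **Tukey HSD** is classical (studentized range, Tukey–Kramer when
  unbalanced) even though the omnibus test is permutation-based — the
  hybrid is standard practice; a fully permutation-based pairwise
  alternative with Bonferroni adjustment (`pairwise_perm_test()`) is also
  provided.
* **PCA** is centered and unscaled by default (`scale. =` switches);
  absolute abundances on a log scale already share units, so unit-variance
  scaling is an option, not the default. Signs are fixed by making the
  dominant entry of each loading vector positive. Constant columns are
  dropped with a warning rather than producing zero-variance axes.

## What the generator emulates

`gen_hive()` draws, per bee and taxon, Bernoulli colonization
(detectability) and a lognormal load when colonized. Defaults encode the
anchors the package is tested against:

* Firm-4 detectability 0.984; Frischella below-LOD fraction 0.269;
  Bartonella 0.053 (identical across bee types — abundance differences are
  carried by the means, keeping mixed-population prevalence estimates
  interpretable).
* Winter log10-mean shifts over foragers of 0 (Gilliamella), +0.3
  (Snodgrassella), +1.3 (Bifidobacterium), +1.4 (Firm-4), +1.0 (Firm-5),
  −1.0 (Frischella) and +1.71 (Bartonella). The Bartonella shift was
  solved (uniroot on the analytic lognormal means) so the expected
  winter:forager total-load ratio is 10; the winter community is then
  dominated by Firm-5 and Bartonella and loses minor taxa (Apibacter
  detectability drops to 0.36, *L. kunkeii* to 0), while nurses sit in
  between (ratio ≈ 5.9, intermediate Bartonella).
* The absolute scale (forager total ≈ 10^7.8 GE/gut) and all within-type
  sds are plausible placeholders — only ratios and prevalences are
  anchored. Gut weights: foragers 35 ± 8 mg, nurses and winter bees
  70 ± 15 mg.

`gen_cq()` is the exact analytic inverse of the quantification chain
(template concentration `GE * loci * (actin_i / median(actin)) / 200`,
plus Gaussian Cq noise), using the empirical median of the batch's actin
draws so that at `sigma_cq = 0` the chain round-trips to 1e-6 relative.
Out-of-range concentrations are emitted at face value — the LOD rule is the
pipeline's job, so the LOD path is genuinely exercised.

`gen_amplicon()` draws multinomial reads with weights `GE * loci`
(copy-number bias included), default depth 27,000 reads/sample (the order
of magnitude of a well-filtered MiSeq run), optional pooling as the
arithmetic mean of per-gut GE over a hive × bee-type group (equal-mass
pooling assumed), an ASV split per core phylotype so collapsing is
exercised, and ~2% off-target (host mitochondria + pollen chloroplast)
reads so exclusion is exercised. `total_16s` is exact, so QMP recovery
error is pure multinomial noise.

`gen_colonization()` encodes the diet experiment: in the sugar-water-only
arm Bartonella colonizes 75% and Frischella 45% of bees, loads and gut
weights are roughly half of the pollen-fed arm, and gut weight is
rank-correlated with total load through a Gaussian-copula latent pair
(`r = 2 sin(pi * rho / 6)` plus a shared per-bee load shift). The achieved
Spearman rho is approximate (the taxon-level noise dilutes it); only
`rho = 0` is exact. All generators are pure functions of (config, seed).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: temporal autocorrelation across months,
inter-assay plate effects, chimeras and contamination, sequencing error at
the read level (counts are drawn at the taxon level, not denoised from
reads), compositional taxon–taxon interactions, and live/dead DNA
differences. Recovery results certify the arithmetic of the pipeline, not
the biology of any particular hive.

## Numerical choices and degenerate inputs

* Curve fitting requires ≥3 distinct dilution levels inside the included
  range (10^2–10^7 for the five assays with a 100-copy LOD, 10^1–10^7
  otherwise) and rejects nonnegative slopes and efficiencies outside
  (1, 2.5].
* Welch's t with two zero-variance groups is defined as 0 (equal means) or
  signed infinity; an infinite observed statistic simply dominates every
  permutation. A fully constant response yields p = 1 with a warning.
* `write_tsv_precise()` writes doubles at 17 significant digits so
  write-then-read round-trips exactly; display rounding happens only in
  print methods.
* Below-LOD zeros are exact zeros, never small constants, except under the
  explicit zero→1 log rule.

## Problem sizes used by the test suite

The suite runs the anchors at n = 100–1000 simulated bees, the QMP
round-trip at depth 50,000, and the type-I calibration of the permutation
ANOVA and PERMANOVA at 1000 null simulations with B = 499 (sizes chosen to
put 3-sigma binomial bands well inside the tolerances being asserted while
keeping a full run in the low minutes on one core). Exhaustive-enumeration
oracles use n = 6; closed-form oracles (OLS, ANOVA, eigendecomposition,
ranks) are recomputed inside the tests rather than frozen from earlier
runs.

## Known limitations

* One-way designs only; no strata/blocking in the permutation engines and
  no mixed models.
* No inter-plate calibration of qPCR runs; batches are assumed comparable
  after actin normalization.
* Phylotype operon numbers are single point values; intra-phylotype operon
  variation propagates directly into GE.
* The dispersion test permutes the centroid distances themselves (not
  model residuals), adequate for one-way balanced-ish designs.
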