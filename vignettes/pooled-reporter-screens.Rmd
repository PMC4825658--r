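---
title: "Methods: pooled FACS reporter screens read out by Bar-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled FACS reporter screens read out by Bar-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experiment this package models

A genome-wide collection of barcoded knockout strains carries a
pathway-responsive fluorescent reporter (for example a MAPK-inducible
promoter driving GFP). The pool is grown with and without inducer and
sorted by FACS into five pools defined against three control strains run
alongside every sort: a reporter-negative control, the uninduced
reporter strain (basal control), and the induced reporter strain.
The pools are:

* `Un_Gfp_neg`, `Un_Gfp_plus` — uninduced cells below the basal peak or
  above it;
* `In_Gfp_neg`, `In_Gfp_basal`, `In_Gfp_plusplus` — induced cells below
  the basal peak, at the basal peak (non-inducing), or above the induced
  peak (hyper-inducing).

Each sorted pool is regrown, its genomic DNA is extracted, and the two
strain barcodes flanking every knockout cassette (UPTAG and DNTAG,
20 nt each) are PCR-amplified with universal primers carrying a
sample-identifying multiplex tag, then sequenced single-end. Counting
reads per barcode per pool and testing each pool against the *presorted*
library identifies mutants whose reporter behaviour is abnormal:
pathway-null (reporter-negative under both conditions), non-inducing
(receptor-dead), elevated basal expression, hyper-induction, and so on.

# Barcode counting

Reads are laid out as multiplex tag + upstream universal priming site +
barcode + downstream priming site. The classic analysis route locates
barcodes by aligning reads to an artificial reference in which all
barcodes are concatenated with 20-bp runs of ambiguous `N` bases; that
reference exists only to coerce a read aligner into barcode lookup.
This package instead anchors on the priming site directly (within a
small window, allowing up to 2 substitutions) and matches the following
20 bases against the catalog by Hamming distance (default radius 2). For
substitution-type errors the two routes are equivalent, and the direct
route is testable against an exhaustive brute-force oracle — the test
suite checks agreement on every query over hundreds of random catalogs.
`build_concatenated_reference()` and `write_reference_fasta()` are kept
so the aligner route can still be cross-validated externally.

Matching rules worth stating:

* A read is assigned only when exactly one gene attains the minimal
  acceptable distance. Ties (including verbatim barcode collisions
  between genes) are counted in an `ambiguous` ledger and never
  fractionally assigned.
* When a primary and a resequenced catalog disagree about a gene's
  barcode, the resequenced entry wins, but the superseded sequence is
  retained as an *alias* so reads carrying the older barcode still count
  toward the same gene.
* Every sample's ledger (`assigned`, `ambiguous`, `unmatched`,
  `no_tag`) partitions its reads exactly; this is asserted on every run.

The minimum-read filter admits a gene when its UPTAG **or** its DNTAG
count in the presorted control library reaches 50 reads. The
disjunctive reading is deliberate (and tested at the 49/50 boundary):
many knockout strains have one failed tag, and requiring both would
discard them.

UPTAG and DNTAG counts for one biological sample are carried into the
test as two separate technical columns rather than summed; summing
would hide tag-specific PCR failure.

# The enrichment test

The test re-implements the classic exact-test lineage for count data
(no GLM, shrinkage, or outlier machinery):

* **Size factors** by median-of-ratios:
  $s_j = \mathrm{median}_g\, k_{gj} / (\prod_j k_{gj})^{1/m}$ over genes
  with positive geometric mean. When no gene is positive everywhere — a
  real possibility in a tightly sorted pool — a documented fallback uses
  positive counts only, over genes present in at least half the samples.
* **Dispersions** per gene by method of moments on common-scale counts,
  $\hat\alpha = \max(0, (s^2-\bar\mu)/\bar\mu^2)$, pooled across
  replicate groups, with a parametric trend
  $\alpha(\mu) = a_0 + a_1/\mu$ fitted by a gamma GLM; the working
  dispersion is $\max(\text{raw}, \text{trend}, 10^{-8})$. A design
  with a single sample in every group (rare sorted pools are sometimes
  sequenced only once) falls back to blind trend-only mode with a loud
  warning.
* **The conditioned NB exact test**: group totals are negative binomial
  with means proportional to the groups' summed size factors and
  variances $\sum_i (\mu_i + \alpha\mu_i^2)$; conditioning on the grand
  total, the two-sided p-value sums the probabilities of all splits at
  most as probable as the observed one. At $\alpha = 0$ this reduces
  exactly to the binomial test (verified to $10^{-6}$ by enumeration),
  and the general case is verified against an independent
  lgamma-based enumeration for all totals up to 100.
* **Multiple testing** by Benjamini–Hochberg within each pool (such
  screens are reported as per-pool ranked tables; the choice is
  recorded in output metadata).
  Ranking ties break by (padj, p, decreasing |log2FC|, gene name) so
  output order is identical across platforms.
* The displayed fold change uses a pseudocount of 0.5 common-scale
  counts to avoid infinite values for dropouts; the pseudocount never
  enters the test.

A caveat that follows from the design, not from the implementation:
median-of-ratios assumes most genes are unchanged. In a razor-clean
sorted pool nearly all reads come from the few truly enriched mutants
and the assumption degrades; in practice (and in the simulator) the
small impurity background of every real sort anchors the size factors.

## Classification

A gene significantly positively enriched (padj ≤ 0.05, log2FC ≥ 1 by
default) in both negative gates is called `GFP_NEG`; in the induced
basal gate, `NON_INDUCER`; in the uninduced elevated gate,
`HIGH_BASAL`; in the hyper-induced gate, `HYPER_INDUCER`. Overlaps
resolve by exactly that priority order (double-pool evidence first).
The priority chain also absorbs physical spillover: a non-inducing
mutant sits at the basal level and necessarily leaks into the induced
negative gate; an elevated-basal mutant leaks into the hyper-induced
gate — real screens of this design observe that the top hits of those
two pools overlap.

# The synthetic screen

The generator is first-class, tested code: it is the package's ground
truth for end-to-end validation.

* **Fluorescence model.** Per class and condition, log10 fluorescence
  per cell is normal (log-normal fluorescence), the simplest family
  matching the unimodal log-axis peaks of flow histograms; the
  switching class is a two-component mixture (default 80% silent / 20%
  expressing). Defaults (log10 arbitrary units): negative control at
  1.0, wild-type basal at 2.0, induced at 3.5, peak SD 0.15. The
  elevated-basal class sits at twice the wild-type basal median and the
  documented two- and three-fold scenarios are reachable via
  `high_basal_fold`; the induced/basal separation is a free parameter
  chosen for clean peak separation, since real screens report it
  only graphically.
* **Gates** are derived from simulated control samples, mirroring
  gating against control strains on the sorter: negative gates end at
  the basal control's 1st percentile, the elevated gate starts at its
  99th, the hyper gate at the induced control's 99th. Overlapping
  controls at the requested percentiles raise a configuration error.
* **Sorting.** The sorter analyzes `n_cells_analyzed` cells per
  condition (default 10 × the collected pool size, i.e. about 10^3
  cells per strain per condition at defaults — the scale of a 10^7-cell
  sort of a genome-wide library) and collects `n_cells_sorted` cells
  per gate. Each collected pool is contaminated with a small fraction
  (`sorting_impurity`, default 2%) of ungated parent cells: a sort is
  never perfectly pure, re-analysis of sorted pools in real screens
  shows exactly this, and the impurity background is what keeps
  normalization anchored (see above). This parameter was set a priori
  from those considerations, not calibrated to any test.
* **Regrowth** multiplies expected composition by
  `fitness^generations`, renormalizes and resamples multinomially at
  the same total, so neutral pools experience pure multinomial drift.
* **Sequencing.** Per-gene read shares are distorted by a log-normal
  per-gene PCR efficiency factor (SD 0.2 on the log scale — one
  parameter reproducing typical Bar-Seq overdispersion) and reads are
  drawn multinomially; each base substitutes independently at rate
  0.001; reads are truncated/padded to 50 nt (50-cycle single-end).
  Indels are not modeled: matching is Hamming-based, and indel realism
  is out of scope.
* **Multiplex tags** are generated with minimum pairwise Hamming
  distance 4 and rotated across replicates, as Bar-Seq protocols
  rotate their tag–sample assignments to avoid primer-specific bias.

What the generator does **not** emulate: transformation background and
mis-integration (upstream of the sorted pool), heavy-tailed instrument
artifacts (doublets, autofluorescence smear), amplification
cycle-by-cycle branching, indels, and quality-score structure
(qualities are fabricated constant). A green end-to-end test therefore
establishes that the analysis chain inverts this stated generative
model at realistic noise levels — not that it is robust to every
artifact of real flow or sequencing data.

# Concordance at the top

`cat_curve()` reports $|{\rm top}_d(A) \cap {\rm top}_d(B)|/d$ over a
depth grid (default 10, 20, … up to min(G, 1000), plus G). Under the
null of two independent uniform orderings the overlap at depth $d$ is
hypergeometric$(G, d, d)$, and the null band is the two-sided 99.9%
quantile region by default. Two-sided is deliberate: agreement *above*
the band is how correspondence manifests at the top of the lists, and
the exit direction is reported. The band is verified against exhaustive
enumeration at small sizes and against 10^6 simulated ordering pairs.
The ranking key for response comparisons is decreasing |log2FC|
(`rank_by_response()`); published CAT comparisons rarely state their key,
so this is a documented package choice.

# Flow-cytometry summaries

Fold changes between strains use medians on the log10 axis
(`10^(median - median)`): flow distributions are heavy-tailed and the
comparison being reproduced is location-based. Bimodal subpopulations
(the silencing-switch phenotype) are detected by a two-component normal
EM fit on the log10 axis — quantile-split initialization plus four
random restarts under fixed seeds, scales floored at 10^-3 sample SDs
to keep the likelihood bounded, per-iteration monotonicity asserted —
and called bimodal when the two-component model beats one component by
more than 10 BIC units, the minor weight is at least 0.05, and the
locations are at least 0.3 log10 units (two-fold) apart. The underlying
observation was visual; the BIC-10 / 0.05 / 0.3 criteria are the
package's own, chosen as conventional "very strong evidence" and
detectability limits, and their false-positive rate is measured by the
test suite rather than asserted.

# Numerical and interface choices

* All intervals are 0-based half-open; stated once, used everywhere.
* Probability ties in the exact test are accepted with relative
  tolerance 10^-7 so float noise cannot drop the observed split.
* Every simulation stage derives a child seed from the master seed;
  identical configuration gives bit-identical FASTQ output.
* The pipeline configuration is a single JSON document (chosen over
  YAML/TOML because the JSON reader is a guaranteed dependency in the
  package's target environment); all CLI flags override config keys.
* Output tables carry `# key: value` provenance headers (package
  version, seed, thresholds, dispersion mode) sufficient to re-run the
  stage.

# Known limitations

* The exact test is the classic lineage by design: no shrinkage of fold
  changes or dispersions, no outlier handling; very low replicate
  numbers lean heavily on the dispersion trend.
* Hamming matching does not recover reads with indels in the barcode.
* Classification is rule-based on significance patterns; mutants with
  phenotypes between classes (e.g. mild basal elevation) land in
  whichever pools reach significance and may be conservatively left
  unclassified.
* The normalization caveat above applies to extremely pure pools with
  few enriched strains; ranked lists remain informative there, but
  calibrated fold changes do not.
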