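---
title: "Methods: pool-seq FST scans, permutation nulls, and hemocyte indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq FST scans, permutation nulls, and hemocyte indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

`poolscan` implements a two-population pooled-sequencing divergence scan and
the immune-assay indices that motivate it. This vignette is the package's
account of the statistical choices: the estimators, the defaults and why
they are what they are, what the synthetic-data generator does and does not
emulate, and the numerical conventions.

## The FST estimator

Pool-seq gives, at each site, read counts over alleles for a pool of many
individuals. After biallelic reduction the data at a SNP are the pool
minor-allele frequencies $p_1, p_2$ estimated from reads. The package uses
the classical Nei-style heterozygosity-ratio estimator:

$$H_i = 2p_i(1-p_i), \quad H_W = \tfrac{1}{2}(H_1+H_2), \quad
\bar p = \tfrac{1}{2}(p_1+p_2), \quad H_T = 2\bar p(1-\bar p),$$
$$F_{ST} = \frac{H_T - H_W}{H_T}.$$

Pools are weighted equally in $\bar p$ and $H_W$ regardless of coverage: the
design is a balanced two-population comparison, and coverage weighting would
let run-to-run depth fluctuations re-weight the populations. (Coverage
weighting can be obtained by pre-aggregating counts; the package does not
offer it as a flag because the equal-weight form is the one whose null the
permutation machinery assumes.)

Uncorrected, $F_{ST} \in [0,1]$ for every polymorphic site; this is the
default. A finite-sample correction multiplies each $H_i$ by $n_i/(n_i-1)$
with $n_i = \min(\text{coverage}_i,\, 2\cdot\text{pool size}_i)$ — the
effective number of sampled chromosomes is bounded both by reads and by the
pool itself. Corrected values can be negative and are *retained*: clamping
at zero would bias genome-wide means upward and distort the permutation
null. The correction defaults off because the pool sizes behind a given
sync file are often unknown; when they are known, pass
`correction = "pool"` and `pool_size`.

**Regions.** A gene's $F_{ST}$ aggregates its exonic SNPs by the ratio of
sums $\left(\sum_s H_{T,s} - \sum_s H_{W,s}\right)/\sum_s H_{T,s}$, which
weights informative (high-$H_T$) sites more and is the region estimate
commonly produced by pool-seq toolchains. Whether published per-gene values
are this ratio or a plain mean of per-SNP values is often ambiguous, so
`region_fst(..., method = "mean")` provides the alternative; the default is
the ratio. The flanking estimate covers exons plus 5 kb on each side of the
gene span ("flanking + coding region"), clipped at scaffold ends. Flank
extension is symmetric, so the combined region is strand-independent;
strand is still recorded for any directional downstream use.

**SNP calling.** The two alleles with the highest summed read count across
pools (A/C/G/T only) form the site's biallelic reduction; third-ranked
counts are dropped from coverage rather than redistributed, the simplest
defensible projection, and such sites are counted in the rejection log.
Ties are broken by base order A < C < G < T so calls are deterministic.
Sites are rejected — a tagged outcome, not an error — when monomorphic
across both pools, when either pool's two-allele coverage leaves
[`min_coverage` = 10, `max_coverage` = 500], or when the summed minor count
is below `min_minor_count` = 2. The thresholds mirror common pool-seq
practice (a lower bound that keeps frequency estimates meaningful, an upper
bound against collapsed repeats, a two-read minimum against sequencing
error); they are not tuned to any dataset. Genes with zero surviving exonic
SNPs have undefined $F_{ST}$ and are excluded from the gene background —
including them (as zeros, say) would drag both the genome-wide mean and the
permutation null toward zero.

## Masking and coordinates

Indels are masked with an odd window (default 5 bp) centred on the indel
position; windows merge when they overlap, and the mask clips at the
scaffold start. Non-genic masking restricts to exons by default; whether a
gene-wise sync should cover whole gene spans instead is genuinely
underdetermined in pool-seq practice, so `apply_masks(feature = "gene")`
switches to spans. Masking is idempotent.

Internally every interval is 0-based half-open; 1-based inclusive
coordinates exist only at the GFF3 and sync file boundaries
(`gff_start = internal_start + 1`, `gff_end = internal_end`). This makes
flank arithmetic, clipping and merging unambiguous. BED12 is already
half-open and needs no shift.

## Candidate-set permutation test

The candidate set's mean $F_{ST}$ is compared with the means of `n_perm`
(default 10,000) same-size sets drawn uniformly *without replacement* from
the background — a set of genes cannot contain duplicates. Random sets are
drawn from the full background *including* the candidates, reading "random
genome-wide sets" literally; excluding candidates (available via
`exclude_candidates = TRUE`) makes the null slightly anti-conservative for
large candidate fractions but changes little at 73-in-13,000 scale.

P-values use the plus-one convention $p_{\text{greater}} =
(1 + \#\{\bar x_{\text{null}} \ge \bar x_{\text{obs}}\})/(n_{\text{perm}}+1)$,
so no p-value is ever zero, and ties count in both tails. Both one-sided
p-values and the doubled two-sided value are always reported, never a
silently chosen tail: a candidate set can be significantly *less* diverged
than the genome (a high $p_{\text{greater}}$ near 1 with a small
$p_{\text{less}}$), and that direction is as informative as the other.

Null means are computed as `mean(sort(sample))`: sorting fixes the
summation order, so two draws of the same multiset give bitwise-identical
doubles and tie counting is exact, which matters for the degenerate
candidate-set-equals-background case and for byte-reproducible reruns. The
background mean is the exact expectation of a null mean under uniform
sampling without replacement, which the test suite checks to Monte-Carlo
precision.

The same function performs the SNP-level analysis: values are named by
`scaffold:position` ids, and the candidate SNP set is the SNPs falling in
the candidate genes' exons (`snps_in_genes()`). No length- or
density-matched resampling is attempted; random sets are simple random
sets, so gene length and SNP density gradients are part of what the test
measures.

## Outliers and term enrichment

The outlier threshold is the linearly interpolated empirical percentile
(R's `quantile` type 7, the common default definition — the estimator is
recorded in output metadata since published percentiles rarely name
theirs); outliers are *strictly above* the threshold ("peaks above the
line"), with ties at the threshold excluded and counted. At the default
97.5 this selects the top 2.5%, up to ties.

Enrichment is the classic one-sided hypergeometric (Fisher) test per term,
Benjamini–Hochberg-adjusted across the terms retained after restriction to
the background (genes with defined $F_{ST}$ — genes without data cannot be
outliers and must not inflate term totals) and the minimum-term-size filter
(default 5, the nodeSize-style cutoff removing terms with fewer than five
annotated genes). Graph-aware decorrelation methods (elim/weight-style) are
deliberately not implemented: they require the ontology DAG, and the
classic test is the transparent baseline against which those refinements
are interpreted. A curated candidate list can be injected as its own custom
term (`add_candidate_term()`), which is how a phagocytosis gene set is
tested directly for over-representation among outliers.

## Hemocyte assay indices

The hemocytometer concentration is
$(\text{cells} \times 10)/(\text{squares} \times \text{dilution})$ with
*dilution* the **hemolymph fraction** of the counted suspension (1/20 for
8 µL hemolymph in 160 µL total), not the fold factor; the fraction reading
is the only one that puts fifth-instar larval counts at the observed
~14,000 cells/µL scale — with 700 cells over 10 Neubauer squares,
$(700 \times 10)/(10 \times 0.05) = 14{,}000$. The ×10 factor converts the
0.1 mm chamber depth to a 1 µL column.

Replicate slides are pooled by summing counts per individual before any
index is formed: the pooled-count index is the individual-level point
estimate, whereas a mean of per-replicate ratios weights small slides up.
Per-replicate indices are also emitted for mixed-model use (replicates as
random factors), but the package stops at tidy tables — model selection
belongs to a stats package, not here. The specific phagocytic index
(within-type phagocytosis propensity) is undefined for individuals in which
a type was never observed; such records are excluded from that type's
analysis and counted, never zero-filled, since not all slides contain all
cell types. By construction the per-type indices, weighted by type totals,
average exactly to the overall phagocytic index.

## The synthetic-data generator

The generator exists so every pipeline claim is testable against recorded
ground truth; its defaults are the desk-scale study conditions used
throughout the tests.

**Divergence.** Per SNP, an ancestral frequency $p \sim U(0.05, 0.95)$ and
Balding–Nichols population frequencies
$q_i \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$,
giving expected fixation index $F$ — direct, seedable control of the
parameter the estimator targets, with no external simulator. Two sampling
layers follow: pool allele frequency
$\mathrm{Bin}(2N, q_i)/2N$ over $N$ = 50 diploids, then read counts
$\mathrm{Bin}(d_i, \cdot)$ at Poisson depth $d_i$ (mean 100). These two
layers are exactly what biases pool-seq $F_{ST}$ at finite depth — the
reason the correction flag exists. Defaults: 2 scaffolds × 2 Mb, 500
non-overlapping genes (1–10 exons), 20 candidate genes, SNP density 0.005
(20,000 SNPs), background $F = 0.05$ — the low-divergence allopatric regime
of a genome-wide mean $F_{ST}$ near 0.05 across ~10⁴ genes, scaled desk-size
from the motivating design (~13,700 genes, 73 candidates) so the full chain
runs in seconds. `candidate_F` applies to SNPs inside candidate gene spans
and equals the background by default (a null candidate set); planted-signal
tests raise it.

What is *not* emulated, hence what passing tests cannot show: no linkage or
recombination (each SNP is an independent draw, so a real gene's SNPs are
more correlated and its $F_{ST}$ noisier than simulated at equal SNP
count), no selection or demographic history, no mapping artefacts, and no
sequencing-error model beyond binomial read sampling. Monomorphic filler
sites (density 0.001) exercise the SNP-rejection path only.

**Cohort.** Per larva: total hemocyte concentration
$\sim$ NegBin(mean 14,037, SD 7,125) — the observed scale and overdispersion
of larval counts — with a Poisson hemocytometer observation; cell-type
composition Dirichlet-multinomial (granulocytes dominant:
0.55/0.30/0.10/0.05, concentration 60); and per-type phagocytosis binomial
with logit-additive structure: population base (north 0.80 vs south 0.67,
echoing the motivating group contrast), a +0.25 logit male effect, and
type offsets (granulocytes most active, "other" least). Defaults are 11
individuals per population × sex and 2 replicate slides of ~100 scored
cells, the assay's actual shape. The generating propensity table is emitted
as truth for recovery tests.

## Numerical conventions and reproducibility

* Undefined results (empty regions, zero-hemocyte individuals, absent cell
  types) are `NA` markers, never zero, and exclusions are messaged with
  counts.
* All randomness flows from one master seed; per-stage seeds are derived
  deterministically (`derive_seeds()`), and permutation results are a pure
  function of (background, candidates, `n_perm`, seed). Pipeline reruns
  under one seed are byte-identical, manifest included (the manifest
  records version, seeds, parameters, input MD5s and row counts, and no
  timestamps, precisely so that reruns compare equal).
* Degenerate inputs: an all-identical value vector yields zero outliers
  with a warning; a candidate set equal to the background yields exact
  $p = 1$ in both tails; monomorphic sites can never reach the $F_{ST}$
  kernel (the guard is an assertion, since the filter contract excludes
  them).

## Problem sizes used by the test suite

The suite validates the estimators against independently coded brute-force
oracles (exact to 1e-12) and the generators against truth-based Monte-Carlo
expectations. The larger experiments run at: 10⁵ SNPs for estimator-range
and parameter-recovery checks at $F \in \{0.01, 0.05, 0.2\}$ (tolerance
±0.02 against a depth- and pool-matched expectation recomputed from truth
frequencies); 5,000-gene genomes with 73-gene candidate sets for
permutation calibration (200 null draws, 2,000 permutations each,
Kolmogorov–Smirnov against uniform at the 1% level) and power (100 genomes
with candidate $F$ twice background, rejection required in ≥80%); 100
genomes of 500 genes with five planted $F = 0.4$ genes for the outlier
scan, parameterised at ~26 exonic SNPs per gene, the empirical
SNP-per-gene density of pool-seq butterfly scans; and cohorts of 50
individuals per group with 200 cells per type for propensity recovery
(±0.02 per type, ±0.03 on the planted population contrast). These sizes
are the package's chosen desk-scale study conditions: large enough that
the stated tolerances are comfortably inside sampling noise, small enough
to run routinely.

## Known limitations

* Exactly two pools; no sliding windows, no $\pi$/$\theta$/Tajima's D.
* The permutation null ignores gene length and SNP density matching.
* Enrichment is DAG-blind classic Fisher; ontology-topology methods will
  rank terms differently.
* The corrected estimator needs true pool sizes; with unknown pools the
  uncorrected estimator's depth-dependent bias is shared by candidates and
  background, which is why the permutation comparison, not the absolute
  $F_{ST}$ value, carries the inference.
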