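---
title: "Detecting and dating ancient whole-genome duplications with paleodup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating ancient whole-genome duplications with paleodup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodup)
```

## The problem

A whole-genome duplication (WGD, polyploidization) copies every chromosome
of a genome at once. Most duplicates are subsequently lost, but the
survivors leave two durable signatures that can still be read a hundred
million years later:

* **Collinearity.** Surviving duplicates sit in long runs of genes whose
  order is preserved between chromosome copies — syntenic blocks. Counting
  how many regions of a duplicated genome correspond to one region of an
  unduplicated relative (the *syntenic depth ratio*) reveals how many
  rounds of duplication occurred: a 1:4 ratio against an unduplicated
  outgroup means two rounds.
* **Synonymous divergence.** Synonymous sites are largely free of
  selection, so the synonymous substitution distance Ks between two
  duplicates accumulates roughly clock-like. All pairs created by the same
  WGD share one divergence time, so their Ks values cluster in a peak, and
  a genome with two WGDs shows two peaks. With a synonymous rate `r`
  (substitutions/site/year), a peak at Ks dates its event at
  `T = Ks / (2 r)` — the factor 2 because both copies accumulate
  substitutions.

The same clock logic dates LTR retrotransposons: an element's 5′ and 3′
long terminal repeats are identical when it inserts, so their present-day
divergence `λ` (mismatch proportion), corrected for multiple hits with
Jukes–Cantor, `K = -0.75 ln(1 - 4λ/3)`, gives the insertion age
`T = K / (2 r)`.

paleodup implements this whole chain — anchor detection, collinear block
chaining, NG86 Ka/Ks, per-block median Ks distributions, kernel density
estimation and multi-Gaussian peak fitting, rate calibration and
cross-lineage rate correction, WGD and LTR dating, plus a k-mer genome-size
survey — together with a synthetic-evolution simulator that generates data
with known truth for every one of those stages.

## The synthetic-evolution simulator

No stage of the pipeline is validated against convenience data; everything
is tested on simulations whose true parameters are known. The generative
model deliberately inverts the dating formulas:

* An ancestral genome (`simulate_ancestral_genome()`) distributes genes
  round-robin across chromosomes and gives each one a random sense-codon
  CDS.
* Each WGD (`apply_wgd()`) duplicates every chromosome at an age `T`;
  each *new* gene is lost independently with probability `loss_prob`
  (i.i.d. loss, no biased fractionation — the simplest model that yields
  the expected depth ratios). Tandem copies and chromosome
  fission/fusion operations are available but default to off.
* Duplicate coding sequences are diverged with synonymous-only
  substitutions (`evolve_pair_sequences()`), so Ka stays ≈ 0 and Ks
  measurement is unconfounded. For a pair whose most recent common
  duplication has age `T`, the measured NG86 Ks is driven to a target
  drawn from `Normal(2 r T, sd)` truncated at zero.
* LTR cohorts (`simulate_ltr_cohort()`) evolve both copies of a random
  ancestral LTR independently under Jukes–Cantor so the expected pairwise
  distance is `2 r T`; no indels are simulated, keeping the alignment
  policy out of the generator.
* Error-free reads at fixed coverage (`simulate_reads()`) feed the k-mer
  survey.

Two implementation details matter for interpreting recovery tests.
First, for a two-copy family the target is enforced directly: the
duplicate is mutated until the *measured* pairwise Ks crosses the target
(the crossing side closer to the target is kept; with 300-codon genes one
substitution moves Ks by ≈ 0.008, which bounds the targeting error).
Second, families with three or more copies cannot satisfy independent
pairwise targets simultaneously, so they are evolved along their
duplication tree: a two-sided calibration run first records how measured
Ks grows with the number of placed substitutions, and branch substitution
budgets are then read off that curve so that every pair's divergence
reflects the age of its most recent common event. Cross-event pairs of
four-copy families retain a small (+2–3 %) upward bias from the
non-reversibility of the within-synonym-set substitution chain; this is
visible as a slight rightward shift of the older Ks peak in end-to-end
runs and is well inside the 10 % recovery tolerance the end-to-end tests
assert.

Per-branch target dispersion is proportional to branch time and
calibrated so a pair split at the *oldest* simulated event has standard
deviation `ks_sd`; younger peaks are proportionally tighter
(`sd × sqrt(T/T_oldest)`), which is also what a clock with rate noise
would produce. The default `ks_sd = 0.12` is a modelling choice — peak
widths are not a published quantity — picked so that two peaks at Ks
0.655 and 0.944 overlap realistically without merging.

What the simulator does *not* emulate: codon-usage bias, indels,
transposon nesting, heterozygosity or repeat structure in reads, and
biased fractionation. Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to every property
of real genomes.

## Synteny

`find_anchors()` reduces a homology hit table (12-column BLAST tabular via
`read_blast_tab()`, or internally computed by `homology_hits()`) to anchor
pairs: self-hits removed, per-query top-`top_k` partners above
`min_score`, then symmetric closure. `homology_hits()` groups identical
protein translations — exact for simulated data, whose divergence is
synonymous-only — and offers a global-alignment identity mode
(identity ≥ 50 %) for small mixed inputs; real data should bring an
external BLAST file.

`chain_blocks()` is MCScanX-style collinearity chaining: within each
chromosome pair, dynamic programming finds the maximal-score chain of
anchors with strictly increasing ranks on one genome and strictly
monotone ranks (both orientations) on the other, consecutive anchors at
most `max_gap = 25` ranks apart, chain score = anchors − 0.5 per gapped
step. Chains are peeled greedily (best first, each anchor used once) and
chains shorter than `min_anchors = 5` are discarded. The published
MCScanX defaults are used because the original parameters are not
printed anywhere; all are exposed. The scoring rule was chosen to be
simple enough that an exhaustive-enumeration oracle verifies the DP
optimum on every small random instance in the test suite.

`classify_duplications()` applies the standard duplicate-mode hierarchy
(block member → `wgd_segmental`; rank-adjacent → `tandem`; within 10
ranks → `proximal`; else `dispersed`), in that precedence order, so the
classes partition all pairs.

`syntenic_depth()` counts, for every gene, the distinct blocks whose rank
span covers it, and reports the modal depth over covered genes in both
directions. Block *span* coverage (not per-anchor hits) is used so that
genes whose individual duplicate was lost still count as covered, and the
mode (not the mean) is reported, matching the integer ratios this
analysis is quoted in. Simulated checks: an unduplicated sister against a
two-WGD lineage yields 1:4; a one-WGD against a two-WGD lineage yields
2:4.

## Ka/Ks

`align_codons()` translates, aligns the proteins globally (BLOSUM62,
affine gaps 10/0.5) and back-translates gaps in whole-codon units.
`ng86_kaks()` implements Nei–Gojobori (1986): fractional synonymous site
counts per codon averaged over both sequences, difference counts averaged
over all minimal substitution pathways excluding those through stop
codons (all pathways are used if every one is blocked), and Jukes–Cantor
correction of both proportions. `S + N = 3 ×`(codons compared) holds
exactly; estimates with `ps` or `pn` ≥ 3/4 are flagged saturated instead
of producing a value.

The published analysis this reimplements used codeml (maximum
likelihood); NG86 is used here instead because it is fully specifiable
and closed-form, so unit tests can assert hand-computed counts exactly.
The simulator's mutation process is NG86-consistent, so dating results
are unaffected by the substitution-model choice; numeric equality with
codeml on real data is *not* claimed.

Downstream fitting uses the Ks window `0.01 ≤ Ks ≤ 2.5`: the lower edge
removes allelic/recent-tandem near-zero pairs, the upper removes
saturated estimates.

## Ks distributions and peak fitting

`block_median_ks()` takes the median Ks over each block's usable pairs
(blocks with fewer than 3 usable pairs are dropped); one value per block
keeps large blocks from dominating. `ks_kde()` puts a Gaussian kernel
density on a 512-point grid over the Ks window, bandwidth by Silverman's
rule, renormalised to unit trapezoid mass over the window.

`fit_gaussian_peaks()` fits a sum of `k` Gaussians to the *density curve*
by least squares (Levenberg–Marquardt with positivity bounds), for
`k = 1..max_components`. This follows the curve-fitting-toolbox procedure
of the original analysis rather than EM on the raw values. Starts are
deterministic: component means at the `k` largest curve maxima (padded
with mass quantiles) crossed with three width scales, best RSS wins, so
refitting the same curve reproduces identical components. The component
count is selected by AICc on the curve residuals with two
identifiability guards: a fit is degenerate if any component carries less
than 8 % of the fitted mass or if two means lie closer than
0.75 × (σᵢ + σⱼ). Without the guards, extra components always pay for
themselves by chasing smoothing wiggles; with them, single-Gaussian
samples select one component and well-separated mixtures select the true
count in ≥ 90 % of seeds. Ties resolve toward fewer components. When the
number of duplication events is known a priori (e.g. dating a genome
whose depth ratios already establish two WGDs), capping
`max_components` at that count is the intended usage.

The LS-on-KDE estimator of component means is unbiased but has ≈ 3 %
relative standard deviation at n = 3000 block medians for overlapping
peaks — noticeably wider than an EM fit would give. That dispersion is a
property of fitting the smoothed curve and is inherited by downstream
age estimates.

## Dating

* `correction_coefficient()` — lineages differ in synonymous rate, so
  before comparing Ks across species each lineage is rescaled by
  `rho = Ks_out,ref / Ks_out,i`, the ratio of ortholog-peak Ks values
  against a common outgroup. After correction all lineages share the
  reference's time scale. (The exact formula in the source analyses is
  not printed; this ratio form is the standard construction and is
  idempotent, which the tests assert.)
* `calibrate_rate()` — `r = Ks / (2 T)` at a node of known age. The
  Laurales-type calibration (corrected Ks 0.944 at 112.1 Ma) reproduces
  `r ≈ 4.21e-9`.
* `date_wgd()` — `T = Ks / (2 r)`, exactly inverse to the simulator's
  generative law, reported in Ma.
* `ltr_divergence()` / `ltr_insertion_time()` / `date_ltr_cohort()` —
  per-element λ from a global alignment (mismatches over non-gap
  columns), `K = -0.75 ln(1 - 4λ/3)`, `T = K/(2r)` with the default LTR
  clock `r = 1.51e-9`; λ ≥ 3/4 yields a saturated flag, not a value.
* `ltr_burst_profile()` — KDE over per-element K; the mode locates the
  insertion burst. A cohort inserted around 9.9 Ma at the default rate
  peaks at K ≈ 0.03.

Whether "the mean Ks of syntenic blocks" in rate calibration means the
fitted peak mean or the arithmetic block mean is ambiguous in the source
material; both are trivially available here (`fit$components$mean` vs
`mean(medians$ks)`), and the fitted peak mean is the default used
throughout, since it is robust to the mixture's other component.

## K-mer survey

`count_kmers()` counts canonical k-mers (lexicographic minimum of k-mer
and reverse complement) with 2-bit packing into doubles — exact for
k ≤ 25; k = 17 is the default, k must be odd so no k-mer is its own
reverse complement. `estimate_genome_size()` cuts the error spike at the
first local minimum of the depth histogram, locates the coverage peak
above it, and divides the counted k-mers above the cutoff by the peak
depth. The peak depth is estimated as the count-weighted mean depth
within [mode/2, 1.5 × mode] rather than the raw integer mode: the mode
quantises the estimate by about one part in the coverage, which alone
would exceed the ±2 % invariance to k and coverage that the estimator
should (and, in tests, does) satisfy. Heterozygosity and repeat
modelling are out of scope; simulated reads are homozygous and
error-free, so the error cutoff is exercised with constructed histogram
fixtures.

## Orchestration and reproducibility

`run_pipeline()` runs the stages (`simulate`, `synteny`, `kaks`,
`peaks`, `date_wgd`, `date_ltr`, `survey`) in dependency order from one
nested configuration (R list or YAML), rejecting unknown keys and
missing stage dependencies before any work. Every TSV artefact carries a
header comment with package version, configuration hash and seed; JSON
reports embed the same provenance. All randomness flows from the single
seed through fixed per-stage offsets, and rerunning a configuration
reproduces every output byte-identically (asserted in the tests by
checksumming two runs). Coordinates are 0-based half-open internally;
GFF3 (1-based inclusive) and BED (0-based half-open) conversions happen
only in the readers/writers, which round-trip losslessly.

## Numerical choices, in one place

| Quantity | Default | Why |
|---|---|---|
| Ks window | [0.01, 2.5] | drop allelic pairs / saturated estimates |
| Block min usable pairs | 3 | a median of fewer is noise |
| Chain `min_anchors`, `max_gap`, `top_k` | 5, 25, 5 | published MCScanX defaults |
| Chain score | anchors − 0.5/gap run | simplest oracle-verifiable rule |
| KDE grid, bandwidth | 512 points, Silverman | curve smooth at these n |
| Peak selection | AICc, k = 1..4, guards 8 % / 0.75·(σᵢ+σⱼ) | see above |
| Ks targeting tolerance | one substitution step (≈ 0.01 at 300 codons) | crossing-side choice |
| Survey k, error cutoff | 17, first local minimum | standard survey practice |
| LTR clock | 1.51e-9 /site/yr | the magnoliid LTR rate in common use |
| Ages | Ma, computed in years at double precision | |

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to keep the complete
run around a minute and a half while still testing the regimes that
matter: ancestral genomes of 40–1000 genes (1000 for the depth-ratio and
end-to-end recovery checks, with 200–300 codons per gene), 3000-value Ks
mixtures for peak fitting, LTR cohorts of 400–2000 elements at 1 kb, and
100 kb genomes at 30× for the survey. Chaining is verified against
exhaustive enumeration only on instances of ≤ 20 anchors, where
enumeration is feasible; nothing about the DP depends on instance size.

## Known limitations

* NG86 (not ML) Ka/Ks: fine for dating simulated data and for Ks-based
  peak work, but not numerically interchangeable with codeml output.
* LS-on-KDE peak fitting inherits KDE smoothing: component σ estimates
  are inflated by roughly the bandwidth in quadrature and means carry
  ≈ 3 % sampling dispersion at n = 3000; use the EM route of your choice
  if you need tighter component means from raw values.
* The depth-ratio machinery assumes gene ranks are trustworthy; heavily
  fragmented assemblies (many tiny scaffolds) will undercount depth.
* The simulator's i.i.d. gene loss ignores biased fractionation, so
  dominance patterns between subgenomes cannot be studied with it.
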