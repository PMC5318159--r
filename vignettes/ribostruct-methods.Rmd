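---
title: "Methods: mRNA structure, translation efficiency, and operon organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mRNA structure, translation efficiency, and operon organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ribostruct)
```

## The scientific problem

Bacterial operons place several open reading frames (ORFs) on one mRNA, yet
adjacent ORFs are often translated at very different rates. ribostruct
implements an analysis chain that asks how much of that differential
translation is explained by mRNA secondary structure, using three per-base
sequencing readouts of the same culture:

* **DMS-seq** — dimethyl sulfate modifies unpaired adenine and cytosine;
  counts at a base report its single-strandedness;
* **mRNA-seq** — transcript abundance and coverage continuity;
* **ribosome profiling** — footprint density, a proxy for protein synthesis.

The chain quantifies per-ORF structure with a Gini index over A/C
reactivities, computes corrected translation efficiencies (TE), identifies
which adjacent ORFs actually share a message, predicts
reactivity-constrained secondary structures across ORF boundaries, and
provides the supporting statistics (bootstrap correlations, ROC benchmarking
against a reference structure, stepwise regression, outlier tests).

## Structure scoring: Lorenz curves and the Gini index

For a region's A/C positions, sort reactivities ascending and plot the
cumulative signal fraction against the cumulative position fraction (the
Lorenz curve). The Gini index is the area between that curve and the
diagonal, normalized by the area under the diagonal; `gini()` computes it as
`2 * sum(i * x_(i)) / (n * sum(x)) - (n + 1) / n`, which is algebraically
identical to both the trapezoidal Lorenz-area ratio and the normalized mean
absolute pairwise difference (the test suite asserts both equivalences to
1e-9). In a structured region most A/C bases are protected and the signal
concentrates on a few bases (high Gini); in an unstructured region the
signal spreads evenly (low Gini).

Ginis are computed on raw coverage-scaled counts, not on normalized
reactivity: the index is invariant to positive rescaling, so the choice
cannot matter, and the tests assert that too. Odd-length ORFs split halves
at `floor(L/2)` nucleotides; windows truncated at region ends are dropped
rather than shrunk so every reported window is computed from the same
number of bases. Nucleotide halves (not A/C-count halves) were chosen for
`orf_half_ginis()`; this is an assumption, flagged here, and any systematic
A/C skew between halves would bias it.

Degenerate inputs are explicit: an all-zero region has no defined
inequality and returns `NA`; fewer than two A/C positions is flagged.

## Reactivity normalization and unpaired calls

`normalize_reactivity()` caps values above the region's 95th percentile at
that percentile (95% Winsorization) and divides by the resulting maximum, so
the most reactive surviving residue scores 1. Quantiles use linear
interpolation between order statistics (R type 7); the percentile rule is
method-ambiguous at small n, so it is fixed and documented rather than
configurable-by-accident. Normalization spans the scored region (an ORF or
an explicit window), not the whole transcriptome, because every downstream
quantity is region-relative. A and C bases above a 0.2 threshold (fraction
of the maximum) are called unpaired; G and U carry no call because DMS does
not report on them. Untreated-control tracks run through the identical code
path — there is no control subtraction.

Coverage gating uses mean raw reads per nucleotide over the ORF, inclusive
at the threshold (default 15 reads/nt). The replicate-reproducibility curve
computes each ORF's Pearson correlation over its first 200 nt (full length
when shorter) and reports the median across ORFs passing each cutoff in
both replicates.

## Translation efficiency

Per ORF:

1. **mRNA abundance (RPKM)** — per-base mRNA-seq counts Winsorized at the
   5th/95th percentiles within the ORF, summed, scaled by
   `1e9 / (length * library_size)`.
2. **Footprint density** — from center-weighted footprint counts: mask the
   first and last 5 codons; divide the initiation-ramp span (default first
   50 codons) by a dataset-wide ramp ratio (mean ramp density over mean
   plateau density across well-covered genes — a single scalar, the simplest
   defensible form); optionally divide by anti-Shine-Dalgarno pause weights
   (off by default; their construction is upstream of this package); cap the
   top and bottom 5% of the remaining per-base signal (90% Winsorization,
   applied after edge masking); average. The correction order is fixed and
   regression-tested.
3. **TE** — density per million footprint reads divided by RPKM. The
   per-million scaling makes TE invariant to sequencing depth and to joint
   library-size rescaling.

Genes with fewer than 128 raw footprint reads, genes on the exclusion list
(selenoproteins; near-identical paralog pairs, seeded with the standard
*E. coli* names and fully configurable), genes with discontinuous mRNA
coverage, and genes without mRNA signal carry QC flags instead of TEs.

## Same-message operon pairs

Two adjacent same-strand ORFs are accepted as residing on one mRNA when
their mean mRNA-seq levels are equivalent and the signal is continuous
across the junction. Both cutoffs are calibrated from intra-ORF variability
at two standard deviations:

* **level** — the sd of log2(first-half / second-half) mean density across
  ORFs; working in log space makes the cutoff symmetric in fold terms;
* **continuity** — the mean + 2 sd of Gini indices of 80-nt windows inside
  ORF bodies; intergenic windows above the cutoff indicate a transcript
  boundary. Only windows that fit entirely inside the intergenic region are
  tested (a junction-centered window for shorter gaps was evaluated and
  rejected: it false-rejects the majority of close-packed junctions while
  breaks require intergenic room anyway), and the tiling is the union of a
  forward and a backward step-40 tiling so the test is exactly symmetric
  under reverse-complementing the genome.

Overlap classification is a sign test on spacing = (downstream start −
upstream end) in 0-based half-open coordinates: spacing <= 0 means the stop
codon overlaps or lies 3' of the start codon. Whole-gene mRNA Ginis beyond
the cohort mean + 2 sd flag discontinuous genes (internal promoters or
premature terminators).

## The folding engine

The internal engine scores −1 per Watson-Crick or GU pair with a minimum
hairpin loop of 3 nt and hard "unpaired" constraints, deliberately simple so
that exhaustive enumeration is a tractable, exact oracle: the Nussinov-style
MFE and the McCaskill-style inside–outside pair probabilities are tested to
1e-9 against brute-force enumeration on short sequences. Ties among
co-optimal MFE structures break deterministically toward the smaller opening
index. Pair probabilities use Boltzmann weight `exp(beta)` per pair; the
default `beta = 2` makes one lost pair cost a factor of about 7 — on the
order of one helix stack at growth temperature — so the ensemble
concentrates near the MFE without freezing; `beta -> 0` recovers the uniform
ensemble (also tested). The partition function rescales per-base so a
500-nt window stays inside double range. Absolute energies are NOT
thermodynamic: figures built on this engine reproduce shapes and signs, not
kcal/mol. An adapter around the ViennaRNA `RNAfold` binary (`fold_vienna()`)
provides a nearest-neighbor engine behind the same `structure_model`
contract, recording the engine version; the boundary statistics accept any
engine through a plain `(sequence, constraints) -> probability matrix`
function.

## Boundary statistics

For each adjacent pair, the 500-nt window from −250 to +250 around the
downstream start codon is folded, constrained by unpaired calls from the
DMS track when one is supplied. Per position, the pairing probability is
summed into the downstream 60 nt and the upstream 60 nt; the directionality
profile is the ratio of the cross-pair means (down/up) per position — the
ratio of means rather than the mean of ratios, because per-pair ratios are
undefined wherever a window is unstructured. Above 1 means the position
folds preferentially downstream. The metagene profile is the cross-pair
mean of total pairing probability per position. Positions without a full
60-nt window on both sides are not reported, and pairs without 250 nt of
context are skipped with a log entry.

## tRNA adaptation index

`relative_adaptiveness()` builds codon weights from tRNA gene copy numbers:
each codon is read by its Watson-Crick anticodon plus one wobble anticodon
(codon-U by G34, codon-C by inosine, codon-A by inosine, codon-G by U34),
each contribution scaled by `1 - s` with the classical fitted wobble
penalties (0.41, 0.28, 0.9999, 0.68) as overridable defaults; weights are
max-scaled and zero-weight codons receive the geometric mean of the nonzero
weights. `tai()` is the geometric mean of body-codon weights (start and
stop codons excluded), computed in log space to avoid underflow; internal
stop codons are flagged rather than scored. The bundled
`synthetic_tgcn.tsv` is an illustrative, non-biological copy-number table
constructed only so that every codon family is decodable — substitute your
organism's table for real work.

## Statistics

Spearman correlations use average ranks (count data tie heavily) with
case-resampling bootstrap percentile intervals; two bootstrap distributions
are compared by a two-sample Kolmogorov-Smirnov test. ROC benchmarking
against a reference structure defines positives as bases unpaired *and*
solvent-accessible, negatives as paired bases, and excludes everything else
(notably unpaired-but-buried bases); AUC is computed by the rank-sum
formula and cross-checked against pROC in the tests. TE regressions operate
on log TE (TE spans orders of magnitude); stepwise fits add features in the
given order and test each addition with a nested-model F-test. The outlier
test — for a gene that falls off a cohort trend, e.g. after a mutation — is
the externally studentized residual from the x–y regression with a
Bonferroni correction over the cohort; the procedure behind the published
number is unnamed, so this standard test is adopted and stated.

## What the synthetic data emulates — and what it does not

`simulate_study()` generates a genome of operons (dense spacing with a
majority of adjacent pairs within 25 nt and a configurable overlapping
fraction), ground-truth structures, and all four tracks:

* **Structures** are tiled hairpins with exact per-base paired labels.
  Stems are random Watson-Crick pairs, so each pair contributes exactly one
  A/C and the realized paired fraction of A/C bases is controlled to within
  0.05 of target; loops and all intergenic filler are drawn from {A, C} so
  that noiseless reactivity constrains every truly unpaired base (loops
  switch to G/U only when a high target is otherwise infeasible). The first
  25 nt of each ORF stay unstructured, mirroring the low-pairing zone at
  bacterial translation starts, and hairpins never span boundaries unless a
  violation is requested.
* **DMS-seq** counts are Poisson draws around a latent per-base rate track:
  structural means (unpaired A/C = 3 x depth, paired A/C scaled by a 0.1
  leak, G/U at 0.1 x depth — the leak is a knob, since its true value is
  not established) times gamma noise with shape 8. Marginally each track is
  negative binomial; replicates share the rate track and differ only in
  counting noise, which is what makes replicate agreement improve with
  depth. Optional per-operon lognormal abundance multipliers create
  coverage gradients; benchmarks that state a depth run without them.
* **Expression**: `log TE = a − b * paired_fraction + N(0, sigma)` with
  defaults a = 0, b = 4, sigma = 0.3; mRNA level is uniform along each
  message; 20% of junctions with at least 40 nt of intergenic room carry an
  internal terminator/promoter that changes the downstream sub-message's
  level 3–10 fold and leaves a near-zero coverage dip in the gap; footprint
  density is level x TE with a 2x ramp over the first 50 codons.

The generator does **not** emulate sequence-realistic thermodynamic
ensembles, RNA-binding proteins, degradation kinetics, mutational-profiling
readouts, or position-level sequence bias. Passing the recovery tests
therefore shows the pipeline's statistical machinery is correct and
well-calibrated under the stated noise model — not that real libraries meet
that model.

## Problem sizes and numerical choices

The test-suite and acceptance benchmarks use 200-ORF grids at 30 reads/nt
for structure-score recovery, 50 reads/nt for TE recovery, 201 junctions
(20% broken) for the operon caller, 10 boundary pairs folded at 500 nt for
directionality, 1000 random sequences up to 14 nt for the folding oracles,
and 500 simulated datasets (n = 200, 1000 bootstrap replicates) for CI
coverage — sizes at which every check is stable across seeds while the
whole suite runs in a few minutes. Quantile type 7 everywhere; NB size 8 as
moderate library overdispersion; seeds are explicit arguments and every
generator is bit-reproducible given one.

## A worked example

```{r example, fig.width = 5, fig.height = 4}
sim <- simulate_study(seed = 1, n_operons = 20, orfs_per_operon = c(2, 3))
gini_tbl <- orf_gini_table(sim$tracks$dms, sim$annotation)
expr <- expression_table(sim$tracks$ribo, sim$tracks$mrna, sim$annotation)
joined <- dplyr::inner_join(expr, gini_tbl[, c("orf_id", "gini", "included")],
                            by = "orf_id")
joined <- joined[!is.na(joined$te) & joined$included, ]
fit <- spearman_bootstrap(joined$gini, log(joined$te), seed = 1)
tidy(fit)
plot_te_vs_structure(expr, gini_tbl)
```

## Known limitations

* The internal energy model has no stacking, dangles, or temperature;
  use the ViennaRNA adapter when absolute stabilities matter.
* The ramp correction is a single dataset-wide scalar; a per-codon-position
  profile would capture curvature in the ramp.
* The same-message caller tests only the intergenic region for continuity;
  boundaries expressed only under other conditions are invisible to it.
* The caller's continuity cutoff is global, while window-Gini noise grows
  at low coverage; on strongly abundance-skewed data, low-expression
  junctions are rejected more often than the nominal 2-sigma rate.
* tAI ignores organism-specific wobble exceptions (e.g. lysidine-modified
  AUA reading); supply custom weights where those matter.
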