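---
title: "Methods: integrated CUT&Tag and GRO-seq analysis with cutTagGro"
author: "cutTagGro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated CUT&Tag and GRO-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cutTagGro` analyses two complementary genomic readouts of a
DNA-binding transcription factor and the transcription it drives:

* **CUT&Tag fragments** — intervals of tagmented DNA reporting where
  the factor sits on chromatin, with per-condition, per-replicate
  libraries;
* **GRO-seq read 5' ends** — stranded single-base positions of
  nascent-transcript reads, reporting where engaged RNA polymerase II
  is, independent of mRNA stability.

The central scientific contrast the package formalizes is between two
mechanisms by which a perturbation (here, a DNA-binding drug at two
exposure regimes) can reduce a gene's output:

1. **Initiation change** — fewer (or more) polymerases start; signal
   shifts up or down uniformly from TSS to TES.
2. **Processivity (elongation) impairment** — polymerases start but
   attrit with distance; signal decays progressively along the gene,
   hitting long genes hardest.

## The elongation index

For each gene we count sense-strand read 5' ends in three windows that
tile `[TSS - 300, TES + 300)` in transcription coordinates:

* TSS window `[TSS - 300, TSS + 30)`
* gene body `[TSS + 30, TES - 30)`
* TES window `[TES - 30, TES + 300)`

The elongation index of a condition is
`EI = log2((TES_cpm + psi) / (TSS_cpm + psi))` on replicate-pooled CPM,
and the treatment effect is `delta EI = EI_treated - EI_control`. An
initiation-only change cancels in the ratio (`delta EI ~ 0`); an added
attrition of `dkappa` per kb over a gene of length `L` kb gives
`delta EI ~ log2(exp(-dkappa * L))`, e.g. `-1.44` for
`dkappa = 0.1/kb` and `L = 10 kb`. The two regimes are therefore
separable by (i) the slope of the scaled metagene log-ratio profile
across gene-body columns and (ii) the ordering of mean `delta EI`
across gene-length tertiles.

A note on the TSS window orientation: the three windows are defined so
that they tile the extended gene exactly, with the TSS window reaching
300 bp upstream and 30 bp into the gene, mirroring the unambiguous TES
window (30 bp inside, 300 bp beyond). The index is insensitive to this
choice as long as it is applied identically to both conditions,
because window geometry cancels in `delta EI`.

## Response-element stratification

GGAA-core response elements are stratified into:

* **microsatellites** — maximal runs of >= 4 perfect, zero-spacer
  `GGAA` units (both orientations scanned, deduplicated by interval);
  the unit threshold is configurable because published scans differ in
  the repeat model they assume;
* **isolated GGAA** — motifs whose nearest other GGAA/TTCC lies at a
  nearest-edge gap of at least 20 bp (the boundary gap of exactly
  20 bp counts as isolated, a determinate reading of "not within
  20 bp");
* **tandem (heterotypic) sites** — a GGAA within 200 bp nearest-edge
  distance of a cofactor consensus (AP-1 `TGASTCA`, RUNX2 `TGYGGTY`,
  E2F `GCGSSAAA`, FLI1 core `CCGGAAGT`). One GGAA may join several
  cofactor classes; the recorded partner is the nearest qualifying
  site with ties to the smaller start. The consensi are deliberately
  short IUPAC defaults, overridable per call, because the underlying
  position-weight matrices are laboratory-specific.

All distances are nearest-edge, consistent with the half-open overlap
semantics of the interval-intersection step (1 bp overlap retains,
abutting does not). Internally the package uses `GRanges` (1-based
closed, the Bioconductor convention); BED files on disk are 0-based
half-open and converted at the boundary.

## Differential binding

Fragments shorter than 1000 bp are retained; a fragment contributes
once to every peak it overlaps by >= 1 bp. Counts are normalized to
CPM (counts per million retained fragments) — the normalization is
deliberately simple and declared, since published "normalized signal"
pipelines vary. Per peak we report the pseudocounted log2 ratio of
condition means, `log2((mean_t + psi) / (mean_c + psi))` with
`psi = 1` CPM so the statistic is bounded at zero counts.

P-values come from a per-peak location test on `log2(cpm + psi)`
across replicates. The default is a **moderated t** (limma linear
model with empirical-Bayes variance shrinkage across peaks): with the
study design of three biological replicates per condition, a plain
Welch t has ~4 degrees of freedom and its power floor is below what a
planted-truth recovery benchmark requires even when the truth is
noise-free by construction; shrinking peak variances toward the
common trend is the standard remedy and is what dedicated
differential-binding engines do internally. The Welch test remains
available (`method = "welch"`). FDR is Benjamini-Hochberg, with
significance called at FDR < 0.05.

Quality control follows common practice: FRiP (fraction of fragments
in peaks) per library and pairwise Spearman correlation of per-peak
signal between samples; a constant sample yields a missing
correlation, never zero. Known-motif enrichment between a foreground
and a background set of sites uses the upper-tail cumulative
hypergeometric probability.

## Target classification

The driver-silencing DE table is filtered at |log2FC| >= 1 and
adjusted p < 0.01. Because fold changes are expressed as silenced vs
control, *induced* targets (genes the fusion protein activates) are
those that go **down** upon silencing (`log2FC <= -1`); *repressed*
targets go up (`log2FC >= +1`). The fold-change boundary is included
and the adjusted-p boundary excluded, so the printed thresholds are
reproduced deterministically. Sites and peaks are annotated to the
same-chromosome gene with the nearest TSS (midpoint distance,
magnitude only, ties to the lexicographically smaller id) — a
deliberate simplification of full genic-feature annotation hierarchies
that is deterministic and sufficient for element-to-gene joins.
Gene-length tertiles use type-7 quantiles at 1/3 and 2/3; boundaries
are always recomputed from the supplied annotation and reported, never
hard-coded, because published boundary values depend on the annotation
build.

# The synthetic-data generator

The generator emulates the structure of a two-condition exposure
study so the whole pipeline can be validated against planted truth.

* **Genome**: 2 x 800 kb of uniform-random sequence; 48 genes placed
  without overlap, lengths drawn in thirds from 2-6 kb, 8-16 kb and
  20-35 kb so all three tertiles are populated; random strands.
* **Elements**: 100 microsatellites (4-12 units), 100 isolated GGAAs,
  25 tandem sites per cofactor class, planted intergenically. Flanks
  are scrubbed of chance GGAA/TTCC within the isolation gap, and every
  element consumes a 400 bp exclusion margin so neighbouring planted
  peaks (centers +/- 250 bp plus fragment reach) cannot bleed into
  each other — per-element truth labels are only meaningful when the
  planted signals are spatially separable.
* **Nascent reads**: the expected sense count in a 50 bp bin at
  distance `d` kb from the TSS is
  `mu = depth * lambda * exp(-kappa d) * boost(d)`, with a 4x pause
  boost within the first 300 bp, signal extending 300 bp past the TES,
  negative-binomial replicate noise (`phi = 0.05`, variance
  `mu + phi mu^2`), 2% uniform background, and ~150k reads per
  replicate. Per-unit counts carry NB noise; compartment totals
  (background) are Poisson, as aggregates of many independent
  low-rate units.
* **Presets**: *lce* changes initiation only (induced targets
  `lambda x 2^-2`, repressed `x 2^+2`, kappa untouched); *hce* adds
  attrition genome-wide (`kappa + 0.1/kb`) with milder (+/- 1 log2)
  initiation effects; *null* leaves treated identical to control.
* **Fragments**: per element and replicate the expected count is
  `200 x occupancy`, NB-realized; midpoints are normal around the
  element center (sd 60 bp), lengths normal (200 +/- 50 bp, truncated
  below the 1000 bp filter); ~40k background fragments per replicate.
  Occupancy shifts are drawn as balanced +/- magnitude pairs
  (|delta log2| in [0.5, 2.5], one third of elements null) over
  elements matched on baseline occupancy, and the background absorbs
  the small residual, so the expected library total is equal across
  conditions and planted per-element shifts are identifiable from
  relative (CPM) data. True peaks are element centers +/- 250 bp.
* **DE table**: planted targets receive strong silencing fold changes
  with tiny adjusted p; unaffected genes get near-zero fold changes
  with adjusted p >= 0.02, so re-applying the thresholds recovers the
  labels exactly.
* **Replicates**: three per condition, matching the study design the
  generator emulates.

Everything is deterministic under the configured seed; re-running any
generator function with the same configuration yields byte-identical
output.

## What the simulation does and does not show

The generator reproduces the *structure* of the data — stranded
promoter-proximal enrichment with distance attrition, replicate
overdispersion, element-centered fragment pileups, background — but
not mappability artifacts, copy-number or GC biases, peak-calling
uncertainty (true peaks are emitted directly), overlapping
transcription units, or enhancer RNAs. Passing the planted-truth
checks therefore demonstrates correctness of the estimators under the
stated model, not robustness to every artifact of real libraries.

# Numerical choices

* Pseudocount `psi = 1` CPM in every log ratio (bounded at zero
  counts); bins of 50 bp for tracks and metagenes, 10 bp for
  element-centred profiles; metagene flanks 3 kb with the gene body
  resampled to 100 columns by length-weighted averaging (each body
  column's count is scaled to a per-50 bp equivalent so columns of
  different genomic width are comparable).
* Mechanism separation is judged on the OLS slope of the body-column
  mean profile: |slope| < 0.005 log2 units/column counts as flat
  (initiation-only), slope < -0.01 as attrition; with the default
  genes (~15 kb mean) an added 0.1/kb attrition predicts about
  -0.02/column, placing the two regimes an order of magnitude apart.
* The closed-form elongation validation uses 30 identical 10 kb genes
  at dispersion 0.01 and ~300k reads per replicate: the check compares
  an estimator to an analytic limit, so replicate dispersion is set
  low to expose estimator bias rather than sampling noise.
* The rank-sum test is exact (enumeration) for combined sample sizes
  up to 12 without ties and a tie- and continuity-corrected normal
  approximation otherwise; identical samples give p = 1.
* Degenerate inputs: genes of length <= 60 bp have an empty body and
  are excluded with a warning; bins clipped by a contig edge become
  missing values excluded from column means; a constant sample's
  correlation is missing; an all-zero control track cannot be used for
  group scaling and errors.
* Test problem sizes (200 x 10 kb oracle sequences, 300 elements,
  ~150k reads per replicate) were chosen so the full validation runs
  in minutes on a single core while keeping Monte-Carlo error well
  inside the asserted tolerances.

# Pipeline and interfaces

`runPipeline()` executes simulate -> motif scan -> target
classification -> differential binding -> nascent-transcription
quantitation -> per-element integration, logging one line per stage
and returning a report with per-stage record counts, FRiP, replicate
correlation minima, differential-peak counts, tertile boundaries and a
configuration hash (changes iff a tunable changes; output paths are
excluded). The master table has exactly one row per (element, class
label); missing joins are explicit `NA`s, never dropped rows. All
tabular outputs are TSV with headers, interval outputs BED6 (0-based
half-open, name = element class, score = 100 x unit count for
microsatellites), and re-running with an unchanged configuration
reproduces outputs byte-identically.

The package is driven from R; a thin command-line wrapper over the
exported functions ships in `inst/scripts/ctg.R` with subcommands
`simulate`, `motifs`, `targets`, `bind`, `gro` and `run` for shell
use.

# Known limitations

* Differential binding is a transparent location-test stand-in, not an
  affinity-model refit; spike-in normalization is out of scope.
* Nearest-TSS annotation ignores genic-feature hierarchies.
* Window counts may double-count reads across overlapping genes (each
  gene is quantified independently); within one gene the three windows
  are disjoint by construction.
* PWM log-odds scanning is not implemented; cofactor motifs are IUPAC
  consensi.
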