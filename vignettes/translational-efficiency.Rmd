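---
title: "Methods: offset calibration, A-site counting and the TE model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: offset calibration, A-site counting and the TE model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboage)
```

This vignette is the package's own account of its methods: the geometric and
statistical model each stage implements, the defaults and why they were
chosen, the numerical details, and what the synthetic generator does and
does not emulate.

## Coordinate conventions

All coordinates are 0-based half-open on the transcript. Metagene positions
are signed, with 0 at the first nucleotide of the start codon (or of the
stop codon for stop-anchored profiles). A read is the pair (5′-end
position, length); its A-site is `five_prime + offset(length)`, the first
nucleotide of the A-site codon.

## A-site offset calibration

An initiating ribosome holds the AUG in its P-site and codon 2 in its
A-site, i.e. the A-site is +3 nt from the start. Footprints accumulating on
initiating ribosomes therefore produce a sharp per-length 5′-end peak at
position `p* = 3 − offset` upstream of the start codon, and
`calibrate_offsets()` inverts this: `offset = 3 − p*`, with `p*` the argmax
of the per-length 5′-end histogram inside a search window.

Choices the data do not fix, made here once and exposed as arguments:

* **Search window** `[−18, −6]`: brackets every offset in the published
  yeast table (13–16 nt, peaks −10 to −13) with margin on both sides while
  excluding the CDS-internal background.
* **Tie rule**: equal counts go to the smaller `|p*|`, then the smaller
  `p*`. Ties essentially never occur at calibration depth (≥ 500 reads per
  length, the `min_reads` default); the rule exists so the operation is a
  function, not a coin flip.
* **Lengths without a calibrated or fixed offset are excluded** from all
  A-site analyses rather than guessed; the published table covers 21–22 and
  26–31 nt and is available as `standard_offsets()`.

## Counting rules

`count_cds()` counts a read for a gene when its A-site lies inside the CDS
and outside the first and last `exclude_codons = 5` codons — the edge
exclusion removes initiation/termination piles from abundance estimates. The
exclusion is applied to both assays; for RNA-Seq fragments a single fixed
15-nt offset stands in for the ribosome-geometry offsets (fragments have no
ribosome, the offset just moves the assignment point off the fragment end).
Every input read lands in exactly one sidecar category (`ncrna_filtered`,
`no_offset_length`, `outside_cds`, `edge_excluded`, `counted`), and this
partition is asserted exactly in the test suite — a read-accounting
invariant that catches coordinate bugs immediately.

Intron-containing reads are counted by ≥ 1 nt overlap with the intron
interval in half-open arithmetic (`mode = "overlap"`); a stricter
`mode = "contained"` (read fully inside the intron) is provided because
"containing the intron" admits both readings. Junction-flagged reads are
tallied separately as spliced evidence.

Repeat families are quantified on a consensus: `consensus_from_msa()` drops
columns with gap fraction > 0.5 and emits the modal non-gap base, ties to
the lexicographically smallest base, with `N` never beating a concrete
base. The aligner itself is out of scope — the alignment is an input.
`count_family()` partitions A-sites into ORF-A-only, ORF-B-only, the
ORF-overlap (excluded from both by default, mirroring the overlap-masking
practice for gag/pol-style overlapping ORFs) and outside.
`frame_in_window()` reports A-site frames relative to the ORF-A start, so a
programmed +1 frameshift appears as a switch from frame 0 to frame 1
downstream of the shift site.

## The TE model

Per gene, counts follow a negative binomial with variance `μ + αμ²` and

```
log μ_s = log sf_s + β0 + βa[ribo] + βc[treatment] + βi[ribo][treatment].
```

`βi/ln 2` is the TE log2 fold change. Multi-condition designs are analyzed
as separate two-condition contrasts against the reference (the first
condition), matching the always-compare-to-control structure of aging
time-point designs.

* **Size factors** are median-of-ratios, computed per assay by default:
  footprint and RNA libraries have unrelated depths, and a joint reference
  would let one assay's depth distort the other's factors. `scope =
  "joint"` is available.
* **Dispersion** is estimated by method of moments on normalized counts
  within each (assay, condition) cell, df-weighted across cells. With 2–3
  replicates the raw per-gene estimate has ~4–8 df and is so noisy that
  many genes draw a negative raw value; flooring those near zero and
  testing them as quasi-Poisson makes the Wald test badly anticonservative.
  The default therefore moderates the per-gene raw estimate toward the
  df-weighted pooled estimate across all genes with `prior_df = 25` pseudo
  degrees of freedom (the squeeze-toward-a-prior idea used throughout the
  count-model literature), flooring at `α_min = 1e−8` after moderation.
  `method = "per_gene"` gives the unmoderated per-cell-floored estimator
  for users who want it. This moderation is what makes the package's own
  type-I calibration test pass at the nominal level.
* **Fitting** is IRLS with the dispersion held fixed: working weights
  `μ/(1 + αμ)`, convergence when the relative deviance change is
  < 1e−8, at most 100 iterations, linear predictors clamped to ±30 to keep
  degenerate cells finite. Fits with any |β| > 20 are flagged
  non-converged and excluded from multiple testing. The IRLS solution is
  cross-checked in the tests against direct numerical maximization of the
  NB likelihood (agreement to 1e−4).
* **Testing** is a Wald z against the normal reference (no LRT, no
  fold-change shrinkage — thresholds apply to the raw MLE), BH-adjusted
  over tested genes. Genes below `min_mean_count = 5` normalized counts are
  excluded from testing and classified `low_count`, a simple
  independent-filtering stand-in.
* **Classification** is strict: `up` requires TE log2FC > 1, `down`
  < −1; a gene at exactly twofold is `unchanged`.

## What the generator emulates

`sim_config()` defaults describe a deep budding-yeast-style experiment:

* **Footprint lengths**: bimodal over the lengths with defined offsets,
  modes at 28 nt (A-site tRNA occupied) and 21 nt (empty A-site), masses
  0.15/0.07/0.08/0.25/0.28/0.09/0.05/0.03 over 21/22/26/27/28/29/30/31 nt.
  Lengths without a published offset are deliberately not emitted.
* **Digestion geometry**: 5′ ends are placed at `A-site − offset` using the
  published table as ground truth, so calibration has a known answer.
* **Initiation enrichment** `start_enrichment = 10` on codon 2, producing
  the −12 metagene peak for 28-nt footprints.
* **Frame noise**: with probability `1 − frame_fidelity` (default fidelity
  0.9) the A-site is perturbed by a shift drawn uniformly from
  {−1, 0, +1}. The expected frame-0 fraction is therefore
  `fidelity + (1 − fidelity)/3` (0.9 → 0.933), and the tests assert exactly
  this law. The uniform-over-three convention (rather than ±1 only) was
  chosen so that "fidelity 0.7 gives 80% frame-0" holds — the form in which
  periodicity is usually quoted.
* **Expression**: log-normal baselines (median 100 counts, log-sd 1),
  NB replicate noise with α = 0.05, condition effects as log2 shifts —
  transcription shifts drawn N(0, 0.5²), TE effects ±1.5 log2 on 3% / 6% of
  genes (up/down), bracketing the up/down asymmetry reported for aging
  cells at desk scale.
* **Intron gene**: RNA fragments drawn from a spliced/unspliced template
  mixture with per-condition unspliced fractions; spliced fragments
  crossing the junction are flagged. The intron is placed in the 3′ trailer
  (10 nt past the stop) rather than inside the CDS: this keeps CDS length a
  multiple of 3 without splice-aware CDS arithmetic, and intron placement
  only affects fragment counting — which is the quantity under test. Real
  intron geometry (e.g. an ORF-interrupting intron) is not emulated.
* **Element family**: indel-free point-mutant copies (default 4 copies,
  2% per-base substitutions) of one ancestor carrying two overlapping ORFs;
  ribosomes traverse ORF-A's frame to the shift site, then ORF-B's +1
  frame. Because copies are indel-free, the copy set is its own trivial
  alignment and the consensus stage can be tested without an aligner.
* **Determinism**: one base seed; every sample and stage derives its own
  substream seed from a fixed hash, so read streams are stable when
  replicate counts change.

Not emulated (and therefore not demonstrated by passing tests): sequencing
error, adapters, rRNA contamination, UMIs, multi-mapping ambiguity,
genome-space splicing alignment, codon-level pause structure, and the
empirical length-offset heterogeneity of real nuclease digests. Tests
passing on this generator show the analysis is correct under its stated
model, not that the model captures every property of real libraries.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen once: calibration experiments
use ~60,000 single-length footprints over 120 genes; the type-I simulation
uses 2,000 genes × 3 replicates; FDR control aggregates 20 seeded runs of
300 genes; effect recovery uses 25 replicates at median 500 counts, where
the Wald SE of the interaction (≈ `sqrt(4α/n)/ln 2` ≈ 0.13 log2 at
α = 0.05) brings the median absolute estimation error under 0.1 log2;
classification recovery plants 100 up + 100 down genes at 3.0-fold among
1,000 genes with 5 replicates, where the same power analysis predicts ~2%
misses at the twofold threshold — hence the ±5 tolerance. These replicate
and effect choices were fixed from that a priori analysis, not tuned.

## Known limitations

* The dispersion moderation shares one pooled prior across all genes; a
  mean-dispersion trend (as empirical-Bayes count frameworks fit) would be
  more faithful when dispersion varies with abundance.
* Wald tests with plug-in dispersions are approximate at very low counts;
  the `min_mean_count` filter bounds, but does not remove, this.
* The consensus caller assumes a flush alignment and does not model
  indels; family quantification assumes reads are already assigned to the
  family (multi-mapping resolution is out of the data model).
* `run_pipeline()` orchestrates single-machine runs only.
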