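---
title: "Methods: epihaplotype extraction and diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epihaplotype extraction and diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epihaplo)
```

## The problem

Targeted deep bisulfite sequencing reads out the methylation state of every
CpG of an amplified region on every sequenced molecule.  Treating each
molecule's binary CpG pattern — its *epihaplotype* — as the unit of
observation preserves information that per-site methylation percentages
destroy: two samples with identical site-wise averages can carry entirely
different molecular populations.  `epihaplo` extracts epihaplotypes from
per-sample FASTA files of merged, quality-filtered amplicon reads and then
treats the resulting sample-by-epihaplotype count table exactly as ecology
treats a community table: rarefaction, alpha diversity, Bray–Curtis beta
diversity, ordination.

The package is self-contained: alignment is an in-house exact
dynamic-programming aligner and all diversity statistics are implemented
from first principles, so no external aligner binary or metagenomics suite
is required.

## The extraction model

**Bisulfite chemistry.**  Bisulfite deaminates unmethylated cytosine to
uracil, read as T; methylated cytosine resists.  On the forward strand of a
PCR-amplified bisulfite template this yields the prediction encoded in
`bisulfite_convert()`: every non-CpG C of the reference is expected as T
(genomic non-CpG methylation is assumed negligible), while each CpG C is the
unknown being assayed.  A terminal C (last base) cannot precede a G and is
classified non-CpG.  Reverse-strand (G→A) libraries are out of scope; reads
sequenced in reverse orientation are reverse-complemented onto the forward
strand during demultiplexing.

**Demultiplexing** (`assign_read()`) scores both orientation hypotheses of
every read against every region: the relevant primer (or reverse-complement)
is aligned semi-globally, with unit edit costs and IUPAC-aware matching,
against a read-end window of primer length + 5 bases; the slack tolerates
small end truncations and insertions.  Similarity is
`(|primer| − d) / |primer|` for edit distance `d`.  Both ends must reach the
threshold (default 0.8); among passing hypotheses the highest summed
similarity wins, and a tie across regions (or orientations) leaves the read
unassigned rather than silently picking one.  Primers are not trimmed.
Length filtering keeps reads within ±50% (default) of the reference length,
boundaries inclusive.

**Alignment** (`align_read()`) is an exact affine-gap semi-global DP against
the bisulfite-converted reference: the read aligns end to end, reference
overhangs are free.  Default scores are BLASTN-like (+2/−3, gap open −5,
extend −2; a gap of length *k* costs `open + (k−1)·extend`).  Traceback
tie-breaks are fixed (diagonal over gap, gap-in-read over gap-in-reference),
so outputs are deterministic.  Reads scoring below `0.3 · match · length`
are discarded as alignment failures.  Since amplicon reads align
near-diagonally to their own few-hundred-bp reference, the exact DP costs a
few milliseconds per read and removes any dependence on an external
aligner's heuristics.

**Efficiency QC and profile calling.**  Per read, bisulfite efficiency is
`#T / (#T + #C)` over the reference's non-CpG C positions whose aligned read
base is C or T; positions showing A, G, a gap, or lying outside the aligned
span are excluded.  The *assayed fraction* divides the assayable positions
by **all** non-CpG C positions of the region, so poor coverage counts
against it.  Filtering order matters: the assayed-fraction check (default
minimum 0.66) runs first, because an efficiency estimated from too few
sites is invalid before it can be trusted; then reads below the efficiency
threshold (default 0.98, boundary passing) are discarded.  A region with no
non-CpG Cs offers no conversion QC, and the filter passes vacuously.
Profiles are then coded per CpG in reference order: C → 1 (methylated),
T → 0 (unmethylated), anything else → 2 (unassessable).

**Counting.**  Abundances are counted over the `2^NCpG` binary
epihaplotypes.  That space has no slot for the symbol 2, so passing reads
with an unassessable site are excluded from the abundance table (and
tallied separately); they remain visible, coded 2, in the profile-matrix
file.  Per-sample counts merge into one sparse profiles × samples table
whose rows sort by (methylation class, lexicographic profile) — the
methylation class, i.e. the number of methylated CpGs, is the first-level
grouping factor and is written into the BIOM taxonomy as
`["class_<n>", "<profile>"]`.

## Diversity analyses

All metrics are first-principles implementations; `vegan`, `ape` and
`stats::cmdscale`/`hclust` serve as independent cross-checks in the test
suite only.

* **Rarefaction** is multivariate-hypergeometric subsampling without
  replacement (`rarefy_counts()`), exact at the requested depth.
* **Alpha metrics**: observed profiles, singletons, Shannon entropy in
  bits (base-2 log), Simpson diversity `1 − Σ p²`, and bias-corrected
  Chao1 `S + F₁(F₁−1) / (2(F₂+1))`.  Base-2 Shannon, the `1 − D` Simpson
  variant and the bias-corrected Chao1 are the conventional defaults of
  community-ecology software; the choices are stated here because other
  variants circulate.
* **Rarefaction curves** use depths `"auto"`: 10 evenly spaced depths from
  10% to 100% of the minimum sample total, a grid that always ends exactly
  at the depth used for beta diversity.  Cells where a sample is smaller
  than the depth are absent, not zero.  Group curves show the mean of
  per-sample means with a `1.96·SE` normal-approximation half-width across
  the group's samples.
* **Beta diversity**: one seeded rarefaction of every sample to the
  minimum sample total, then pairwise Bray–Curtis
  `Σ|x−y| / Σ(x+y)`.
* **PCoA** is classical scaling: `B = −½·J·D∘D·J`, eigendecomposition,
  coordinates scaled by `√λ`.  Bray–Curtis matrices are generally
  non-Euclidean, so negative eigenvalues occur; they are reported as-is,
  their axes get zero coordinates, and proportion explained is computed
  over the positive eigenvalues only.  No Lingoes/Cailliez correction is
  applied.
* **UPGMA** (`upgma()`) is size-weighted average linkage with merge
  heights reported as ultrametric node heights (half the average
  inter-cluster distance).  Ties break on the smallest cluster-index pair
  and the leaf order puts the earlier-formed subtree on the left, making
  heatmap row orders reproducible.
* **Group distances** pool all within-group and all between-group pairs,
  plus per-group and per-pair details, feeding the distance boxplots.

## The synthetic-read generator

`synth_generate()` is a first-class module, not a test fixture: it encodes
the data-generating process the extraction model assumes, with ground-truth
bookkeeping (`SynthTruth`) so end-to-end recovery can be checked exactly.
Per read: an epihaplotype is drawn from the mixture; each non-CpG C
converts with probability `conversion_rate`; each unmethylated CpG converts
with the same probability — a failed conversion leaves a C, i.e. a
false-methylation event, which is precisely the artifact the efficiency
filter guards against; methylated CpGs always keep their C.  Substitutions
and single-base indels are applied uniformly over the insert; primers are
attached; a configurable fraction of reads is emitted reverse-complemented.
Identical spec and seed give byte-identical FASTA.

`example_region()` fixes the default study conditions: a 406-bp synthetic
promoter-like insert with 8 CpGs and a dense non-CpG C complement (~100
QC positions), flanked by adapter-tailed primers of a two-step indexing
design.  Those dimensions mirror a typical few-hundred-bp vertebrate
promoter amplicon on a desktop-scale MiSeq run.  Defaults elsewhere —
conversion 0.99, substitution 0.003/base, indel 5e-4/base, half the reads
reverse — are realistic for a well-behaved bisulfite MiSeq library.  What
the generator does *not* model: PCR duplicates and amplification bias,
chimeras, quality-score structure, reverse-strand (G→A) chemistry.
Pipeline guarantees demonstrated on synthetic data therefore speak to the
calling logic, not to artifacts upstream of it.

The two primer-adjacent terminal bases of the synthetic insert are forced
non-C.  This reflects a real estimator limitation, not cosmetics: an
unconverted C at the very first or last reference position sits in the
alignment's free-end zone, where skipping the position is cheaper than a
mismatch, so such positions silently drop out of the conversion assay.  For
real amplicons whose reference begins or ends with a cytosine the same
blind spot applies and the efficiency estimate carries a correspondingly
tiny upward bias.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed intervals internally and in all reports.
* Thresholds compare with `>=`: values at the boundary pass.
* Empty inputs produce complete, empty outputs (header-only tables), not
  errors; a sample with zero passing reads is visible in the attrition log.
* Beta diversity requires at least two samples with positive counts; with
  one sample the step is skipped with a message.
* Site percentages with a zero denominator are reported `NA`, never 0.
* All stochastic steps (rarefaction, generation) derive from the single
  configured seed; re-running a pipeline reproduces every data file byte
  for byte.  PDF plot files embed a creation timestamp in their metadata;
  their drawing content is deterministic.
* The BIOM writer emits version 1.0 JSON, sparse triples, fixed epoch
  date field (for reproducibility), and is paired with a validating reader;
  files are interoperable with standard BIOM tooling.

## Problem sizes used in validation

The shipped tests run the full pipeline on 6 synthetic samples in 2 groups
(120–300 reads per sample; 2,000 reads where a property is checked against
a 3-standard-error band), exercise the aligner against an independent
plain-R DP on the exhaustive grid of all sequence pairs up to length 8 over
a two-letter alphabet, and round-trip 200 random abundance tables through
BIOM.  These sizes were chosen so the whole suite completes in minutes on
one CPU while every stochastic check retains conventional statistical
power; the analyses themselves scale to MiSeq-size inputs (tens of
thousands of reads per sample) in minutes.

## Known limitations

* Forward-strand chemistry only; no CHH/CHG (non-CpG methylation) calling.
* No SNP-awareness: a genomic C/T polymorphism at a CpG masquerades as an
  unmethylated call.
* Uncertain (code 2) CpG states are excluded from abundance counting, not
  imputed; deep indel-rich data will lose reads accordingly.
* Bray–Curtis PCoA can place a large share of variance on negative
  eigenvalues for strongly non-Euclidean tables; inspect the reported
  eigenvalue spectrum before reading the 2D plots literally.
* The efficiency estimator's reference-edge blind spot described above.
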