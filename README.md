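# epihaplo

Epihaplotype extraction and diversity analysis for targeted deep bisulfite
amplicon sequencing.

## What it does, and for whom

Bisulfite PCR amplicon sequencing reads the methylation state of every CpG
of a target region on every sequenced DNA molecule.  Most methylation tools
collapse this to per-site percentages.  `epihaplo` is for experiments where
the *single-molecule* pattern matters: it calls, per read, the binary
methylation vector over all CpGs of the region — the **epihaplotype** — and
then analyzes the sample-by-epihaplotype count table with the statistical
machinery ecology uses for species-abundance tables, treating each distinct
methylation pattern as a taxonomic unit.  Typical users are groups studying
methylation heterogeneity in development or cancer who have per-sample
FASTA files of merged, quality-filtered amplicon reads and want molecule-
level profiles plus population-structure statistics without installing an
aligner binary or a metagenomics suite.

## The method in brief

For each read and target region:

1. **Demultiplex / orient**: the read's 5′ and 3′ ends are compared with
   the region's PCR primers by semi-global edit distance (IUPAC-aware);
   both ends must reach a similarity threshold (default 0.8), and
   reverse-oriented reads are reverse-complemented.  Length filter:
   within ±50% of the reference length.
2. **Align**: exact affine-gap semi-global alignment (match +2, mismatch
   −3, gap open −5, extend −2) to the *bisulfite-converted* reference, in
   which every non-CpG C is replaced by T.
3. **QC**: per-read bisulfite efficiency = #T / (#T + #C) over the
   reference's non-CpG cytosines (assumed unmethylated, hence fully
   convertible).  Reads are kept when at least 66% of those positions are
   assayable and efficiency ≥ 0.98 (defaults; boundaries pass).
4. **Call**: per CpG site, read base C → 1 (methylated), T → 0
   (unmethylated), gap/A/G → 2 (unassessable).  Profiles containing a 2
   are excluded from abundance counting (the 2^NCpG pattern space has no
   slot for them) but remain in the profile-matrix report.

Per-sample counts merge into a sparse profiles × samples table
(BIOM 1.0 JSON with the methylation class — number of methylated CpGs — as
taxonomy), which feeds:

* **alpha diversity** under rarefaction: observed profiles, singletons,
  Shannon entropy (bits), Simpson index 1 − Σp², bias-corrected Chao1
  S + F₁(F₁−1)/(2(F₂+1));
* **beta diversity**: single rarefaction to the minimum sample depth,
  pairwise Bray–Curtis Σ|x−y|/Σ(x+y), principal coordinates analysis,
  within/between-group distance summaries;
* reports and plots: summary statistics, class composition, a heatmap with
  UPGMA-ordered rows, rarefaction curves, 2D PCoA panels, distance
  boxplots.

A seedable synthetic-read generator (`synth_generate()`) emulates the whole
data-generating process — epihaplotype mixtures, stochastic bisulfite
conversion (including failed conversion of unmethylated CpGs), sequencing
substitutions and indels, primer flanks, mixed orientations — with
ground-truth bookkeeping, so the pipeline can be validated end to end.

## Worked example

Two simulated groups of two samples, dominated by disjoint epihaplotypes:

```r
library(epihaplo)
reg <- example_region()          # 406-bp synthetic promoter-like amplicon
cfg <- epihaplo_config(rng_seed = 42)

dir <- tempfile("demo_"); dir.create(dir)
mixes <- list(
  adult1 = c("11111111" = 0.7, "11110000" = 0.3),
  adult2 = c("11111111" = 0.6, "11110000" = 0.4),
  young1 = c("00000000" = 0.8, "00001111" = 0.2),
  young2 = c("00000000" = 0.7, "00001111" = 0.3))
fastas <- character(0)
for (s in names(mixes)) {
  sp <- synth_spec(reg, mixes[[s]], n_reads = 500,
                   seed = cfg$rng_seed + match(s, names(mixes)))
  fastas[s] <- file.path(dir, paste0(s, ".fasta"))
  write_synth_fasta(synth_generate(sp), fastas[s])
}
groups <- c(adult1 = "adult", adult2 = "adult",
            young1 = "young", young2 = "young")

res <- run_pipeline(fastas, list(reg), cfg, groups,
                    out_dir = file.path(dir, "out"))
summary(res$tables$synthetic_region)
```

```
Num samples: 4
Num observations: 27
Total count: 1709
Table density (fraction of non-zero values): 0.3796

Counts/sample summary:
 Min: 416
 Max: 437
 Median: 428
 Mean: 427.25
 Std. dev.: 8.95824
```

Of the 500 reads per sample, ~430 are counted; the attrition log shows the
rest failed the 98% efficiency filter (the generator's conversion rate is
0.99, so a minority of reads carry ≥2 unconverted cytosines) or contained
an unassessable CpG.  The group structure is recovered cleanly:

```r
res$eha$synthetic_region$beta$pcoa
gs <- res$eha$synthetic_region$beta$group_summary
c(within = mean(gs$within), between = mean(gs$between))
```

```
PCoA of 4 samples; first 3 eigenvalues: 0.990857, 0.017130, 0.001156
proportion explained: 0.98188, 0.01698, 0.00115
 within between
  0.117   1.000
```

Within-group Bray–Curtis distances average 0.117; between-group distances
average 1.000 (the dominant epihaplotypes are disjoint), and the first PCoA
axis carrying 98% of the variation separates the groups.  The output
directory contains, per region: demultiplexed FASTA, plain-text alignments,
the 0/1/2 profile matrix, summary/quality statistics, tabular and BIOM
abundances, and the `eha/` report folder (summary, class composition,
heatmap, `Alpha/`, `Beta/` with `bray_curtis_dm.txt` and
`bray_curtis_pc.txt`).

A command-line wrapper with the same defaults ships in `exec/epihaplo`
(subcommands `extract`, `merge`, `eha`, `simulate`, `run-all`).

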