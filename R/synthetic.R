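# Synthetic bisulfite amplicon reads from a known epihaplotype mixture,
# with ground-truth bookkeeping.  This is the validation oracle for the
# whole pipeline: chemistry, demultiplexing, alignment and calling can all
# be checked against what the generator actually did.

#' A deterministic example target region
#'
#' A 406-bp synthetic promoter-like amplicon with 8 CpG sites and a dense
#' complement of non-CpG cytosines (~18% of bases are C), flanked by
#' adapter-tailed PCR primers typical of a two-step indexing design.  The
#' sequence is generated from a fixed internal seed, so the region is
#' identical across sessions; it emulates the *structure* of a real
#' few-hundred-bp promoter amplicon, not any particular genomic locus.
#'
#' @param n_cpg Number of CpG sites to embed (default 8).
#' @param length Amplicon insert length (default 406).
#' @return A [region()].
#' @export
example_region <- function(n_cpg = 8L, length = 406L) {
  stopifnot(length >= 10L * n_cpg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20160001L)
  # backbone without C or G runs that would create accidental CpGs
  chars <- sample(c("A", "C", "T", "G"), length, replace = TRUE,
                  prob = c(0.3, 0.25, 0.3, 0.15))
  # remove accidental CpGs, then place n_cpg evenly spaced CpG dinucleotides
  for (i in seq_len(length - 1L))
    if (chars[i] == "C" && chars[i + 1L] == "G") chars[i + 1L] <- "A"
  at <- as.integer(round(seq(20, length - 20, length.out = n_cpg)))
  for (p in at) { chars[p] <- "C"; chars[p + 1L] <- "G" }
  # re-scrub accidental CpGs introduced next to the placed ones
  for (i in seq_len(length - 1L))
    if (chars[i] == "C" && chars[i + 1L] == "G" && !(i %in% at))
      chars[i + 1L] <- "A"
  # primer-adjacent terminal bases are non-C: a C at the very edge of the
  # insert sits in the alignment's free-end zone and would escape the
  # conversion assay
  chars[1L] <- "A"; chars[length] <- "T"
  region("synthetic_region",
         fw_primer = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
         rv_primer = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG",
         ref_seq = paste(chars, collapse = ""))
}

#' Specification for a synthetic-read experiment
#'
#' @param reg A [region()].
#' @param mixture Named numeric vector: epihaplotype string (length =
#'   number of CpGs of `reg`) -> proportion; proportions must sum to 1.
#' @param n_reads Number of reads to generate.
#' @param conversion_rate Probability `c` that an unmethylated cytosine
#'   (non-CpG, or unmethylated CpG) is converted to T; failed conversion of
#'   an unmethylated CpG leaves a C, i.e. a false-methylation event.
#' @param substitution_rate Per-base sequencing substitution probability.
#' @param indel_rate Per-base single-base insertion/deletion probability.
#' @param reverse_fraction Fraction of reads emitted reverse-complemented.
#' @param seed Integer seed; all randomness derives from it.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(reg, mixture, n_reads = 2000L,
                       conversion_rate = 0.99, substitution_rate = 0.003,
                       indel_rate = 5e-4, reverse_fraction = 0.5,
                       seed = 1L) {
  ncpg <- length(reg$cpg_positions)
  if (any(nchar(names(mixture)) != ncpg))
    stop(sprintf("mixture epihaplotypes must have length %d", ncpg))
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture proportions must sum to 1")
  structure(list(reg = reg, mixture = mixture, n_reads = as.integer(n_reads),
                 conversion_rate = conversion_rate,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 reverse_fraction = reverse_fraction,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate synthetic bisulfite amplicon reads with ground truth
#'
#' Per read: an epihaplotype is drawn from the mixture; starting from the
#' genomic reference, every non-CpG C converts to T with probability
#' `conversion_rate`, every CpG keeps its C if methylated and otherwise
#' converts with the same probability; sequencing substitutions and
#' single-base indels are applied uniformly over the converted insert; the
#' forward primer is prepended and the reverse complement of the reverse
#' primer appended; finally a `reverse_fraction` of reads is emitted
#' reverse-complemented.  Identical spec and seed give byte-identical
#' output.
#'
#' @param spec A [synth_spec()].
#' @return List of class `synth_result`: `reads` (named character vector),
#'   `truth` (list: `counts` — realized reads per epihaplotype — and
#'   `per_read` data.frame with the source epihaplotype, the number of
#'   unconverted non-CpG Cs and of failed-conversion unmethylated CpGs,
#'   and the emitted orientation).
#' @export
synth_generate <- function(spec) {
  reg <- spec$reg
  set.seed(spec$seed)
  haps <- names(spec$mixture)
  ref_chars <- strsplit(reg$ref_seq, "", fixed = TRUE)[[1]]
  cpg <- reg$cpg_positions
  noncpg <- reg$noncpg_c_positions
  hap_mats <- lapply(haps, function(h)
    as.integer(strsplit(h, "", fixed = TRUE)[[1]]))
  names(hap_mats) <- haps
  n <- spec$n_reads
  draw <- sample(haps, n, replace = TRUE, prob = spec$mixture)
  is_rev <- stats::runif(n) < spec$reverse_fraction
  reads <- character(n)
  n_uncv <- integer(n); n_failed_cpg <- integer(n)
  rc_rv <- revcomp(reg$rv_primer)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    chars <- ref_chars
    conv_ok <- stats::runif(length(noncpg)) < spec$conversion_rate
    chars[noncpg[conv_ok]] <- "T"
    n_uncv[i] <- sum(!conv_ok)
    hap <- hap_mats[[draw[i]]]
    unmeth <- cpg[hap == 0L]
    cpg_ok <- stats::runif(length(unmeth)) < spec$conversion_rate
    chars[unmeth[cpg_ok]] <- "T"
    n_failed_cpg[i] <- sum(!cpg_ok)
    # sequencing noise on the insert
    if (spec$substitution_rate > 0) {
      hit <- which(stats::runif(length(chars)) < spec$substitution_rate)
      for (p in hit)
        chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    if (spec$indel_rate > 0) {
      hit <- which(stats::runif(length(chars)) < spec$indel_rate)
      for (p in rev(hit)) {
        if (stats::runif(1) < 0.5) {
          chars <- chars[-p]                       # deletion
        } else {
          chars <- append(chars, sample(bases, 1L), after = p)  # insertion
        }
      }
    }
    seq <- paste0(reg$fw_primer, paste(chars, collapse = ""), rc_rv)
    if (is_rev[i]) seq <- revcomp(seq)
    reads[i] <- seq
  }
  names(reads) <- sprintf("synth_%06d", seq_len(n))
  counts <- vapply(haps, function(h) sum(draw == h), integer(1))
  structure(list(
    reads = reads,
    truth = list(counts = counts,
                 per_read = data.frame(
                   read_id = names(reads), epihaplotype = draw,
                   n_unconverted_noncpg = n_uncv,
                   n_failed_conversion_cpg = n_failed_cpg,
                   orientation = ifelse(is_rev, "reverse", "forward"),
                   stringsAsFactors = FALSE))),
    class = "synth_result")
}

#' Write synthetic reads as FASTA plus a truth table
#'
#' @param sr A `synth_result` from [synth_generate()].
#' @param fasta_path Output FASTA path.
#' @param truth_path Optional output TSV path for the per-read truth.
#' @return `fasta_path`, invisibly.
#' @export
write_synth_fasta <- function(sr, fasta_path, truth_path = NULL) {
  x <- Biostrings::DNAStringSet(sr$reads)
  Biostrings::writeXStringSet(x, filepath = fasta_path, width = 80L)
  if (!is.null(truth_path))
    write.table(sr$truth$per_read, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fasta_path)
}
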