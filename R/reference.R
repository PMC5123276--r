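# Target-region model: genomic reference, in-silico bisulfite conversion,
# CpG / non-CpG cytosine indices.  All coordinates are 1-based.

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

#' Reverse-complement a DNA string
#'
#' IUPAC ambiguity codes are complemented to their partner codes.
#'
#' @param seq A single DNA string (uppercase).
#' @return The reverse complement as a character scalar.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' In-silico bisulfite conversion of a reference sequence
#'
#' Models full conversion of the top strand: every cytosine that is not
#' followed by a guanine (non-CpG C, assumed unmethylated in the genome)
#' deaminates to thymine, while CpG cytosines are left in place because their
#' methylation state is the unknown being assayed.  A cytosine at the last
#' position cannot precede a G and is classified non-CpG.
#'
#' @param ref_seq Genomic reference sequence, uppercase A/C/G/T only.
#' @return A list with `bis_ref` (converted sequence), `cpg_positions` and
#'   `noncpg_c_positions` (1-based offsets of the C of each CpG dinucleotide
#'   and of every other C, respectively).
#' @examples
#' bisulfite_convert("CCGG")  # first C is non-CpG -> T; second is CpG -> kept
#' @export
bisulfite_convert <- function(ref_seq) {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L)
  if (nchar(ref_seq) == 0L) stop("reference sequence is empty")
  bad <- regexpr("[^ACGT]", ref_seq)
  if (bad > 0L)
    stop(sprintf("non-ACGT character '%s' in reference at position %d",
                 substr(ref_seq, bad, bad), bad))
  chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_c <- chars == "C"
  next_g <- c(chars[-1] == "G", FALSE)
  cpg <- which(is_c & next_g)
  noncpg <- which(is_c & !next_g)
  bis <- chars
  bis[noncpg] <- "T"
  list(bis_ref = paste(bis, collapse = ""),
       cpg_positions = cpg,
       noncpg_c_positions = noncpg)
}

#' Construct a target-region object
#'
#' A `region` bundles everything downstream stages need about one amplicon:
#' its PCR primers, its genomic reference, the derived bisulfite-converted
#' reference, and the index of CpG and non-CpG cytosine positions.
#'
#' @param region_id Region identifier.
#' @param fw_primer,rv_primer Forward and reverse PCR primer sequences
#'   (uppercase; IUPAC ambiguity codes allowed).
#' @param ref_seq Genomic reference sequence of the amplified region
#'   (uppercase A/C/G/T only; no ambiguity codes).
#' @return An object of class `region`.
#' @examples
#' r <- region("r1", "ACGTACGT", "TTGGCCAA", "ACCGTTCGA")
#' r$cpg_positions
#' @export
region <- function(region_id, fw_primer, rv_primer, ref_seq) {
  stopifnot(is.character(region_id), length(region_id) == 1L, nzchar(region_id))
  for (p in list(fw = fw_primer, rv = rv_primer)) {
    if (!is.character(p) || length(p) != 1L || !nzchar(p))
      stop("primers must be non-empty DNA strings")
  }
  if (grepl(sprintf("[^%s]", IUPAC_CHARS), fw_primer) ||
      grepl(sprintf("[^%s]", IUPAC_CHARS), rv_primer))
    stop("primers may contain only IUPAC nucleotide codes")
  conv <- bisulfite_convert(ref_seq)
  structure(list(region_id = region_id,
                 fw_primer = fw_primer,
                 rv_primer = rv_primer,
                 ref_seq = ref_seq,
                 bis_ref = conv$bis_ref,
                 cpg_positions = conv$cpg_positions,
                 noncpg_c_positions = conv$noncpg_c_positions),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region '%s': %d bp reference, %d CpG sites, %d non-CpG Cs\n",
              x$region_id, nchar(x$ref_seq), length(x$cpg_positions),
              length(x$noncpg_c_positions)))
  invisible(x)
}

#' Load target regions from a CSV description and a reference FASTA
#'
#' The CSV must have a header `id,fw_primer,rv_primer`; the FASTA must carry
#' one record per region, keyed by the same identifier (first whitespace-
#' delimited token of the header line).
#'
#' @param regions_csv Path to the comma-separated region description file.
#' @param references_fasta Path to the FASTA file of untreated genomic
#'   reference sequences.
#' @return A named list of [region()] objects, in CSV order.
#' @export
load_regions <- function(regions_csv, references_fasta) {
  df <- read.csv(regions_csv, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("id", "fw_primer", "rv_primer")
  if (!all(need %in% names(df)))
    stop("regions CSV must have header 'id,fw_primer,rv_primer'")
  if (nrow(df) == 0L) stop("regions CSV contains no regions")
  if (anyDuplicated(df$id))
    stop(sprintf("duplicate region_id '%s' in regions CSV",
                 df$id[duplicated(df$id)][1]))
  refs <- Biostrings::readDNAStringSet(references_fasta)
  names(refs) <- sub("\\s.*$", "", names(refs))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    id <- df$id[i]
    if (!id %in% names(refs))
      stop(sprintf("no reference sequence for region '%s' in %s",
                   id, references_fasta))
    out[[i]] <- region(id, toupper(df$fw_primer[i]), toupper(df$rv_primer[i]),
                       toupper(as.character(refs[[id]])))
  }
  names(out) <- df$id
  out
}
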