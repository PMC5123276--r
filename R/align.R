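# Read-to-reference alignment against the bisulfite-converted reference.

#' Align a read to a bisulfite-converted reference
#'
#' Exact semi-global alignment with affine gap penalties: the read is
#' aligned end to end while reference overhangs on either side are free, so
#' the read maps onto the best-scoring stretch of the reference.  Scoring is
#' taken from the configuration (`align_match`, `align_mismatch`,
#' `align_gap_open`, `align_gap_extend`); a gap of length `k` costs
#' `gap_open + (k-1) * gap_extend`.  Ties are broken deterministically
#' (diagonal move preferred over a gap, gap-in-read over gap-in-reference).
#'
#' Reads scoring below `0.3 * align_match * nchar(seq)` are flagged as
#' alignment failures (`ok = FALSE`); such chimeric or off-target reads
#' would otherwise produce nonsense methylation profiles.
#'
#' @param seq Read sequence (forward-oriented DNA string).
#' @param bis_ref Bisulfite-converted reference string.
#' @param cfg An [epihaplo_config()].
#' @param read_id Identifier stored in the result.
#' @return An object of class `bis_alignment`: list with `read_id`,
#'   `aln_read`, `aln_ref` (equal-length gapped strings over `A,C,G,T,-`),
#'   `ref_start`, `ref_end` (1-based inclusive reference span), `score` and
#'   `ok`.
#' @examples
#' cfg <- epihaplo_config()
#' align_read("TTCGT", "TTCGT", cfg)$score  # 10: five matches at +2
#' @export
align_read <- function(seq, bis_ref, cfg = epihaplo_config(), read_id = "read") {
  stopifnot(nzchar(seq), nzchar(bis_ref))
  a <- .align_semiglobal_cpp(seq, bis_ref,
                             cfg$align_match, cfg$align_mismatch,
                             cfg$align_gap_open, cfg$align_gap_extend)
  a$read_id <- read_id
  a$ok <- a$score >= cfg$align_match * 0.3 * nchar(seq)
  class(a) <- "bis_alignment"
  a
}

#' @export
print.bis_alignment <- function(x, ...) {
  cat(sprintf("alignment of '%s': score %d, reference span %d-%d%s\n",
              x$read_id, x$score, x$ref_start, x$ref_end,
              if (x$ok) "" else " (failed low-score guard)"))
  invisible(x)
}

# '|' where aligned characters are equal, ' ' elsewhere
.match_line <- function(aln_read, aln_ref) {
  a <- strsplit(aln_read, "", fixed = TRUE)[[1]]
  b <- strsplit(aln_ref, "", fixed = TRUE)[[1]]
  paste(ifelse(a == b & a != "-", "|", " "), collapse = "")
}

#' Write a plain-text alignment report
#'
#' One five-row entry per passing read: (1) read id, length, sample and
#' region; (2) the per-read bisulfite efficiency as a percentage; (3) the
#' gapped read; (4) a match line; (5) the gapped bisulfite-converted
#' reference.
#'
#' @param alignments List of `bis_alignment` objects.
#' @param efficiencies Numeric vector of per-read bisulfite efficiencies
#'   (fractions), parallel to `alignments`.
#' @param sample_id,region_id Annotation values.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignment_report <- function(alignments, efficiencies,
                                   sample_id, region_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    read_len <- nchar(gsub("-", "", a$aln_read, fixed = TRUE))
    writeLines(c(
      sprintf("%s %d %s %s", a$read_id, read_len, sample_id, region_id),
      sprintf("bisulfite_efficiency=%.2f",
              if (is.na(efficiencies[i])) NA_real_ else 100 * efficiencies[i]),
      a$aln_read,
      .match_line(a$aln_read, a$aln_ref),
      a$aln_ref), con)
  }
  invisible(path)
}
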