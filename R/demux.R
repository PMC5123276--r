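# Demultiplexing: assign each read to a region by primer matching at both
# ends, orient it to the forward strand, and apply the length filter.

# extra bases searched beyond the primer length at each read end, to
# tolerate small 5' truncations or insertions
PRIMER_WINDOW_SLACK <- 5L

#' Similarity between a read end and a PCR primer
#'
#' Semi-global similarity: the primer is aligned end to end against the best
#' matching substring of the window (window ends free), under unit edit
#' costs.  IUPAC ambiguity codes in the primer match any base of their
#' expansion set at zero cost.  The similarity is
#' `(len(primer) - d) / len(primer)` clipped below at zero, where `d` is the
#' minimum edit distance.
#'
#' @param window The read-end window searched (DNA string).
#' @param primer The primer sequence (DNA string, IUPAC codes allowed).
#' @return A fraction in `[0, 1]`.
#' @examples
#' primer_similarity("ACGTAAAA", "ACGT")  # 1
#' primer_similarity("ACGAAAAA", "ACGT")  # 0.75
#' @export
primer_similarity <- function(window, primer) {
  stopifnot(is.character(window), length(window) == 1L,
            is.character(primer), length(primer) == 1L)
  if (!nzchar(primer)) stop("primer must be non-empty")
  if (!nzchar(window)) return(0)
  d <- .primer_edit_distance_cpp(window, primer)
  max(0, (nchar(primer) - d) / nchar(primer))
}

# score both orientation hypotheses of one read against one region;
# returns list(orientation, sim5, sim3) of parallel vectors
.score_region <- function(seq, reg) {
  n <- nchar(seq)
  w5 <- function(p) substr(seq, 1L, min(n, nchar(p) + PRIMER_WINDOW_SLACK))
  w3 <- function(p) substr(seq, max(1L, n - nchar(p) - PRIMER_WINDOW_SLACK + 1L), n)
  rc_rv <- revcomp(reg$rv_primer)
  rc_fw <- revcomp(reg$fw_primer)
  list(
    orientation = c("forward", "reverse"),
    sim5 = c(primer_similarity(w5(reg$fw_primer), reg$fw_primer),
             primer_similarity(w5(reg$rv_primer), reg$rv_primer)),
    sim3 = c(primer_similarity(w3(rc_rv), rc_rv),
             primer_similarity(w3(rc_fw), rc_fw)))
}

#' Assign a read to a region by primer matching
#'
#' For every region two orientation hypotheses are scored: *forward*
#' (forward primer against the 5' window, reverse complement of the reverse
#' primer against the 3' window) and *reverse* (the mirror image).  A
#' hypothesis passes when both end similarities reach
#' `cfg$primer_similarity_min`; the read is assigned to the passing
#' hypothesis with the highest summed similarity.  A tie for the best sum
#' leaves the read unassigned (ambiguous demultiplexing is treated as
#' failure).  Reads assigned in reverse orientation are stored
#' reverse-complemented so that all downstream work is on the forward
#' strand.
#'
#' @param read_id,seq Identifier and sequence of the read.
#' @param regions A list of [region()] objects.
#' @param cfg An [epihaplo_config()].
#' @return A list with `read_id`, `seq` (oriented), `assigned_region` (id or
#'   `NA`), `orientation` (`"forward"`, `"reverse"` or `NA`) and
#'   `fail_reason` (`"none"` or `"no_primer_match"`).
#' @export
assign_read <- function(read_id, seq, regions, cfg = epihaplo_config()) {
  stopifnot(length(regions) >= 1L)
  best <- NULL; best_sum <- -Inf; tie <- FALSE
  for (reg in regions) {
    sc <- .score_region(seq, reg)
    ok <- sc$sim5 >= cfg$primer_similarity_min &
          sc$sim3 >= cfg$primer_similarity_min
    if (!any(ok)) next
    sums <- (sc$sim5 + sc$sim3)[ok]
    orient <- sc$orientation[ok]
    i <- which.max(sums)
    if (sum(sums == sums[i]) > 1L) { # forward/reverse tie within one region
      if (sums[i] >= best_sum) { tie <- TRUE; best_sum <- max(best_sum, sums[i]) }
      next
    }
    if (sums[i] > best_sum) {
      best_sum <- sums[i]; tie <- FALSE
      best <- list(region_id = reg$region_id, orientation = orient[i])
    } else if (sums[i] == best_sum) {
      tie <- TRUE
    }
  }
  if (is.null(best) || tie)
    return(list(read_id = read_id, seq = seq, assigned_region = NA_character_,
                orientation = NA_character_, fail_reason = "no_primer_match"))
  oriented <- if (best$orientation == "reverse") revcomp(seq) else seq
  list(read_id = read_id, seq = oriented, assigned_region = best$region_id,
       orientation = best$orientation, fail_reason = "none")
}

#' Length filter for an assigned read
#'
#' A read passes when its length lies in
#' `[ceil((1-t)L), floor((1+t)L)]` where `L` is the reference length and `t`
#' the configured tolerance; both boundaries are inclusive.
#'
#' @param seq Read sequence (oriented).
#' @param reg The assigned [region()].
#' @param cfg An [epihaplo_config()].
#' @return `TRUE` if the read passes, else `FALSE`.
#' @export
length_filter <- function(seq, reg, cfg = epihaplo_config()) {
  L <- nchar(reg$ref_seq)
  t <- cfg$length_tolerance
  n <- nchar(seq)
  n >= ceiling((1 - t) * L) && n <= floor((1 + t) * L)
}

#' Demultiplex one sample's reads across the target regions
#'
#' Applies [assign_read()] and [length_filter()] to every read and returns
#' the per-region passing reads along with a per-read outcome log.  The
#' outcomes partition the input: every read ends as exactly one of
#' `passed`, `no_primer_match` or `length_out_of_range`.
#'
#' @param reads Named character vector of read sequences (names = read ids).
#' @param regions List of [region()] objects.
#' @param cfg An [epihaplo_config()].
#' @param sample_id Sample identifier recorded in the log and FASTA headers.
#' @return A list with `by_region` (named list of named character vectors of
#'   oriented passing reads) and `log` (data.frame: read_id, sample_id,
#'   region, orientation, outcome).
#' @export
demultiplex_reads <- function(reads, regions, cfg = epihaplo_config(),
                              sample_id = "sample") {
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  names(regions) <- vapply(regions, `[[`, "", "region_id")
  out_region <- character(n); out_orient <- character(n)
  outcome <- character(n); oriented <- character(n)
  for (i in seq_len(n)) {
    a <- assign_read(ids[i], reads[[i]], regions, cfg)
    if (a$fail_reason == "no_primer_match") {
      outcome[i] <- "no_primer_match"
      out_region[i] <- NA_character_; out_orient[i] <- NA_character_
      oriented[i] <- reads[[i]]
    } else {
      reg <- regions[[a$assigned_region]]
      out_region[i] <- a$assigned_region
      out_orient[i] <- a$orientation
      oriented[i] <- a$seq
      outcome[i] <- if (length_filter(a$seq, reg, cfg)) "passed"
                    else "length_out_of_range"
    }
  }
  by_region <- lapply(regions, function(reg) {
    keep <- which(outcome == "passed" & out_region == reg$region_id)
    structure(oriented[keep], names = ids[keep])
  })
  names(by_region) <- vapply(regions, `[[`, "", "region_id")
  list(by_region = by_region,
       log = data.frame(read_id = ids, sample_id = rep(sample_id, n),
                        region = out_region, orientation = out_orient,
                        outcome = outcome, stringsAsFactors = FALSE))
}

#' Write demultiplexed reads as an annotated FASTA
#'
#' Headers carry the read id, sample and region as
#' `readid;sample=S;region=R`.
#'
#' @param reads Named character vector of oriented passing reads.
#' @param sample_id,region_id Annotation values.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_demux_fasta <- function(reads, sample_id, region_id, path) {
  if (length(reads) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  headers <- sprintf("%s;sample=%s;region=%s", names(reads), sample_id, region_id)
  x <- Biostrings::DNAStringSet(unname(unlist(reads)))
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

# read a FASTA file into a named character vector; empty file -> empty vector
read_fasta_seqs <- function(path) {
  if (file.size(path) == 0L) return(structure(character(0), names = character(0)))
  x <- Biostrings::readDNAStringSet(path)
  structure(toupper(as.character(x)), names = sub("\\s.*$", "", names(x)))
}
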