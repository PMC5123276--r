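# Interpretation of alignments: per-read bisulfite efficiency, quality
# filtering, ternary CpG profile calling, per-site statistics.

# For each reference position in [ref_start, ref_end], the read character
# aligned to it ('-' where the read has a gap), as a plain vector indexed
# by (position - ref_start + 1).  Reference gap columns (insertions in the
# read) do not consume a reference position.
.read_base_by_ref_pos <- function(aln) {
  rr <- strsplit(aln$aln_read, "", fixed = TRUE)[[1]]
  rf <- strsplit(aln$aln_ref, "", fixed = TRUE)[[1]]
  rr[rf != "-"]
}

#' Per-read bisulfite conversion efficiency
#'
#' The bisulfite efficiency of a read is the fraction of its assayable
#' non-CpG cytosine positions read as T: non-CpG Cs are assumed
#' unmethylated in the genome, so any remaining C marks a failed chemical
#' conversion.  A non-CpG C position is *assayable* when the aligned read
#' base is C or T; positions showing A, G, a gap, or lying outside the
#' aligned reference span are excluded.  The assayed fraction is taken over
#' *all* non-CpG C positions of the region, so poor reference coverage
#' lowers it.
#'
#' @param aln A `bis_alignment` from [align_read()].
#' @param reg The [region()] the read was aligned to.
#' @return List with `bis_efficiency` (fraction, `NA` when no position was
#'   assayable) and `assayed_fraction`.
#' @export
compute_efficiency <- function(aln, reg) {
  total <- length(reg$noncpg_c_positions)
  if (total == 0L)
    return(list(bis_efficiency = NA_real_, assayed_fraction = NA_real_))
  bases <- .read_base_by_ref_pos(aln)
  covered <- reg$noncpg_c_positions[reg$noncpg_c_positions >= aln$ref_start &
                                    reg$noncpg_c_positions <= aln$ref_end]
  b <- bases[covered - aln$ref_start + 1L]
  n_t <- sum(b == "T"); n_c <- sum(b == "C")
  assayable <- n_t + n_c
  list(bis_efficiency = if (assayable > 0L) n_t / assayable else NA_real_,
       assayed_fraction = assayable / total)
}

#' Quality filter on the efficiency estimate
#'
#' The assayed-fraction check runs first: an efficiency estimated from too
#' few sites is invalid before it can be compared with its threshold.  Both
#' comparisons pass at the boundary (`>=`).
#'
#' @param bis_efficiency Fraction or `NA`.
#' @param assayed_fraction Fraction.
#' @param cfg An [epihaplo_config()].
#' @return List with `pass` (logical) and `fail_reason` (`"none"`,
#'   `"low_assayed_fraction"` or `"low_efficiency"`).  When
#'   `assayed_fraction` is `NA` (the region has no non-CpG cytosines at
#'   all) the filter passes vacuously.
#' @export
filter_call <- function(bis_efficiency, assayed_fraction,
                        cfg = epihaplo_config()) {
  # a region with no non-CpG Cs offers no conversion QC at all: vacuous pass
  if (is.na(assayed_fraction))
    return(list(pass = TRUE, fail_reason = "none"))
  if (is.na(bis_efficiency) || assayed_fraction < cfg$assayed_fraction_min)
    return(list(pass = FALSE, fail_reason = "low_assayed_fraction"))
  if (bis_efficiency < cfg$bis_efficiency_min)
    return(list(pass = FALSE, fail_reason = "low_efficiency"))
  list(pass = TRUE, fail_reason = "none")
}

#' Call the ternary CpG methylation profile of an aligned read
#'
#' One symbol per CpG site of the region, in reference order: a C read at
#' the site means the cytosine resisted conversion and is called methylated
#' (1); a T means it converted and is called unmethylated (0); a gap, A or
#' G, or a site outside the aligned span leaves the state unassessable (2).
#'
#' @param aln A `bis_alignment`.
#' @param reg The [region()].
#' @return Integer vector over `{0,1,2}` of length `length(reg$cpg_positions)`.
#' @export
call_profile <- function(aln, reg) {
  bases <- .read_base_by_ref_pos(aln)
  p <- reg$cpg_positions
  out <- rep(2L, length(p))
  inr <- p >= aln$ref_start & p <= aln$ref_end
  b <- bases[p[inr] - aln$ref_start + 1L]
  out[inr] <- ifelse(b == "C", 1L, ifelse(b == "T", 0L, 2L))
  out
}

#' Process one sample-region batch of demultiplexed reads
#'
#' Aligns every read, estimates its bisulfite efficiency, applies the
#' quality filters and calls its CpG profile.  The outcome of every read is
#' logged; outcomes partition the input into `counted`,
#' `ambiguous_profile` (passing but containing an unassessable site),
#' `align_failed`, `low_assayed_fraction` and `low_efficiency`.
#'
#' @param reads Named character vector of oriented reads.
#' @param reg The [region()].
#' @param cfg An [epihaplo_config()].
#' @return List of class `profile_calls`: `calls` (list per read: read_id,
#'   profile, bis_efficiency, assayed_fraction, pass, fail_reason),
#'   `alignments` (for passing reads, in input order), `efficiencies`
#'   (parallel to `alignments`), and `log` (data.frame read_id, outcome).
#' @export
call_reads <- function(reads, reg, cfg = epihaplo_config()) {
  ids <- names(reads)
  calls <- vector("list", length(reads))
  alns <- list(); effs <- numeric(0)
  outcome <- character(length(reads))
  for (i in seq_along(reads)) {
    a <- align_read(reads[[i]], reg$bis_ref, cfg, read_id = ids[i])
    if (!a$ok) {
      calls[[i]] <- list(read_id = ids[i], profile = NULL,
                         bis_efficiency = NA_real_, assayed_fraction = 0,
                         pass = FALSE, fail_reason = "align_failed")
      outcome[i] <- "align_failed"
      next
    }
    e <- compute_efficiency(a, reg)
    f <- filter_call(e$bis_efficiency, e$assayed_fraction, cfg)
    prof <- if (f$pass) call_profile(a, reg) else NULL
    calls[[i]] <- list(read_id = ids[i], profile = prof,
                       bis_efficiency = e$bis_efficiency,
                       assayed_fraction = e$assayed_fraction,
                       pass = f$pass, fail_reason = f$fail_reason)
    if (f$pass) {
      alns[[length(alns) + 1L]] <- a
      effs[length(effs) + 1L] <- e$bis_efficiency
      outcome[i] <- if (any(prof == 2L)) "ambiguous_profile" else "counted"
    } else {
      outcome[i] <- f$fail_reason
    }
  }
  structure(list(calls = calls, alignments = alns, efficiencies = effs,
                 log = data.frame(read_id = ids, outcome = outcome,
                                  stringsAsFactors = FALSE),
                 region_id = reg$region_id),
            class = "profile_calls")
}

#' Per-site methylation and conversion statistics over passing reads
#'
#' CpG sites tally methylated (C), unmethylated (T) and ambiguous calls;
#' the site methylation percentage is methylated / (methylated +
#' unmethylated).  Non-CpG C sites tally converted (T), unconverted (C) and
#' excluded positions analogously, giving the per-site conversion
#' percentage.
#'
#' @param pc A `profile_calls` object from [call_reads()].
#' @param reg The [region()].
#' @return List of class `site_stats` with `n_pass_reads`, `cpg`
#'   (data.frame: position, methylated, unmethylated, ambiguous,
#'   percent_methylated) and `noncpg_c` (data.frame: position, converted,
#'   unconverted, excluded, percent_converted).
#' @export
accumulate_site_stats <- function(pc, reg) {
  pass_idx <- which(vapply(pc$calls, `[[`, TRUE, "pass"))
  ncpg <- length(reg$cpg_positions)
  meth <- un <- amb <- integer(ncpg)
  conv <- unconv <- excl <- integer(length(reg$noncpg_c_positions))
  for (k in seq_along(pass_idx)) {
    prof <- pc$calls[[pass_idx[k]]]$profile
    meth <- meth + (prof == 1L)
    un <- un + (prof == 0L)
    amb <- amb + (prof == 2L)
    a <- pc$alignments[[k]]
    bases <- .read_base_by_ref_pos(a)
    p <- reg$noncpg_c_positions
    b <- rep(".", length(p))
    inr <- p >= a$ref_start & p <= a$ref_end
    b[inr] <- bases[p[inr] - a$ref_start + 1L]
    conv <- conv + (b == "T")
    unconv <- unconv + (b == "C")
    excl <- excl + (b != "T" & b != "C")
  }
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  structure(list(
    n_pass_reads = length(pass_idx),
    cpg = data.frame(position = reg$cpg_positions, methylated = meth,
                     unmethylated = un, ambiguous = amb,
                     percent_methylated = pct(meth, meth + un)),
    noncpg_c = data.frame(position = reg$noncpg_c_positions, converted = conv,
                          unconverted = unconv, excluded = excl,
                          percent_converted = pct(conv, conv + unconv))),
    class = "site_stats")
}

#' Count epihaplotype abundances from passing calls
#'
#' The abundance table is defined over the `2^NCpG` binary epihaplotypes,
#' which has no slot for unassessable states: passing reads whose profile
#' contains a 2 are excluded from the counts and tallied separately (they
#' remain visible in the profile-matrix output).
#'
#' @param pc A `profile_calls` object.
#' @return List with `counts` (named integer vector keyed by `{0,1}`
#'   profile strings) and `ambiguous_read_count`.
#' @export
count_profiles <- function(pc) {
  keys <- character(0)
  n_amb <- 0L
  for (call in pc$calls) {
    if (!isTRUE(call$pass)) next
    if (any(call$profile == 2L)) { n_amb <- n_amb + 1L; next }
    keys[length(keys) + 1L] <- paste(call$profile, collapse = "")
  }
  counts <- if (length(keys)) table(keys) else table(character(0))
  out <- as.integer(counts)
  names(out) <- names(counts)
  list(counts = out, ambiguous_read_count = n_amb)
}

#' Write the CpG methylation profile matrix
#'
#' Tab-separated: one row per passing read (alignment-report order), one
#' column per CpG site in reference order, entries 0/1/2.
#'
#' @param pc A `profile_calls` object.
#' @param reg The [region()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_matrix <- function(pc, reg, path) {
  pass <- Filter(function(x) isTRUE(x$pass), pc$calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("read_id", paste0("CpG_", reg$cpg_positions)),
                   collapse = "\t"), con)
  for (call in pass)
    writeLines(paste(c(call$read_id, call$profile), collapse = "\t"), con)
  invisible(path)
}

#' Write the summary and quality statistics report
#'
#' Reports the number of passing reads, the methylation percentage of each
#' CpG site and the conversion percentage of each non-CpG C site (1-based
#' reference positions).
#'
#' @param stats A `site_stats` object.
#' @param sample_id,region_id Annotation values.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary_stats <- function(stats, sample_id, region_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("sample\t%s", sample_id),
               sprintf("region\t%s", region_id),
               sprintf("passing_reads\t%d", stats$n_pass_reads),
               "", "CpG site methylation (position\tpercent_methylated)"), con)
  for (i in seq_len(nrow(stats$cpg)))
    writeLines(sprintf("CpG_%d\t%s", stats$cpg$position[i],
                       format(stats$cpg$percent_methylated[i], digits = 4)), con)
  writeLines(c("", "non-CpG C conversion (position\tpercent_converted)"), con)
  for (i in seq_len(nrow(stats$noncpg_c)))
    writeLines(sprintf("C_%d\t%s", stats$noncpg_c$position[i],
                       format(stats$noncpg_c$percent_converted[i], digits = 4)), con)
  invisible(path)
}

#' Write the tabular epihaplotype abundance report
#'
#' Columns: `id` (sample), `profile`, `count`, `n_meths` (number of
#' methylated CpGs in the profile).
#'
#' @param counts Named integer vector from [count_profiles()].
#' @param sample_id Sample identifier.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_abundance_tab <- function(counts, sample_id, path) {
  profs <- names(counts)
  if (is.null(profs)) profs <- character(0)
  nm <- vapply(profs, function(p) sum(strsplit(p, "")[[1]] == "1"), integer(1))
  ord <- order(nm, profs)
  df <- data.frame(id = rep(sample_id, length(profs)),
                   profile = profs, count = as.integer(counts),
                   n_meths = nm)[ord, , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
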