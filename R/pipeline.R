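# Orchestration: demultiplex -> align -> call -> count -> merge -> EHA
# over multiple samples and regions, with per-stage attrition logging.

#' Read a sample metadata file
#'
#' Tab-separated with a header; the first column is the sample id, the
#' remaining columns are group factors.
#'
#' @param path Path to the metadata TSV.
#' @param group_column Which factor column to use (name or index; default
#'   the first factor column).
#' @return Named character vector: sample id -> group label.
#' @export
read_metadata <- function(path, group_column = 2L) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("metadata needs a sample column and a group column")
  structure(as.character(df[[group_column]]), names = as.character(df[[1]]))
}

#' Extract methylation profiles for every sample and region
#'
#' Runs demultiplexing, length filtering, alignment, efficiency filtering
#' and profile calling for each (sample, region) pair, writing the per-pair
#' reports (demultiplexed FASTA, plain-text alignments, profile matrix,
#' summary/quality statistics, tabular abundance) under
#' `out_dir/<region>/<sample>/`.  Every read's fate is logged; outcomes
#' partition the input reads.
#'
#' @param sample_fastas Named character vector: sample id -> FASTA path.
#' @param regions List of [region()] objects (e.g. from [load_regions()]).
#' @param cfg An [epihaplo_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @return List of class `extract_result`: `counts` (region -> sample ->
#'   named count vector), `ambiguous` (region -> sample -> count),
#'   `site_stats`, `attrition` (data.frame: sample, region, outcome,
#'   reads), `log` (per-read outcome data.frame).
#' @export
run_extract <- function(sample_fastas, regions, cfg = epihaplo_config(),
                        out_dir = NULL) {
  stopifnot(!is.null(names(sample_fastas)))
  missing <- sample_fastas[!file.exists(sample_fastas)]
  if (length(missing))
    stop(sprintf("input FASTA not found: %s", missing[1]))
  region_ids <- vapply(regions, `[[`, "", "region_id")
  counts <- ambiguous <- site_stats <- setNames(
    lapply(region_ids, function(...) list()), region_ids)
  logs <- list()
  for (s in names(sample_fastas)) {
    reads <- read_fasta_seqs(sample_fastas[[s]])
    dm <- demultiplex_reads(reads, regions, cfg, sample_id = s)
    dlog <- dm$log
    for (rid in region_ids) {
      reg <- regions[[match(rid, region_ids)]]
      rr <- dm$by_region[[rid]]
      pc <- call_reads(rr, reg, cfg)
      st <- accumulate_site_stats(pc, reg)
      cp <- count_profiles(pc)
      counts[[rid]][[s]] <- cp$counts
      ambiguous[[rid]][[s]] <- cp$ambiguous_read_count
      site_stats[[rid]][[s]] <- st
      # fold calling outcomes into the sample log
      if (nrow(pc$log)) {
        m <- match(pc$log$read_id, dlog$read_id)
        dlog$outcome[m] <- pc$log$outcome
      }
      if (!is.null(out_dir)) {
        d <- file.path(out_dir, rid, s)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_demux_fasta(rr, s, rid, file.path(d, "demultiplexed.fasta"))
        write_alignment_report(pc$alignments, pc$efficiencies, s, rid,
                               file.path(d, "alignments.txt"))
        write_profile_matrix(pc, reg, file.path(d, "profile_matrix.tsv"))
        write_summary_stats(st, s, rid, file.path(d, "summary_stats.txt"))
        write_abundance_tab(cp$counts, s, file.path(d, "abundance.tsv"))
      }
    }
    logs[[s]] <- dlog
  }
  log <- do.call(rbind, unname(logs))
  if (nrow(log)) {
    attrition <- as.data.frame(table(sample = log$sample_id,
                                     outcome = log$outcome),
                               stringsAsFactors = FALSE)
    names(attrition)[3] <- "reads"
  } else {
    attrition <- data.frame(sample = character(0), outcome = character(0),
                            reads = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, ambiguous = ambiguous,
                 site_stats = site_stats, attrition = attrition, log = log),
            class = "extract_result")
}

#' Epihaplotype-based analysis of one region's abundance table
#'
#' Writes the region's report folder: a text summary of the table, the
#' methylation-class composition (`profileSummary/`), a heatmap with
#' UPGMA-ordered rows, the alpha-rarefaction results (`Alpha/`) and—when
#' at least two samples are present—the beta-diversity results (`Beta/`:
#' `bray_curtis_dm.txt`, `bray_curtis_pc.txt`, 2D PCoA plots, and distance
#' boxplots when groups are given).  With a single sample the beta step is
#' skipped with a message.
#'
#' @param tab A [profile_table()] (or path to a BIOM file).
#' @param cfg An [epihaplo_config()].
#' @param groups Optional named character vector (sample id -> group);
#'   must cover every sample of the table.
#' @param out_dir Output folder for the region's reports; `NULL` to skip
#'   writing files.
#' @return List of class `eha_result`: `summary`, `class_composition`,
#'   `alpha`, `beta` (`NULL` with fewer than 2 samples).
#' @export
run_eha <- function(tab, cfg = epihaplo_config(), groups = NULL,
                    out_dir = NULL) {
  if (is.character(tab)) tab <- read_biom(tab)
  if (!is.null(groups)) {
    missing <- setdiff(tab$sample_ids, names(groups))
    if (length(missing))
      stop(sprintf("metadata is missing sample id '%s'", missing[1]))
  }
  smry <- summary(tab)
  comp <- class_composition(tab)
  alpha <- alpha_rarefaction(tab, cfg, groups)
  beta <- NULL
  pos <- tab$sample_ids[colSums(tab$counts) > 0]
  if (length(tab$sample_ids) < 2L) {
    message("single sample: beta diversity skipped")
  } else if (length(pos) < 2L) {
    message("fewer than 2 samples with passing reads: beta diversity skipped")
  } else {
    bt <- tab
    if (length(pos) < length(tab$sample_ids))
      bt <- profile_table(tab$counts[, pos, drop = FALSE], tab$region_id)
    beta <- beta_pipeline(bt, cfg, groups)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(out_dir, "summary.txt"), "w")
    sink(con); print(smry); sink(); close(con)
    ps <- file.path(out_dir, "profileSummary")
    dir.create(ps, showWarnings = FALSE)
    write.table(comp, file.path(ps, "class_composition.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    if (ncol(comp)) plot_class_composition(comp, file.path(ps, "class_composition.pdf"))
    if (length(tab$profiles) >= 2L)
      plot_heatmap(tab, file.path(out_dir, "heatmap.pdf"))
    ad <- file.path(out_dir, "Alpha")
    dir.create(ad, showWarnings = FALSE)
    write.table(alpha$values, file.path(ad, "alpha_values.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(alpha$group_curves))
      write.table(alpha$group_curves, file.path(ad, "alpha_group_curves.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(alpha$values))
      plot_rarefaction(alpha, file.path(ad, "rarefaction_curves.pdf"), groups)
    if (!is.null(beta)) {
      bd <- file.path(out_dir, "Beta")
      dir.create(bd, showWarnings = FALSE)
      write.table(beta$distance, file.path(bd, "bray_curtis_dm.txt"),
                  sep = "\t", quote = FALSE, col.names = NA)
      write_pcoa_txt(beta$pcoa, file.path(bd, "bray_curtis_pc.txt"))
      plot_pcoa_2d(beta$pcoa, file.path(bd, "pcoa_2d.pdf"), groups)
      if (!is.null(beta$group_summary)) {
        write.table(beta$group_summary$detail,
                    file.path(bd, "group_distances.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        plot_distance_boxplots(beta$group_summary,
                               file.path(bd, "distance_boxplots.pdf"))
      }
    }
  }
  structure(list(summary = smry, class_composition = comp,
                 alpha = alpha, beta = beta),
            class = "eha_result")
}

#' Write PCoA results as a text report
#'
#' Eigenvalues, proportion explained, then per-sample coordinates.
#'
#' @param pc A `pcoa_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pcoa_txt <- function(pc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("Eigvals", paste(format(pc$eigenvalues, digits = 10),
                                collapse = "\t"), "",
               "Proportion explained",
               paste(format(pc$proportion_explained, digits = 10),
                     collapse = "\t"), "", "Site"), con)
  coords <- pc$coordinates
  for (i in seq_len(nrow(coords)))
    writeLines(paste(c(rownames(coords)[i],
                       format(coords[i, ], digits = 10)), collapse = "\t"), con)
  invisible(path)
}

#' Run the full pipeline: extraction, merging and per-region analyses
#'
#' @param sample_fastas Named character vector: sample id -> FASTA path.
#' @param regions List of [region()] objects.
#' @param cfg An [epihaplo_config()].
#' @param groups Optional named character vector (sample id -> group).
#' @param out_dir Output root; per-region extraction output under
#'   `extract/`, merged tables and analyses under `eha/<region>/`.
#' @return List of class `pipeline_result`: `extract`, `tables` (region ->
#'   [profile_table()]), `eha` (region -> `eha_result`).
#' @export
run_pipeline <- function(sample_fastas, regions, cfg = epihaplo_config(),
                         groups = NULL, out_dir = NULL) {
  ex <- run_extract(sample_fastas, regions, cfg,
                    out_dir = if (!is.null(out_dir)) file.path(out_dir, "extract"))
  tables <- list(); eha <- list()
  for (rid in names(ex$counts)) {
    tab <- merge_sample_counts(ex$counts[[rid]], region_id = rid)
    tables[[rid]] <- tab
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, "eha", rid)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_biom(tab, file.path(d, "abundance.biom"))
    }
    eha[[rid]] <- run_eha(tab, cfg, groups,
                          out_dir = if (!is.null(out_dir)) file.path(out_dir, "eha", rid))
  }
  structure(list(extract = ex, tables = tables, eha = eha),
            class = "pipeline_result")
}
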