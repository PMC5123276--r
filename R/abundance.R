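# Sparse samples x epihaplotypes abundance table; tabular and BIOM 1.0
# JSON serialization.

.n_meths <- function(profiles)
  vapply(profiles, function(p) sum(strsplit(p, "")[[1]] == "1"), integer(1),
         USE.NAMES = FALSE)

#' Construct an epihaplotype abundance table
#'
#' Rows are distinct epihaplotypes (binary profile strings, the
#' observations), columns are samples.  Rows are stored sorted by
#' (methylation class, lexicographic profile) and all-zero rows are
#' dropped, so equal tables have identical layouts.
#'
#' @param counts Integer matrix (profiles x samples) with rownames =
#'   profile strings, colnames = sample ids; or `NULL` for an empty table.
#' @param region_id Region identifier.
#' @return Object of class `profile_table` with fields `region_id`,
#'   `sample_ids`, `profiles`, `counts` (integer matrix), `n_meths`.
#' @export
profile_table <- function(counts, region_id = "region") {
  if (is.null(counts) || nrow(counts) == 0L) {
    counts <- matrix(integer(0), nrow = 0L,
                     ncol = if (is.null(counts)) 0L else ncol(counts),
                     dimnames = list(NULL, colnames(counts)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  lens <- nchar(rownames(counts))
  if (length(unique(lens)) > 1L)
    stop("inconsistent profile lengths in abundance table")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  profs <- rownames(counts)
  if (is.null(profs)) profs <- character(0)
  nm <- .n_meths(profs)
  ord <- order(nm, profs)
  counts <- counts[ord, , drop = FALSE]
  structure(list(region_id = region_id,
                 sample_ids = colnames(counts),
                 profiles = profs[ord],
                 counts = matrix(as.integer(counts), nrow = nrow(counts),
                                 ncol = ncol(counts),
                                 dimnames = dimnames(counts)),
                 n_meths = nm[ord]),
            class = "profile_table")
}

#' Merge per-sample epihaplotype counts into one table
#'
#' @param per_sample Named list (names = sample ids) of named integer
#'   vectors (names = profile strings) as returned by [count_profiles()].
#' @param region_id Region identifier.
#' @return A [profile_table()] whose columns follow the input sample order
#'   and whose column sums equal each sample's unambiguous passing count.
#' @examples
#' merge_sample_counts(list(s1 = c("11" = 2L), s2 = c("00" = 3L)))
#' @export
merge_sample_counts <- function(per_sample, region_id = "region") {
  stopifnot(is.list(per_sample), !is.null(names(per_sample)))
  lens <- unique(nchar(unlist(lapply(per_sample, names), use.names = FALSE)))
  if (length(lens) > 1L)
    stop("inconsistent profile lengths across samples")
  profs <- sort(unique(unlist(lapply(per_sample, names), use.names = FALSE)))
  m <- matrix(0L, nrow = length(profs), ncol = length(per_sample),
              dimnames = list(profs, names(per_sample)))
  for (s in names(per_sample)) {
    v <- per_sample[[s]]
    if (length(v)) m[names(v), s] <- as.integer(v)
  }
  profile_table(m, region_id = region_id)
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("profile_table '%s': %d epihaplotypes x %d samples, %d reads\n",
              x$region_id, length(x$profiles), length(x$sample_ids),
              sum(x$counts)))
  invisible(x)
}

#' Summary statistics of an abundance table
#'
#' @param object A [profile_table()].
#' @param ... Unused.
#' @return List with `n_samples`, `n_observations` (distinct profiles),
#'   `total_count`, `density` (fraction of non-zero cells; 0 for an empty
#'   table), and `per_sample` counts with min/max/median/mean/sd (sample
#'   standard deviation).
#' @export
summary.profile_table <- function(object, ...) {
  m <- object$counts
  per <- if (ncol(m)) colSums(m) else integer(0)
  dens <- if (length(m)) sum(m > 0) / length(m) else 0
  out <- list(region_id = object$region_id,
              n_samples = length(object$sample_ids),
              n_observations = length(object$profiles),
              total_count = sum(m),
              density = dens,
              counts_per_sample = per,
              min = if (length(per)) min(per) else NA_real_,
              max = if (length(per)) max(per) else NA_real_,
              median = if (length(per)) median(per) else NA_real_,
              mean = if (length(per)) mean(per) else NA_real_,
              sd = if (length(per) > 1L) sd(per) else NA_real_)
  class(out) <- "summary.profile_table"
  out
}

#' @export
print.summary.profile_table <- function(x, ...) {
  cat(sprintf("Num samples: %d\n", x$n_samples))
  cat(sprintf("Num observations: %d\n", x$n_observations))
  cat(sprintf("Total count: %d\n", x$total_count))
  cat(sprintf("Table density (fraction of non-zero values): %.4f\n", x$density))
  cat("\nCounts/sample summary:\n")
  cat(sprintf(" Min: %s\n Max: %s\n Median: %s\n Mean: %s\n Std. dev.: %s\n",
              format(x$min), format(x$max), format(x$median),
              format(x$mean, digits = 6), format(x$sd, digits = 6)))
  cat("\nCounts/sample detail:\n")
  for (s in names(x$counts_per_sample))
    cat(sprintf(" %s: %d\n", s, x$counts_per_sample[[s]]))
  invisible(x)
}

#' Per-sample composition by methylation class
#'
#' @param t A [profile_table()].
#' @return Numeric matrix (classes 0..NCpG x samples) of relative
#'   abundances; each reported column sums to 1.  Samples with zero total
#'   are dropped.
#' @export
class_composition <- function(t) {
  if (length(t$profiles) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  ncpg <- nchar(t$profiles[1])
  classes <- 0:ncpg
  m <- matrix(0, nrow = length(classes), ncol = length(t$sample_ids),
              dimnames = list(paste0("class_", classes), t$sample_ids))
  for (i in seq_along(t$profiles))
    m[t$n_meths[i] + 1L, ] <- m[t$n_meths[i] + 1L, ] + t$counts[i, ]
  tot <- colSums(m)
  keep <- tot > 0
  sweep(m[, keep, drop = FALSE], 2, tot[keep], "/")
}

#' Write an abundance table as BIOM 1.0 JSON
#'
#' Single-document sparse BIOM (type "OTU table"): observations are the
#' epihaplotypes, carrying `taxonomy = ["class_<n_meths>", "<profile>"]` so
#' the methylation class acts as the first-level grouping factor; `data`
#' holds `[row, col, value]` triples with 0-based indices.
#'
#' @param t A [profile_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_biom <- function(t, path) {
  nr <- length(t$profiles); nc <- length(t$sample_ids)
  rows <- lapply(seq_len(nr), function(i) {
    list(id = t$profiles[i],
         metadata = list(taxonomy = c(paste0("class_", t$n_meths[i]),
                                      t$profiles[i])))
  })
  cols <- lapply(t$sample_ids, function(s) list(id = s, metadata = NULL))
  nz <- which(t$counts != 0, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(nz)), function(k)
    c(nz[k, 1] - 1L, nz[k, 2] - 1L, t$counts[nz[k, 1], nz[k, 2]]))
  doc <- list(
    id = t$region_id,
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = paste0("epihaplo ",
                          as.character(utils::packageVersion("epihaplo"))),
    date = "1970-01-01T00:00:00",
    matrix_type = "sparse",
    matrix_element_type = "int",
    shape = c(nr, nc),
    rows = rows,
    columns = cols,
    data = data)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a BIOM 1.0 JSON abundance table
#'
#' Accepts sparse or dense `matrix_type`.  Observation ids are taken as the
#' profile strings.
#'
#' @param path Path to a BIOM 1.0 JSON file.
#' @param region_id Region id for the resulting table; defaults to the
#'   document's `id` field when present.
#' @return A [profile_table()].
#' @export
read_biom <- function(path, region_id = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("format", "type", "matrix_type", "shape", "rows",
                "columns", "data"))
    if (is.null(doc[[key]]))
      stop(sprintf("BIOM document is missing required key '%s'", key))
  nr <- doc$shape[[1]]; nc <- doc$shape[[2]]
  profs <- vapply(doc$rows, function(r) r$id, "")
  samps <- vapply(doc$columns, function(cc) cc$id, "")
  m <- matrix(0L, nrow = nr, ncol = nc, dimnames = list(profs, samps))
  if (identical(doc$matrix_type, "sparse")) {
    for (trip in doc$data)
      m[trip[[1]] + 1L, trip[[2]] + 1L] <- as.integer(trip[[3]])
  } else if (identical(doc$matrix_type, "dense")) {
    for (i in seq_len(nr))
      m[i, ] <- as.integer(unlist(doc$data[[i]]))
  } else stop(sprintf("unsupported matrix_type '%s'", doc$matrix_type))
  if (is.null(region_id))
    region_id <- if (!is.null(doc$id)) doc$id else "region"
  profile_table(m, region_id = region_id)
}
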