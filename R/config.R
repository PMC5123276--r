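#' Pipeline configuration
#'
#' Collects every tunable threshold and scoring parameter of the pipeline in
#' one validated object.  Defaults follow the values used for a typical
#' MiSeq amplicon run of a few-hundred-bp promoter region: reads must match
#' their primers at 80% similarity at both ends, lie within +/-50% of the
#' reference length, and show at least 98% bisulfite conversion of non-CpG
#' cytosines before their CpG profile is counted.
#'
#' @param primer_similarity_min Minimum primer similarity in `[0,1]` required
#'   at *both* read ends for demultiplexing (default 0.8).
#' @param length_tolerance Fractional length tolerance `t`: a read passes if
#'   its length is within `[ceil((1-t)L), floor((1+t)L)]` of the reference
#'   length `L` (default 0.5).
#' @param bis_efficiency_min Minimum per-read bisulfite conversion efficiency
#'   over non-CpG cytosines (default 0.98; reads at the boundary pass).
#' @param assayed_fraction_min Minimum fraction of reference non-CpG
#'   cytosines that must be assayable (read base C or T) for the efficiency
#'   estimate to be considered valid (default 0.66).
#' @param align_match,align_mismatch,align_gap_open,align_gap_extend Integer
#'   alignment scores (BLASTN-like defaults +2/-3/-5/-2).  A gap of length
#'   `k` costs `align_gap_open + (k-1) * align_gap_extend`.
#' @param rarefaction_depths Either `"auto"` (10 evenly spaced depths from
#'   10% to 100% of the minimum sample total) or a vector of positive
#'   integer depths.
#' @param rarefaction_iterations Number of random subsamples per
#'   (sample, depth) cell (default 10).
#' @param rng_seed Integer seed governing every stochastic step (rarefaction,
#'   synthetic reads).
#' @return An object of class `epihaplo_config` (a validated list).
#' @examples
#' cfg <- epihaplo_config(bis_efficiency_min = 0.95)
#' cfg$bis_efficiency_min
#' @export
epihaplo_config <- function(primer_similarity_min = 0.8,
                            length_tolerance = 0.5,
                            bis_efficiency_min = 0.98,
                            assayed_fraction_min = 0.66,
                            align_match = 2L,
                            align_mismatch = -3L,
                            align_gap_open = -5L,
                            align_gap_extend = -2L,
                            rarefaction_depths = "auto",
                            rarefaction_iterations = 10L,
                            rng_seed = 1L) {
  frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a single fraction in [0,1]", nm), call. = FALSE)
    as.numeric(x)
  }
  cfg <- list(
    primer_similarity_min = frac(primer_similarity_min, "primer_similarity_min"),
    length_tolerance = frac(length_tolerance, "length_tolerance"),
    bis_efficiency_min = frac(bis_efficiency_min, "bis_efficiency_min"),
    assayed_fraction_min = frac(assayed_fraction_min, "assayed_fraction_min"),
    align_match = as.integer(align_match),
    align_mismatch = as.integer(align_mismatch),
    align_gap_open = as.integer(align_gap_open),
    align_gap_extend = as.integer(align_gap_extend),
    rarefaction_depths = rarefaction_depths,
    rarefaction_iterations = as.integer(rarefaction_iterations),
    rng_seed = as.integer(rng_seed))
  if (cfg$align_match <= 0L) stop("'align_match' must be positive", call. = FALSE)
  if (cfg$align_mismatch >= 0L) stop("'align_mismatch' must be negative", call. = FALSE)
  if (cfg$align_gap_open >= 0L || cfg$align_gap_extend >= 0L)
    stop("gap penalties must be negative", call. = FALSE)
  if (!identical(cfg$rarefaction_depths, "auto")) {
    d <- cfg$rarefaction_depths
    if (!is.numeric(d) || any(d < 1) || any(d != floor(d)))
      stop("'rarefaction_depths' must be \"auto\" or positive integers", call. = FALSE)
    cfg$rarefaction_depths <- as.integer(d)
  }
  if (cfg$rarefaction_iterations < 1L)
    stop("'rarefaction_iterations' must be >= 1", call. = FALSE)
  class(cfg) <- "epihaplo_config"
  cfg
}

#' @export
print.epihaplo_config <- function(x, ...) {
  cat("epihaplo pipeline configuration\n")
  cat(sprintf("  primer similarity >= %.3g (both ends), length tolerance +/-%.0f%%\n",
              x$primer_similarity_min, 100 * x$length_tolerance))
  cat(sprintf("  bisulfite efficiency >= %.3g over >= %.3g of non-CpG Cs\n",
              x$bis_efficiency_min, x$assayed_fraction_min))
  cat(sprintf("  alignment scores: match %+d, mismatch %+d, gap open %+d, gap extend %+d\n",
              x$align_match, x$align_mismatch, x$align_gap_open, x$align_gap_extend))
  dep <- if (identical(x$rarefaction_depths, "auto")) "auto"
         else paste(x$rarefaction_depths, collapse = ",")
  cat(sprintf("  rarefaction: depths %s, %d iterations, seed %d\n",
              dep, x$rarefaction_iterations, x$rng_seed))
  invisible(x)
}
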