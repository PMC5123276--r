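# Ecology-style diversity analyses of epihaplotype abundances:
# rarefaction, five alpha metrics, Bray-Curtis, PCoA, UPGMA, group
# distance summaries.  All metrics are implemented from first principles;
# vegan/ape serve only as independent cross-checks in the test suite.

#' Rarefy a count vector to a fixed depth
#'
#' Draws `depth` observations without replacement from the community
#' described by `counts` (a multivariate hypergeometric sample), removing
#' sequencing-depth differences between samples.  Deterministic for a fixed
#' RNG state.
#'
#' @param counts Non-negative integer vector.
#' @param depth Target depth, at most `sum(counts)`.
#' @return Integer vector of the same length summing exactly to `depth`.
#' @examples
#' set.seed(1); rarefy_counts(c(5, 0), 3)  # c(3, 0)
#' @export
rarefy_counts <- function(counts, depth) {
  counts <- as.integer(counts)
  total <- sum(counts)
  if (depth > total) stop("rarefaction depth exceeds the sample total")
  if (depth == total) return(counts)
  pool <- rep.int(seq_along(counts), counts)
  picked <- pool[sample.int(total, depth)]
  tabulate(picked, nbins = length(counts))
}

#' Alpha diversity metrics
#'
#' Five within-sample diversity measures of an epihaplotype abundance
#' vector: the number of observed profiles (richness), the number of
#' singletons (profiles seen exactly once), Shannon entropy in bits
#' (base-2 log), the Simpson diversity index `1 - sum(p_i^2)`, and the
#' bias-corrected Chao1 richness estimate
#' `S_obs + F1*(F1-1) / (2*(F2+1))` with `F1`/`F2` the singleton/doubleton
#' counts.
#'
#' @param v Non-negative count vector.
#' @return A single number.
#' @examples
#' shannon_entropy(c(1, 1, 2))   # 1.5 bits
#' simpson_index(c(1, 1, 1, 1))  # 0.75
#' chao1_richness(c(1, 1, 2, 5)) # 4.5
#' @name alpha-metrics
NULL

#' @rdname alpha-metrics
#' @export
observed_profiles <- function(v) sum(v > 0)

#' @rdname alpha-metrics
#' @export
singleton_count <- function(v) sum(v == 1)

#' @rdname alpha-metrics
#' @export
shannon_entropy <- function(v) {
  if (sum(v) <= 0) stop("total count must be positive")
  p <- v[v > 0] / sum(v)
  -sum(p * log2(p))
}

#' @rdname alpha-metrics
#' @export
simpson_index <- function(v) {
  if (sum(v) <= 0) stop("total count must be positive")
  p <- v / sum(v)
  1 - sum(p^2)
}

#' @rdname alpha-metrics
#' @export
chao1_richness <- function(v) {
  if (sum(v) <= 0) stop("total count must be positive")
  f1 <- sum(v == 1); f2 <- sum(v == 2)
  sum(v > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

ALPHA_METRICS <- list(observed_profiles = observed_profiles,
                      shannon = shannon_entropy,
                      simpson = simpson_index,
                      chao1 = chao1_richness,
                      singletons = singleton_count)

#' Alpha-diversity rarefaction analysis
#'
#' For every sample, every requested depth and every iteration, the sample
#' is rarefied and the five alpha metrics are computed.  Depths `"auto"`
#' are 10 evenly spaced values from 10% to 100% of the minimum sample
#' total.  Cells where a sample is smaller than the requested depth are
#' absent (not zero).  Group curves report the mean across the group's
#' per-sample means with a 95% normal-approximation half-width
#' (`1.96 * SE`).
#'
#' @param t A [profile_table()].
#' @param cfg An [epihaplo_config()]; uses `rarefaction_depths`,
#'   `rarefaction_iterations` and `rng_seed`.
#' @param groups Optional named character vector mapping sample id to group
#'   label.
#' @return Object of class `alpha_result`: `values` (long data.frame:
#'   sample, depth, iteration, metric, value) and `group_curves`
#'   (data.frame: group, depth, metric, mean, ci_halfwidth, n_samples; only
#'   when `groups` given).
#' @export
alpha_rarefaction <- function(t, cfg = epihaplo_config(), groups = NULL) {
  totals <- colSums(t$counts)
  if (length(totals) == 0L) stop("abundance table has no samples")
  depths <- cfg$rarefaction_depths
  if (identical(depths, "auto")) {
    dmin <- min(totals)
    depths <- unique(pmax(1L, as.integer(round(seq(0.1, 1, length.out = 10) * dmin))))
  }
  set.seed(cfg$rng_seed)
  mnames <- names(ALPHA_METRICS)
  col_sample <- character(0); col_depth <- integer(0)
  col_iter <- integer(0); col_metric <- character(0); col_value <- numeric(0)
  for (s in t$sample_ids) {
    v <- t$counts[, s]
    for (d in depths) {
      if (d > totals[[s]]) next
      for (it in seq_len(cfg$rarefaction_iterations)) {
        rv <- rarefy_counts(v, d)
        vals <- vapply(ALPHA_METRICS, function(f) f(rv), 0.0)
        col_sample <- c(col_sample, rep(s, length(mnames)))
        col_depth <- c(col_depth, rep(d, length(mnames)))
        col_iter <- c(col_iter, rep(it, length(mnames)))
        col_metric <- c(col_metric, mnames)
        col_value <- c(col_value, vals)
      }
    }
  }
  values <- data.frame(sample = col_sample, depth = col_depth,
                       iteration = col_iter, metric = col_metric,
                       value = unname(col_value), stringsAsFactors = FALSE)
  group_curves <- NULL
  if (!is.null(groups) && nrow(values)) {
    missing <- setdiff(t$sample_ids, names(groups))
    if (length(missing))
      stop(sprintf("metadata is missing sample id '%s'", missing[1]))
    # per-sample mean over iterations, then mean/SE across group members
    agg <- stats::aggregate(value ~ sample + depth + metric, values, mean)
    agg$group <- unname(groups[agg$sample])
    gc <- stats::aggregate(value ~ group + depth + metric, agg, function(x)
      c(mean = mean(x), se = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
        n = length(x)))
    group_curves <- data.frame(group = gc$group, depth = gc$depth,
                               metric = gc$metric,
                               mean = gc$value[, "mean"],
                               ci_halfwidth = qnorm(0.975) * gc$value[, "se"],
                               n_samples = gc$value[, "n"],
                               stringsAsFactors = FALSE)
  }
  structure(list(values = values, group_curves = group_curves,
                 depths = depths), class = "alpha_result")
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; 0 for identical compositions, 1 for
#' disjoint supports.
#'
#' @param x,y Equal-length non-negative vectors, not both all zero.
#' @return A fraction in `[0, 1]`.
#' @examples
#' bray_curtis(c(6, 0, 2), c(2, 4, 2))  # 0.5
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all zero")
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis distance matrix of a table's samples
#'
#' @param t A [profile_table()] (or a plain profiles x samples matrix).
#' @return Symmetric matrix with zero diagonal, labelled by sample id.
#' @export
bray_curtis_matrix <- function(t) {
  m <- if (inherits(t, "profile_table")) t$counts else t
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- bray_curtis(m[, i], m[, j])
  d
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers the squared distance matrix, `B = -1/2 * J D^2 J`, and
#' eigendecomposes it.  Coordinates on axes with positive eigenvalues are
#' eigenvectors scaled by the square root of their eigenvalue; axes with
#' non-positive eigenvalues (possible because Bray-Curtis is non-Euclidean)
#' get zero coordinates but their eigenvalues are still reported.
#' Proportion explained is computed over the positive eigenvalues only.
#'
#' @param d Symmetric distance matrix.
#' @return Object of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (descending), `proportion_explained`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("PCoA needs at least 2 samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- ev > .Machine$double.eps^0.5 * max(abs(ev), 1)
  coords <- matrix(0, n, n, dimnames = list(rownames(d), paste0("PC", 1:n)))
  if (any(pos))
    coords[, pos] <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(ev[pos]), sum(pos))
  prop <- ifelse(pos, ev / sum(ev[pos]), 0)
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = prop), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  cat(sprintf("PCoA of %d samples; first %d eigenvalues: %s\n",
              nrow(x$coordinates), k,
              paste(format(x$eigenvalues[1:k], digits = 4), collapse = ", ")))
  cat(sprintf("proportion explained: %s\n",
              paste(format(x$proportion_explained[1:k], digits = 3),
                    collapse = ", ")))
  invisible(x)
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerates the two closest clusters repeatedly, averaging distances
#' with cluster-size weights (the classical unweighted pair-group method).
#' Merge heights are half the average inter-cluster distance, the
#' ultrametric node height at which the two subtrees join; heights are
#' non-decreasing.  Ties are broken by the smallest (i, j) label pair, and
#' the leaf order follows dendrogram traversal with the first-merged
#' subtree on the left.
#'
#' @param d Symmetric distance matrix with labels.
#' @return Object of class `upgma_tree`: `merges` (data.frame: step,
#'   left, right, height — members as comma-joined labels), `order`
#'   (character vector of leaf labels), `heights`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2) {
    return(structure(list(merges = data.frame(), order = labs,
                          heights = numeric(0)), class = "upgma_tree"))
  }
  clusters <- lapply(seq_len(n), function(i) list(members = labs[i],
                                                  leaves = labs[i],
                                                  size = 1L, idx = i))
  D <- d
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    new <- list(members = c(clusters[[i]]$members, clusters[[j]]$members),
                leaves = c(clusters[[i]]$leaves, clusters[[j]]$leaves),
                size = clusters[[i]]$size + clusters[[j]]$size)
    merges[[length(merges) + 1L]] <- data.frame(
      step = length(merges) + 1L,
      left = paste(clusters[[i]]$leaves, collapse = ","),
      right = paste(clusters[[j]]$leaves, collapse = ","),
      height = bestd / 2, stringsAsFactors = FALSE)
    heights[length(heights) + 1L] <- bestd / 2
    # UPGMA update: size-weighted average of distances to the merged pair.
    # The merged cluster takes slot i (keeping earlier clusters to the
    # left), slot j is dropped.
    upd <- (clusters[[i]]$size * D[, i] + clusters[[j]]$size * D[, j]) /
      new$size
    D[, i] <- upd; D[i, ] <- upd; D[i, i] <- 0
    D <- D[-j, -j, drop = FALSE]
    clusters[[i]] <- new
    clusters <- clusters[-j]
  }
  structure(list(merges = do.call(rbind, merges),
                 order = clusters[[1]]$leaves,
                 heights = heights), class = "upgma_tree")
}

#' Within- and between-group distance summaries
#'
#' Pools all within-group pairwise distances and all between-group pairwise
#' distances, and additionally reports per-group within distances and
#' per-pair between distances.
#'
#' @param d Symmetric distance matrix with sample labels.
#' @param groups Named character vector mapping sample id to group label.
#' @return List with `within` / `between` (numeric vectors of pooled
#'   distances) and `detail` (data.frame: comparison, kind, distance).
#' @export
group_distances <- function(d, groups) {
  d <- as.matrix(d)
  ids <- rownames(d)
  missing <- setdiff(ids, names(groups))
  if (length(missing))
    stop(sprintf("metadata is missing sample id '%s'", missing[1]))
  rows <- list()
  n <- length(ids)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    gi <- groups[[ids[i]]]; gj <- groups[[ids[j]]]
    kind <- if (gi == gj) "within" else "between"
    comparison <- if (gi == gj) gi else paste(sort(c(gi, gj)), collapse = "_vs_")
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = comparison, kind = kind, distance = d[i, j],
      sample_i = ids[i], sample_j = ids[j], stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, rows)
  list(within = detail$distance[detail$kind == "within"],
       between = detail$distance[detail$kind == "between"],
       detail = detail)
}

#' Beta-diversity pipeline: rarefaction, Bray-Curtis, PCoA, group summaries
#'
#' Every sample is rarefied once to the minimum sample total (seeded from
#' the configuration), pairwise Bray-Curtis dissimilarities are computed,
#' the distance matrix is embedded by PCoA, and—when groups are given—
#' within/between-group distances are pooled.
#'
#' @param t A [profile_table()] with at least 2 samples.
#' @param cfg An [epihaplo_config()].
#' @param groups Optional named character vector (sample id -> group).
#' @return List of class `beta_result`: `distance` (matrix), `pcoa`
#'   ([pcoa()] result), `rarefied` (counts matrix actually used),
#'   `group_summary` (from [group_distances()], or `NULL`).
#' @export
beta_pipeline <- function(t, cfg = epihaplo_config(), groups = NULL) {
  if (length(t$sample_ids) < 2)
    stop("beta diversity needs at least 2 samples")
  if (any(colSums(t$counts) == 0))
    stop("beta diversity needs a positive read count in every sample")
  set.seed(cfg$rng_seed + 1L)
  dmin <- min(colSums(t$counts))
  rare <- apply(t$counts, 2, rarefy_counts, depth = dmin)
  rownames(rare) <- t$profiles
  d <- bray_curtis_matrix(rare)
  structure(list(distance = d,
                 pcoa = pcoa(d),
                 rarefied = rare,
                 group_summary = if (!is.null(groups)) group_distances(d, groups)),
            class = "beta_result")
}
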