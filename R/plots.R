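# Static report plots (PDF device; works headless).  Base graphics,
# deterministic output given the same inputs.

.group_palette <- function(labels) {
  u <- sort(unique(labels))
  structure(grDevices::hcl.colors(max(3L, length(u)), "Dark 3")[seq_along(u)],
            names = u)
}

#' Plot alpha rarefaction curves
#'
#' One panel per metric: per-sample mean curves (thin) and, when group
#' curves are present, group means with shaded 95% confidence bands.
#'
#' @param ar An `alpha_result` from [alpha_rarefaction()].
#' @param path Output PDF path.
#' @param groups Optional named character vector (sample id -> group) used
#'   to color per-sample curves.
#' @return The path, invisibly.
#' @export
plot_rarefaction <- function(ar, path, groups = NULL) {
  grDevices::pdf(path, width = 8, height = 10)
  on.exit(grDevices::dev.off())
  metrics <- unique(ar$values$metric)
  graphics::par(mfrow = c(ceiling(length(metrics) / 2), 2),
                mar = c(4, 4, 2, 1))
  agg <- stats::aggregate(value ~ sample + depth + metric, ar$values, mean)
  for (m in metrics) {
    sub <- agg[agg$metric == m, ]
    graphics::plot(NA, xlim = range(sub$depth), ylim = range(sub$value),
                   xlab = "rarefaction depth", ylab = m, main = m)
    cols <- if (!is.null(groups)) .group_palette(groups)
    for (s in unique(sub$sample)) {
      ss <- sub[sub$sample == s, ]
      ss <- ss[order(ss$depth), ]
      col <- if (!is.null(groups)) cols[[groups[[s]]]] else "grey40"
      graphics::lines(ss$depth, ss$value, col = col)
    }
    if (!is.null(ar$group_curves)) {
      gsub <- ar$group_curves[ar$group_curves$metric == m, ]
      for (g in unique(gsub$group)) {
        gg <- gsub[gsub$group == g, ]
        gg <- gg[order(gg$depth), ]
        col <- cols[[g]]
        graphics::polygon(c(gg$depth, rev(gg$depth)),
                          c(gg$mean - gg$ci_halfwidth,
                            rev(gg$mean + gg$ci_halfwidth)),
                          col = grDevices::adjustcolor(col, 0.2), border = NA)
        graphics::lines(gg$depth, gg$mean, col = col, lwd = 2)
      }
    }
  }
  invisible(path)
}

#' 2D PCoA scatter plots for the first three axis pairs
#'
#' Panels for axis pairs (1,2), (1,3) and (2,3), labelled with the
#' proportion of variation explained.
#'
#' @param pc A `pcoa_result`.
#' @param path Output PDF path.
#' @param groups Optional named character vector for point colors.
#' @return The path, invisibly.
#' @export
plot_pcoa_2d <- function(pc, path, groups = NULL) {
  grDevices::pdf(path, width = 10, height = 4)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  ids <- rownames(pc$coordinates)
  cols <- if (!is.null(groups)) .group_palette(groups)[groups[ids]] else "grey30"
  k <- min(3L, ncol(pc$coordinates))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (p in pairs) {
    if (max(p) > k) next
    lab <- sprintf("PC%d (%.1f%%)", p, 100 * pc$proportion_explained[p])
    graphics::plot(pc$coordinates[, p[1]], pc$coordinates[, p[2]],
                   col = cols, pch = 19, xlab = lab[1], ylab = lab[2],
                   main = sprintf("PCoA axes %d vs %d", p[1], p[2]))
    graphics::text(pc$coordinates[, p[1]], pc$coordinates[, p[2]],
                   labels = ids, pos = 3, cex = 0.7)
  }
  invisible(path)
}

#' Boxplots of within- and between-group distances
#'
#' Pooled within, pooled between, then one box per group and per group
#' pair.
#'
#' @param gd Result of [group_distances()].
#' @param path Output PDF path.
#' @return The path, invisibly.
#' @export
plot_distance_boxplots <- function(gd, path) {
  grDevices::pdf(path, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  det <- gd$detail
  groupsets <- c(list(`all within` = gd$within, `all between` = gd$between),
                 split(det$distance, det$comparison))
  graphics::par(mar = c(8, 4, 2, 1))
  graphics::boxplot(groupsets, las = 2, ylab = "Bray-Curtis distance",
                    main = "pairwise distances within / between groups")
  invisible(path)
}

#' Heatmap of relative epihaplotype abundances with UPGMA-ordered rows
#'
#' Columns are samples; rows are epihaplotypes ordered by UPGMA clustering
#' of their relative-abundance vectors across samples (Bray-Curtis
#' distance between profile rows).
#'
#' @param tab A [profile_table()].
#' @param path Output PDF path.
#' @return The path, invisibly; the row order used is attached as
#'   attribute `"row_order"`.
#' @export
plot_heatmap <- function(tab, path) {
  m <- tab$counts
  rel <- sweep(m, 2, pmax(1, colSums(m)), "/")
  ord <- seq_len(nrow(rel))
  if (nrow(rel) > 2) {
    dr <- bray_curtis_matrix(t(rel))     # distances between profile rows
    rownames(dr) <- colnames(dr) <- tab$profiles
    ord <- match(upgma(dr)$order, tab$profiles)
  }
  grDevices::pdf(path, width = 6, height = max(4, 0.25 * nrow(rel)))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 6, 2, 1))
  z <- t(rel[ord, , drop = FALSE])
  graphics::image(x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "epihaplotype relative abundance")
  graphics::axis(1, at = seq_len(nrow(z)), labels = rownames(z), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(ncol(z)), labels = colnames(z), las = 2,
                 cex.axis = 0.6)
  out <- invisible(path)
  attr(out, "row_order") <- ord
  out
}

#' Barplot of per-sample methylation-class composition
#'
#' @param comp Matrix from [class_composition()].
#' @param path Output PDF path.
#' @return The path, invisibly.
#' @export
plot_class_composition <- function(comp, path) {
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 4, 2, 8), xpd = TRUE)
  cols <- grDevices::hcl.colors(max(3L, nrow(comp)), "Viridis")
  graphics::barplot(comp, col = cols[seq_len(nrow(comp))], las = 2,
                    ylab = "relative abundance",
                    main = "methylation-class composition")
  graphics::legend("topright", inset = c(-0.35, 0), legend = rownames(comp),
                   fill = cols[seq_len(nrow(comp))], cex = 0.7)
  invisible(path)
}
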