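test_that("alpha metrics reproduce hand-derived values", {
  expect_equal(observed_profiles(c(1, 1, 2, 5)), 4)
  expect_equal(singleton_count(c(1, 1, 2, 5)), 2)
  expect_equal(observed_profiles(c(0, 0)), 0)
  expect_equal(singleton_count(c(7)), 0)

  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2.0)
  expect_equal(shannon_entropy(c(5)), 0.0)
  expect_equal(shannon_entropy(c(1, 1, 2)), 1.5)

  expect_equal(simpson_index(c(1, 1)), 0.5)
  expect_equal(simpson_index(c(9)), 0.0)
  expect_equal(simpson_index(c(1, 1, 1, 1)), 0.75)

  expect_equal(chao1_richness(c(3, 4, 5)), 3.0)
  expect_equal(chao1_richness(c(1, 1, 2, 5)), 4.5)
  expect_equal(chao1_richness(c(1, 3)), 2.0)
})

test_that("alpha metrics agree with vegan on random vectors", {
  skip_if_not_installed("vegan")
  set.seed(61)
  for (k in 1:200) {
    v <- rpois(sample(2:12, 1), 2)
    if (sum(v) == 0) v[1] <- 1
    expect_equal(shannon_entropy(v),
                 vegan::diversity(v, index = "shannon", base = 2))
    expect_equal(simpson_index(v), vegan::diversity(v, index = "simpson"))
    # estimateR's auxiliary SE terms can warn about NaN on sparse vectors;
    # only the point estimates are compared
    est <- suppressWarnings(vegan::estimateR(v))
    expect_equal(chao1_richness(v), unname(est["S.chao1"]))
    expect_equal(observed_profiles(v), unname(est["S.obs"]))
  }
})

test_that("rarefaction subsamples without replacement at exact depth", {
  set.seed(62)
  expect_equal(rarefy_counts(c(5, 0), 3), c(3, 0))
  expect_equal(rarefy_counts(c(2, 2), 4), c(2, 2))
  v <- c(10, 5, 1, 0, 7)
  expect_equal(rarefy_counts(v, sum(v)), v)
  expect_error(rarefy_counts(c(1, 1), 3), "exceeds")
  for (k in 1:30) {
    r <- rarefy_counts(v, 9)
    expect_equal(sum(r), 9)
    expect_true(all(r <= v))
  }
})

test_that("mean observed profiles under rarefaction matches the hypergeometric closed form", {
  v <- c(12, 7, 4, 2, 1, 1, 30)
  N <- sum(v); n <- 20L
  expected <- sum(1 - choose(N - v, n) / choose(N, n))
  set.seed(63)
  iters <- 200
  obs <- replicate(iters, observed_profiles(rarefy_counts(v, n)))
  se <- sd(obs) / sqrt(iters)
  expect_lt(abs(mean(obs) - expected), 3 * se + 1e-9)
})

test_that("alpha rarefaction grid has deterministic seeded cells and sane curves", {
  t <- merge_sample_counts(list(
    s1 = c("11" = 20L, "10" = 5L, "00" = 10L),
    s2 = c("00" = 12L, "01" = 3L)))
  cfg <- epihaplo_config(rarefaction_depths = c(5L, 10L, 15L, 35L),
                         rarefaction_iterations = 8)
  ar <- alpha_rarefaction(t, cfg)
  # s2 (total 15) has no cells at depth 35
  expect_false(any(ar$values$sample == "s2" & ar$values$depth == 35))
  # at depth == total, no subsampling: iteration variance is zero
  full <- ar$values[ar$values$sample == "s1" & ar$values$depth == 35 &
                    ar$values$metric == "observed_profiles", ]
  expect_equal(nrow(full), 8L)
  expect_equal(var(full$value), 0)
  expect_equal(full$value[1], 3)
  # monotonicity of mean observed profiles in depth
  m <- aggregate(value ~ depth,
                 ar$values[ar$values$metric == "observed_profiles" &
                           ar$values$sample == "s1", ], mean)
  expect_true(all(diff(m$value[order(m$depth)]) >= 0))
  # same seed, same values
  ar2 <- alpha_rarefaction(t, cfg)
  expect_equal(ar$values, ar2$values)
})

test_that("group curves carry normal-approximation confidence half-widths", {
  t <- merge_sample_counts(list(
    a1 = c("11" = 20L, "10" = 5L), a2 = c("11" = 15L, "00" = 10L),
    b1 = c("00" = 25L), b2 = c("00" = 20L, "01" = 2L)))
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  cfg <- epihaplo_config(rarefaction_depths = c(10L), rarefaction_iterations = 5)
  ar <- alpha_rarefaction(t, cfg, groups)
  gc <- ar$group_curves
  expect_setequal(unique(gc$group), c("A", "B"))
  row <- gc[gc$group == "A" & gc$metric == "observed_profiles", ]
  agg <- aggregate(value ~ sample,
                   ar$values[ar$values$metric == "observed_profiles" &
                             ar$values$sample %in% c("a1", "a2"), ], mean)
  expect_equal(row$mean, mean(agg$value))
  expect_equal(row$ci_halfwidth,
               qnorm(0.975) * sd(agg$value) / sqrt(2))
  expect_error(alpha_rarefaction(t, cfg, groups[-1]), "a1")
})

test_that("Bray-Curtis matches its definition and vegan", {
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(6, 0, 2), c(2, 4, 2)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "zero")

  set.seed(64)
  for (k in 1:50) {
    x <- rpois(6, 3); y <- rpois(6, 3)
    if (sum(x) + sum(y) == 0) next
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
    if (requireNamespace("vegan", quietly = TRUE))
      expect_equal(d, as.numeric(vegan::vegdist(rbind(x, y), "bray")))
  }
})

test_that("PCoA reconstructs Euclidean distances and the 2-sample closed form", {
  set.seed(65)
  for (k in 1:10) {
    pts <- matrix(rnorm(12), ncol = 2,
                  dimnames = list(paste0("s", 1:6), NULL))
    D <- as.matrix(dist(pts))
    p <- pcoa(D)
    rec <- as.matrix(dist(p$coordinates))
    expect_lt(max(abs(rec - D)), 1e-8)
  }
  # two samples at distance d: coordinates +/- d/2, first eigenvalue d^2/2
  d <- 0.62
  D <- matrix(c(0, d, d, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- pcoa(D)
  expect_equal(sort(p$coordinates[, 1]), c(-d / 2, d / 2),
               ignore_attr = TRUE)
  expect_equal(p$eigenvalues[1], d^2 / 2)
  # identical samples: all eigenvalues zero
  p0 <- pcoa(matrix(0, 3, 3))
  expect_true(all(abs(p0$eigenvalues) < 1e-12))
  expect_true(all(p0$coordinates == 0))
})

test_that("PCoA agrees with classical cmdscale on Euclidean input", {
  set.seed(66)
  pts <- matrix(rnorm(10), ncol = 2)
  D <- as.matrix(dist(pts))
  p <- pcoa(D)
  cs <- cmdscale(D, k = 2, eig = TRUE)
  expect_equal(abs(p$coordinates[, 1:2]), abs(cs$points), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(p$eigenvalues[1:2], cs$eig[1:2], tolerance = 1e-10)
})

test_that("UPGMA merges at average-linkage heights with deterministic ties", {
  D <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u <- upgma(D)
  expect_equal(u$heights, c(1, 4))   # ultrametric node heights d/2
  expect_equal(u$merges$left, c("A", "A,B"))
  expect_equal(u$merges$right, c("B", "C"))
  expect_equal(u$order, c("A", "B", "C"))

  # all distances equal: tie-broken cascade, constant heights
  E <- matrix(1, 4, 4) - diag(4)
  dimnames(E) <- list(letters[1:4], letters[1:4])
  ue <- upgma(E)
  expect_true(all(ue$heights == 0.5))
  expect_equal(ue$merges$left[1], "a")
  expect_equal(ue$merges$right[1], "b")

  # two leaves: one merge at d/2
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(D2)$heights, 1.5)

  # heights are non-decreasing on random distance matrices,
  # and the size-weighted (UPGMA proper) heights match hclust "average"
  set.seed(67)
  for (k in 1:10) {
    pts <- matrix(rnorm(14), ncol = 2)
    D <- as.matrix(dist(pts))
    rownames(D) <- colnames(D) <- paste0("s", 1:7)
    u <- upgma(D)
    expect_true(all(diff(u$heights) >= -1e-12))
    h <- hclust(as.dist(D), method = "average")
    expect_equal(u$heights, h$height / 2, tolerance = 1e-12)
    expect_setequal(u$order, rownames(D))
  }
})

test_that("group distance pooling counts within and between pairs", {
  D <- matrix(0, 4, 4, dimnames = list(c("a1", "a2", "b1", "b2"),
                                       c("a1", "a2", "b1", "b2")))
  D["a1", "a2"] <- D["a2", "a1"] <- 0.1
  D["b1", "b2"] <- D["b2", "b1"] <- 0.2
  D["a1", "b1"] <- D["b1", "a1"] <- 0.8
  D["a1", "b2"] <- D["b2", "a1"] <- 0.9
  D["a2", "b1"] <- D["b1", "a2"] <- 0.7
  D["a2", "b2"] <- D["b2", "a2"] <- 0.6
  gd <- group_distances(D, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_length(gd$within, 2L)
  expect_length(gd$between, 4L)
  expect_setequal(gd$within, c(0.1, 0.2))
  expect_equal(mean(gd$between), 0.75)
  expect_error(group_distances(D, c(a1 = "A")), "a2")
})

test_that("the beta pipeline rarefies to the minimum depth and is seeded", {
  t <- merge_sample_counts(list(
    s1 = c("11" = 30L, "10" = 10L), s2 = c("00" = 15L, "11" = 5L),
    s3 = c("00" = 18L, "01" = 2L)))
  cfg <- epihaplo_config(rng_seed = 7)
  b <- beta_pipeline(t, cfg)
  expect_equal(unname(colSums(b$rarefied)), rep(20, 3))
  expect_equal(b$distance, t(b$distance))
  expect_true(all(diag(b$distance) == 0))
  b2 <- beta_pipeline(t, cfg)
  expect_equal(b$distance, b2$distance)
  expect_error(beta_pipeline(merge_sample_counts(list(s = c("1" = 3L)))),
               "at least 2")
})
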