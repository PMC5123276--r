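random_table <- function(n_samples = NULL) {
  ncpg <- sample(2:6, 1)
  npro <- sample(1:8, 1)
  profs <- unique(vapply(seq_len(npro), function(i)
    paste(sample(0:1, ncpg, replace = TRUE), collapse = ""), ""))
  if (is.null(n_samples)) n_samples <- sample(1:5, 1)
  m <- matrix(rpois(length(profs) * n_samples, 3), nrow = length(profs),
              dimnames = list(profs, paste0("s", seq_len(n_samples))))
  m[rowSums(m) > 0, , drop = FALSE]
  profile_table(m, region_id = "rt")
}

test_that("merging per-sample counts unions profiles and keeps column sums", {
  t <- merge_sample_counts(list(s1 = c("11" = 2L), s2 = c("00" = 3L)), "r")
  expect_equal(dim(t$counts), c(2L, 2L))
  expect_equal(sum(t$counts > 0) / length(t$counts), 0.5)
  expect_equal(colSums(t$counts), c(s1 = 2, s2 = 3))
  # rows sorted by (methylation class, profile)
  expect_equal(t$profiles, c("00", "11"))
  expect_equal(t$n_meths, c(0L, 2L))

  single <- merge_sample_counts(list(only = c("10" = 4L, "01" = 1L)))
  expect_equal(single$counts[, "only"], c("01" = 1L, "10" = 4L))

  twin <- merge_sample_counts(list(a = c("1" = 2L), b = c("1" = 2L)))
  expect_equal(twin$counts[, "a"], twin$counts[, "b"])

  expect_error(merge_sample_counts(list(a = c("11" = 1L), b = c("0" = 1L))),
               "inconsistent profile lengths")
})

test_that("merge then split by column reproduces the input maps", {
  set.seed(51)
  for (k in 1:20) {
    ncpg <- sample(2:5, 1)
    maps <- lapply(1:3, function(i) {
      profs <- unique(replicate(sample(1:6, 1),
        paste(sample(0:1, ncpg, replace = TRUE), collapse = "")))
      stats::setNames(sample(1:9, length(profs), replace = TRUE), profs)
    })
    names(maps) <- paste0("s", 1:3)
    t <- merge_sample_counts(maps)
    for (s in names(maps)) {
      col <- t$counts[, s]
      col <- col[col > 0]
      expect_equal(col[sort(names(maps[[s]]))],
                   maps[[s]][sort(names(maps[[s]]))])
    }
  }
})

test_that("BIOM write/read is the identity on tables", {
  t <- merge_sample_counts(list(s1 = c("11" = 2L), s2 = c("00" = 3L)), "r")
  f <- tempfile(fileext = ".biom")
  write_biom(t, f)
  t2 <- read_biom(f)
  expect_equal(t2$counts, t$counts)
  expect_equal(t2$profiles, t$profiles)
  expect_equal(t2$sample_ids, t$sample_ids)
  expect_equal(t2$n_meths, t$n_meths)
  expect_equal(t2$region_id, "r")

  # the sparse triple for observation "11" (row 1 by class sort is "00")
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(doc$matrix_type, "sparse")
  trips <- vapply(doc$data, function(x) paste(unlist(x), collapse = ","), "")
  expect_true("1,0,2" %in% trips)  # "11" is row index 1 (0-based), s1 col 0
  tax <- doc$rows[[2]]$metadata$taxonomy
  expect_equal(unlist(tax), c("class_2", "11"))

  # empty table round-trips
  e <- profile_table(matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("a", "b"))), "empty")
  write_biom(e, f)
  e2 <- read_biom(f)
  expect_length(e2$profiles, 0L)
  expect_equal(e2$sample_ids, c("a", "b"))
})

test_that("BIOM round-trip identity holds on random tables", {
  set.seed(52)
  for (k in 1:30) {
    t <- random_table()
    f <- tempfile(fileext = ".biom")
    write_biom(t, f)
    t2 <- read_biom(f)
    expect_equal(t2$counts, t$counts)
    expect_equal(t2$profiles, t$profiles)
    expect_equal(t2$n_meths, t$n_meths)
    unlink(f)
  }
})

test_that("our BIOM files parse with the independent biomformat reader", {
  skip_if_not_installed("biomformat")
  set.seed(53)
  t <- random_table(n_samples = 3)
  f <- tempfile(fileext = ".biom")
  write_biom(t, f)
  b <- biomformat::read_biom(f)
  m <- as(biomformat::biom_data(b), "matrix")
  expect_equal(m[t$profiles, t$sample_ids], t$counts,
               ignore_attr = TRUE)
})

test_that("malformed BIOM documents are rejected naming the missing key", {
  f <- tempfile(fileext = ".biom")
  writeLines('{"format": "x", "type": "OTU table"}', f)
  expect_error(read_biom(f), "matrix_type")
})

test_that("table summaries report counts, density and spread", {
  t <- merge_sample_counts(list(s1 = c("11" = 2L), s2 = c("00" = 3L)), "r")
  s <- summary(t)
  expect_equal(s$n_samples, 2L)
  expect_equal(s$n_observations, 2L)
  expect_equal(s$total_count, 5L)
  expect_equal(s$density, 0.5)
  expect_equal(s$min, 2); expect_equal(s$max, 3); expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sd(c(2, 3)))

  e <- profile_table(NULL, "empty")
  se <- summary(e)
  expect_equal(se$n_observations, 0L)
  expect_equal(se$total_count, 0L)
  expect_equal(se$density, 0)

  one <- merge_sample_counts(list(s = c("1" = 4L)))
  so <- summary(one)
  expect_equal(so$n_observations, 1L)
  expect_equal(so$density, 1.0)
})

test_that("class composition gives per-sample fractions summing to one", {
  t <- merge_sample_counts(list(s1 = c("11" = 2L, "00" = 2L)))
  comp <- class_composition(t)
  expect_equal(comp["class_0", "s1"], 0.5)
  expect_equal(comp["class_2", "s1"], 0.5)
  expect_equal(comp["class_1", "s1"], 0)

  t <- merge_sample_counts(list(s = c("10" = 1L, "01" = 1L)))
  expect_equal(class_composition(t)["class_1", "s"], 1.0)

  t <- merge_sample_counts(list(s = c("11" = 1L, "10" = 1L, "00" = 2L)))
  comp <- class_composition(t)
  expect_equal(unname(comp[, "s"]), c(0.5, 0.25, 0.25))

  set.seed(54)
  for (k in 1:10) {
    t <- random_table()
    comp <- class_composition(t)
    expect_true(all(abs(colSums(comp) - 1) < 1e-12))
  }
})
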