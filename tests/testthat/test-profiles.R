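cfg <- epihaplo_config()

test_that("bisulfite efficiency counts T/(T+C) over assayable non-CpG Cs", {
  reg <- noncpg_only_region(10L)   # "CAT" x 10, non-CpG Cs at 1,4,...,28
  bis <- reg$bis_ref               # "TAT" x 10

  # full conversion: T at every non-CpG C
  a <- manual_alignment(bis, bis)
  e <- compute_efficiency(a, reg)
  expect_equal(e$bis_efficiency, 1.0)
  expect_equal(e$assayed_fraction, 1.0)

  # 9 T, 1 C
  read <- paste0("C", substr(bis, 2, nchar(bis)))
  e <- compute_efficiency(manual_alignment(read, bis), reg)
  expect_equal(e$bis_efficiency, 0.9)
  expect_equal(e$assayed_fraction, 1.0)

  # 7 T, 1 C, 2 gaps: gaps excluded from the assay
  chars <- strsplit(bis, "")[[1]]
  chars[1] <- "C"; chars[4] <- "-"; chars[7] <- "-"
  e <- compute_efficiency(manual_alignment(paste(chars, collapse = ""), bis), reg)
  expect_equal(e$bis_efficiency, 0.875)
  expect_equal(e$assayed_fraction, 0.8)

  # uncovered reference positions count against the assayed fraction
  e <- compute_efficiency(manual_alignment(substr(bis, 4, 15),
                                           substr(bis, 4, 15),
                                           ref_start = 4L), reg)
  expect_equal(e$assayed_fraction, 0.4)  # positions 4,7,10,13 of 10 Cs
  expect_equal(e$bis_efficiency, 1.0)
})

test_that("quality filtering checks the assayed fraction before efficiency", {
  cfg98 <- epihaplo_config(bis_efficiency_min = 0.98,
                           assayed_fraction_min = 0.5)
  expect_true(filter_call(0.98, 1.0, cfg98)$pass)        # boundary passes
  f <- filter_call(0.979, 1.0, cfg98)
  expect_false(f$pass); expect_equal(f$fail_reason, "low_efficiency")
  f <- filter_call(1.0, 0.4, cfg98)
  expect_false(f$pass); expect_equal(f$fail_reason, "low_assayed_fraction")
  # undefined efficiency is a coverage failure, not an efficiency failure
  f <- filter_call(NA_real_, 0, cfg98)
  expect_false(f$pass); expect_equal(f$fail_reason, "low_assayed_fraction")
  # order: a read failing both is reported as low_assayed_fraction
  f <- filter_call(0.5, 0.1, cfg98)
  expect_equal(f$fail_reason, "low_assayed_fraction")
})

test_that("CpG profile calling codes C/T/other as 1/0/2", {
  reg <- region("one", "ACGTACGT", "TTGGCCAA", "TTCGT")
  bis <- reg$bis_ref
  expect_equal(bis, "TTCGT")
  expect_equal(call_profile(manual_alignment("TTCGT", bis), reg), 1L)
  expect_equal(call_profile(manual_alignment("TTTGT", bis), reg), 0L)
  expect_equal(call_profile(manual_alignment("TT-GT", bis), reg), 2L)
  expect_equal(call_profile(manual_alignment("TTAGT", bis), reg), 2L)
  # CpG site outside the aligned span is unassessable
  expect_equal(call_profile(manual_alignment("GT", "GT", ref_start = 4L), reg), 2L)
})

test_that("site statistics tally calls per position", {
  reg <- region("one", "ACGTACGT", "TTGGCCAA", "TTCGT")
  bis <- reg$bis_ref
  reads <- c("TTCGT", "TTCGT", "TTTGT", "TTAGT")
  pc <- call_reads(structure(reads, names = paste0("r", 1:4)), reg,
                   epihaplo_config(assayed_fraction_min = 0))
  st <- accumulate_site_stats(pc, reg)
  expect_equal(st$n_pass_reads, 4L)
  expect_equal(st$cpg$methylated, 2L)
  expect_equal(st$cpg$unmethylated, 1L)
  expect_equal(st$cpg$ambiguous, 1L)
  expect_equal(st$cpg$percent_methylated, 100 * 2 / 3)

  # no passing reads: percentages undefined
  pc0 <- call_reads(structure(character(0), names = character(0)), reg, cfg)
  st0 <- accumulate_site_stats(pc0, reg)
  expect_equal(st0$n_pass_reads, 0L)
  expect_true(all(is.na(st0$cpg$percent_methylated)))
})

test_that("profile counting excludes uncertain profiles from the 2^N space", {
  mk_call <- function(prof) list(read_id = "x", profile = prof, pass = TRUE,
                                 bis_efficiency = 1, assayed_fraction = 1,
                                 fail_reason = "none")
  pc <- structure(list(calls = list(mk_call(c(1L, 1L)), mk_call(c(1L, 1L)),
                                    mk_call(c(0L, 0L)))),
                  class = "profile_calls")
  r <- count_profiles(pc)
  expect_equal(r$counts, c("00" = 1L, "11" = 2L)[names(r$counts)])
  expect_equal(sort(names(r$counts)), c("00", "11"))
  expect_equal(r$ambiguous_read_count, 0L)

  pc <- structure(list(calls = list(mk_call(c(1L, 2L)))),
                  class = "profile_calls")
  r <- count_profiles(pc)
  expect_length(r$counts, 0L)
  expect_equal(r$ambiguous_read_count, 1L)

  pc <- structure(list(calls = list()), class = "profile_calls")
  r <- count_profiles(pc)
  expect_length(r$counts, 0L)
  expect_equal(r$ambiguous_read_count, 0L)
})

test_that("calling outcomes conserve the input reads", {
  reg <- example_region()
  sp <- synth_spec(reg, c("11001100" = 1.0), n_reads = 120,
                   conversion_rate = 0.95, substitution_rate = 0.01,
                   indel_rate = 0.002, seed = 77)
  sr <- synth_generate(sp)
  dm <- demultiplex_reads(sr$reads, list(reg), cfg, "s")
  pc <- call_reads(dm$by_region[[1]], reg, cfg)
  expect_equal(nrow(pc$log), length(dm$by_region[[1]]))
  allowed <- c("counted", "ambiguous_profile", "align_failed",
               "low_assayed_fraction", "low_efficiency")
  expect_true(all(pc$log$outcome %in% allowed))
  cp <- count_profiles(pc)
  expect_equal(sum(cp$counts) + cp$ambiguous_read_count,
               sum(pc$log$outcome %in% c("counted", "ambiguous_profile")))
})

test_that("profile matrix and abundance reports have the documented layout", {
  reg <- region("one", "ACGTACGT", "TTGGCCAA", "TTCGTACGA")
  pc <- call_reads(c(r1 = "TTCGTACGA", r2 = "TTTGTATGA"), reg,
                   epihaplo_config(assayed_fraction_min = 0))
  mpath <- tempfile()
  write_profile_matrix(pc, reg, mpath)
  lines <- readLines(mpath)
  expect_equal(lines[1], "read_id\tCpG_3\tCpG_7")
  expect_equal(lines[2], "r1\t1\t1")
  expect_equal(lines[3], "r2\t0\t0")

  apath <- tempfile()
  write_abundance_tab(c("11" = 2L, "01" = 1L), "s1", apath)
  df <- read.delim(apath)
  expect_equal(names(df), c("id", "profile", "count", "n_meths"))
  expect_equal(df$n_meths, c(1L, 2L))  # sorted by methylation class
})
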