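# Shared fixtures and independent oracles.  Oracles are deliberately
# written as plain, slow R so they share no code with the package
# implementation they check.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a small non-repetitive region with CpGs and non-CpG Cs in known places
toy_region <- function() {
  # ref:      T A C G T C A T T C G A C T G
  # CpG Cs at 3 and 10; non-CpG Cs at 6 and 13
  region("toy", fw_primer = "ACGTACGT", rv_primer = "TTGGCCAA",
         ref_seq = "TACGTCATTCGACTG")
}

# a region whose reference is n_c copies of "CAT": n_c non-CpG Cs, no CpGs
noncpg_only_region <- function(n_c = 10L) {
  region("flat", fw_primer = "ACGTACGT", rv_primer = "TTGGCCAA",
         ref_seq = strrep("CAT", n_c))
}

# hand-build a bis_alignment (for calling tests that bypass the aligner)
manual_alignment <- function(aln_read, aln_ref, ref_start = 1L,
                             read_id = "r") {
  ref_len <- nchar(gsub("-", "", aln_ref, fixed = TRUE))
  structure(list(read_id = read_id, aln_read = aln_read, aln_ref = aln_ref,
                 ref_start = ref_start, ref_end = ref_start + ref_len - 1L,
                 score = 0L, ok = TRUE),
            class = "bis_alignment")
}

# --- primer-similarity oracle: minimum Levenshtein distance between the
# primer and every substring of the window, via utils::adist -------------
oracle_primer_distance <- function(window, primer) {
  n <- nchar(window)
  best <- nchar(primer)  # align primer against the empty substring
  for (i in seq_len(n)) for (j in i:n) {
    d <- utils::adist(primer, substr(window, i, j))[1, 1]
    if (d < best) best <- d
  }
  best
}

# --- alignment score oracles -------------------------------------------
# plain-R three-state affine DP, semi-global (read global, ref ends free);
# score only
oracle_align_score <- function(read, ref, match = 2L, mismatch = -3L,
                               gap_open = -5L, gap_extend = -2L) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  f <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(r); m <- length(f)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- gap_open + (i - 2) * gap_extend
    for (j in 1:(m + 1)) {
      if (j > 1) {
        s <- if (r[i - 1] == f[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
        Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend)
      }
      cand <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend)
      X[i, j] <- max(X[i, j], cand)
    }
  }
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ])
}

# exhaustive enumeration oracle: tries every reference substring (and the
# empty one) and every monotone alignment path, scoring gaps affinely.
# Only usable for tiny strings.
oracle_align_enumerate <- function(read, ref, match = 2L, mismatch = -3L,
                                   gap_open = -5L, gap_extend = -2L) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  score_pair <- function(a, b) {   # global alignment of r vs b, enumerated
    rec <- function(i, j, prev) {
      if (i > length(a) && j > length(b)) return(0)
      best <- -Inf
      if (i <= length(a) && j <= length(b)) {
        s <- if (a[i] == b[j]) match else mismatch
        best <- max(best, s + rec(i + 1, j + 1, "M"))
      }
      if (i <= length(a)) {
        g <- if (identical(prev, "X")) gap_extend else gap_open
        best <- max(best, g + rec(i + 1, j, "X"))
      }
      if (j <= length(b)) {
        g <- if (identical(prev, "Y")) gap_extend else gap_open
        best <- max(best, g + rec(i, j + 1, "Y"))
      }
      best
    }
    rec(1, 1, "none")
  }
  f <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- length(f)
  best <- score_pair(r, character(0))
  for (i in seq_len(m)) for (j in i:m)
    best <- max(best, score_pair(r, f[i:j]))
  best
}

# --- synthetic two-group study used by pipeline-level tests -------------
make_two_group_study <- function(dir, n_reads = 300L, seed0 = 100L,
                                 conversion = 0.99, sub = 0.003,
                                 indel = 5e-4) {
  reg <- example_region()
  mixA <- c("11111111" = 0.6, "11110000" = 0.3, "10000000" = 0.1)
  mixB <- c("00000000" = 0.6, "00001111" = 0.3, "00000001" = 0.1)
  fastas <- character(0); truths <- list()
  k <- 0L
  for (g in c("A", "B")) for (i in 1:3) {
    k <- k + 1L
    s <- sprintf("%s%d", g, i)
    sp <- synth_spec(reg, if (g == "A") mixA else mixB, n_reads = n_reads,
                     conversion_rate = conversion, substitution_rate = sub,
                     indel_rate = indel, seed = seed0 + k)
    sr <- synth_generate(sp)
    f <- file.path(dir, paste0(s, ".fasta"))
    write_synth_fasta(sr, f)
    fastas[s] <- f
    truths[[s]] <- sr$truth
  }
  list(region = reg, fastas = fastas, truths = truths,
       groups = stats::setNames(rep(c("A", "B"), each = 3),
                                names(fastas)))
}
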