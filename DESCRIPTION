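Package: epihaplo
Title: Epihaplotype Extraction and Diversity Analysis for Targeted
    Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts single-molecule CpG methylation profiles
    (epihaplotypes) from merged, quality-filtered reads of targeted deep
    bisulfite amplicon sequencing, with no external aligner dependency.
    Reads are demultiplexed by PCR primer matching, oriented, length
    filtered, aligned to an in-silico bisulfite-converted reference with
    an exact affine-gap semi-global aligner, screened by per-read
    bisulfite conversion efficiency, and coded as ternary CpG methylation
    profiles.  Per-sample epihaplotype abundances are merged into a
    sparse contingency table serialized as BIOM 1.0 JSON, and analyzed
    with ecology-style statistics: rarefaction with five alpha-diversity
    metrics (observed profiles, Shannon entropy, Simpson index, Chao1,
    singletons), Bray-Curtis beta diversity, principal coordinates
    analysis, UPGMA clustering, and within/between-group distance
    summaries.  A seedable synthetic-read generator with ground-truth
    bookkeeping supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    biomformat
Config/testthat/edition: 3
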