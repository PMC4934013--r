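Package: riboscope
Title: Analysis Toolkit for Ligation-Free Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("riboscope", "developers", email = "riboscope@example.org",
           role = c("aut", "cre"))
Description: Reusable implementation of the computational analysis behind
    ligation-free (template-switching) ribosome profiling of complex tissue:
    read-structure preprocessing (fixed trimming, poly(A) clipping, rRNA
    subtraction, transcriptome mapping, duplicate marking), library quality
    control (3-nt periodicity power spectrum, gene-body distribution,
    saturation under downsampling), translation-efficiency quantification
    with median-of-ratios normalization, RiboTag IP enrichment scoring,
    cell-type enrichment scores with pre-ranked permutation GSEA over
    TE-binned gene sets, 5' UTR / uAUG feature analysis, and differential-TE
    analysis with TOP-motif overlap. A synthetic-data generator emulating the
    statistical structure of brain ribosome profiling data makes every stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
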