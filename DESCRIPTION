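Package: poolscan
Title: Pool-Seq FST Genome Scans, Candidate-Set Permutation Tests, and
    Hemocyte Phagocytosis Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-population pooled-sequencing genome scans:
    reading Popoolation2-style sync allele-count files, indel and
    non-genic masking, biallelic SNP calling, Nei-style fixation-index
    (FST) estimation at SNP, gene and 5 kb flanking-region level,
    candidate-gene-set permutation tests against resampled random sets,
    empirical-percentile outlier selection, and hypergeometric
    (Fisher) term-enrichment among outliers. Also computes insect
    hemocyte immune-assay indices (hemocytometer concentration,
    phagocytic index, specific phagocytic index) from tidy cell-count
    tables, and ships a Balding-Nichols synthetic-data generator that
    produces every input the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    withr,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
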