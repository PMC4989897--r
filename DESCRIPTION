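Package: ecgi
Title: Identification of CpG-Island Enhancers and Their Tumorigenic Hypermethylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies CpG islands into promoter, noncoding-promoter,
    enhancer (eCGI) and inactive-orphan classes from H3K27ac/DNase
    hypersensitivity peaks and transcription-start evidence; assigns
    enhancer target genes from ChIA-PET chromatin interactions; tests
    transcription-regulator targeting by random-segment permutation and
    tumor-suppressor enrichment by Fisher's exact test; and quantifies
    differential DNA methylation of enhancer CpG islands together with
    silencing of their target genes. Ships a synthetic-data generator with
    planted ground truth so the full workflow is testable offline, plus an
    end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
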