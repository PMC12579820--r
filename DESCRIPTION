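Package: ighclonal
Title: IGH Clonality Analysis for B-Cell Precursor Leukemia Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of immunoglobulin heavy chain (IGH) clonality from
    per-sample clone tables, as produced by RNA-seq repertoire aligners.
    Merges complete VDJ rearrangements that share a DJ junction into ongoing
    rearrangement clones using a Poisson co-occurrence test, fits a discrete
    power law to clone abundances by maximum likelihood with data-driven
    lower-boundary selection, calls leukemic disease clones as e-value
    outliers, classifies patients into UDC/IDC/CDC clonotypes, quantifies
    repertoire diversity (Shannon entropy) and diagnosis-to-relapse overlap
    (Morisita-Horn index), classifies per-clone evolution patterns between
    diagnosis and relapse, and runs cohort-level association statistics.
    Includes a seeded synthetic-repertoire generator with ground truth for
    validating the detection pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
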