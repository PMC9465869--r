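Package: clonotrace
Title: Tracking Vaccine-Enriched T Cell Receptor Clonotypes Across Blood and Tumor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of bulk T cell receptor beta-chain (TRB) repertoires for
    longitudinal immunomonitoring of therapeutic cancer vaccination. Reads
    AIRR-style rearrangement tables, collapses receptor reads into CDR3
    amino-acid clonotypes, normalizes sequencing depth by seeded downsampling
    (multivariate hypergeometric), and computes repertoire diversity,
    Shannon-entropy clonality, clonotype overlap and repertoire fractions.
    Identifies clones significantly expanded after in vitro peptide
    stimulation with a depth-matched two-sided Fisher exact test and
    Benjamini-Hochberg correction, filters out clones already present at
    baseline, and tracks the resulting vaccine-enriched clonotypes across
    later blood samples and tumor biopsies. Includes a stimulation-index
    immune-response caller for triplicate lymphocyte proliferation assays and
    a synthetic-data generator (Zipf clone-size distributions, longitudinal
    persistence, blood-tumor sharing, stimulation spike-ins with known fold
    changes) so that every pipeline stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
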