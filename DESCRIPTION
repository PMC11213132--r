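Package: NeoTier
Title: Tiered Prioritization of Neoantigen Candidates from Ensemble MHC
    Binding Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational engine for prioritizing tumor neoantigen
    candidates. Enumerates all mutant/wild-type short-peptide registers
    arising from somatic missense, in-frame indel and frameshift variants
    across configurable peptide lengths; groups transcripts into sets by
    identical peptide repertoires; aggregates per-algorithm MHC class I/II
    binding predictions (IC50 and percentile rank) into per-peptide medians
    and minima; assigns each variant a suitability tier from binding
    affinity, allele expression, transcript support level, clonality and
    allele-specific anchor-position scenarios; and reads/writes the
    aggregate report (TSV) and metrics (JSON) formats with evaluation
    round-trip, supplementary-class merging and gene-of-interest flagging.
    Includes a deterministic synthetic-data generator so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
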