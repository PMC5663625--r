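Package: clusrm
Title: Constraint-Based Redescription Mining on Two-View Data with Missing Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tree-based redescription mining for two-view tabular data
    (CLUS-RM): multi-target predictive clustering trees generate conjunctive
    queries on each view, queries are alternately re-described across views,
    and quality-filtered query pairs are maintained in a bounded redescription
    set optimised against accuracy and instance/attribute redundancy scores.
    Supports data with missing values through a three-valued query semantics
    and the query non-missing Jaccard index, strict/soft/suggested attribute
    constraint modes, query minimisation, a synthetic two-view benchmark
    generator with planted redescriptions, and post-hoc redescription-set
    analytics (support-set label entropy, attribute co-occurrence tables,
    normality-screened correlation reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
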