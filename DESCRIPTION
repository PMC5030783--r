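Package: oralbiofilm
Title: Quantification of Ex Vivo Oral Biofilm Viability and Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for native oral biofilm transferred from
    the mouth into a flow reactor. Implements live/dead viability analysis of
    two-channel confocal z-stacks (exact 1-D k-means background removal,
    large-component yeast exclusion, double-label reassignment, per-subject
    survival series across four time points) and paired T0-versus-T3
    compositional-shift analysis of OTU count tables (common-OTU filtering,
    relative abundance, taxonomy collapse, paired Wilcoxon signed-rank tests
    with Bonferroni correction, zero-exclusion log2 fold changes, heat-map
    matrix export). A synthetic-data module generates both input kinds with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
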