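Package: acetoprot
Title: Post-Processing of Metaproteomic Protein-Group Tables from
    Vinegar Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream processing of label-free LC-MS/MS protein-group
    exports from submerged vinegar fermentations dominated by acetic acid
    bacteria. Provides identification-quality and replicate-presence
    filtering, global-sample-intensity normalization, taxonomic and GO-term
    frequency profiling, Pearson-distance complete-linkage hierarchical
    clustering with heat-map export, per-protein one-way ANOVA with
    Tukey-Kramer post-hoc tests and Storey q-value correction, UpSet-style
    intersection analysis, and a synthetic-data generator with planted
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
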