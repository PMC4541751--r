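Package: vaersnet
Title: Vaccine-Adverse-Event Association Networks from Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Signal detection and network analysis for spontaneous
    vaccine adverse-event reporting data in the VAERS three-table CSV
    dialect. Computes stratified proportional reporting ratios (overall,
    per reporting year, per sex), builds bipartite vaccine-adverse-event
    association networks from disproportionally reported pairs,
    characterizes them (average degree, average path length, diameter),
    projects them onto vaccines with a Pearson-correlation association
    index for hierarchical clustering and cross-sex comparison, and
    exports association summaries as RDF. Includes a synthetic report
    generator with planted, optionally sex-specific, associations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
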