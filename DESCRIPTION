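Package: keynodes
Title: Validation of Network Centrality Measures for Key Node Identification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes five classical centrality measures (degree, betweenness,
    closeness, eccentricity, eigenvector) from first principles on undirected
    simple graphs, and scores how well each measure recovers nodes documented
    as influential. Ships the classic benchmark networks (Zachary karate club,
    Doubtful Sound dolphins, C. elegans neural network) as plain-text fixtures,
    a seeded Erdos-Renyi baseline generator, planted-structure generators with
    known ground truth, cross-measure rank-correlation and top-k concordance
    reports, and a susceptible-infected diffusion probe that relates seed
    centrality to spreading speed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
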