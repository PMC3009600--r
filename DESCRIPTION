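Package: compevo
Title: Compensatory Evolution of Dispersed G+C and Nucleosome-Occupancy Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting compensatory evolution of
    dispersed G+C content encodings such as the DNA-encoded nucleosome
    organization of yeast intergenic sequences. Provides a synthetic-data
    generator (context-dependent sequence evolution on a fixed phylogeny,
    occupancy tracks anti-correlated with A+T content, planted compensatory
    substitution pairs, selection-tilted SNP panels), genome partitioning by
    nucleosome occupancy and TSS proximity, inference of per-lineage
    flanking-context-dependent substitution rates and ancestral states by
    loopy belief propagation with generalized EM, a spatial gain/loss
    coupling statistic with a bootstrap significance test, a Wright-Fisher
    forward model of selection on G+C content with its analytic birth-death
    stationary approximation, and SNP minor-allele-frequency selection
    signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
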