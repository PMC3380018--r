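Package: phylosvm
Title: Composition-Based Hierarchical Taxonomic Assignment of Metagenome
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomic binning of metagenome sequence fragments (contigs and
    scaffolds) by genomic signature. Fragments are represented as
    length-normalized k-mer composition vectors (k = 4, 5, 6) and classified
    onto a reference taxonomy by an ensemble of linear structured-output
    support vector machines trained with a margin-rescaled cutting-plane
    algorithm whose loss is the geodesic (edge-count) distance between
    taxonomy nodes. Supports generic models built from labelled reference
    genomes and sample-specific models that pool roughly 100 kb of
    user-labelled sequence per expected population with the reference data
    under a user-defined taxonomy. Includes the standard binning evaluation
    statistics (fragment- and base-pair-weighted consistency, taxonomic
    distance, per-rank accuracy with micro and macro averages), a synthetic
    community generator based on hierarchically perturbed Markov composition
    models for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
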