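Package: parasym
Title: Evolutionary Rates and Asymmetry of Recently Duplicated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the early evolution of paralogous gene
    families from in-frame coding sequences. Implements Nei-Gojobori (1986)
    counting of synonymous and non-synonymous sites and differences with
    Jukes-Cantor correction, sequence-identity single-linkage clustering of
    genes into families, per-gene ("individual") dN and dS rates from
    sister/cousin triplets via the three-point formula, detection of
    asymmetrically evolving paralog pairs by outgroup-parsimony substitution
    assignment and exact binomial tests (with a genome-scale binomial
    meta-test), and dN/dS-versus-dS trend regression. Includes a calibrated
    codon-level gene-family simulator with per-branch control of the
    synonymous rate and of dN/dS, so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
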