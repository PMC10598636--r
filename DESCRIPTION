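Package: mitoforma
Title: Repeat-Mediated Recombination, SSR, MTPT and RNA-Editing Analysis of
    Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the structural dynamics of plant
    mitochondrial genomes from assembled sequence and long reads: discovery of
    dispersed repeat pairs by self-alignment, in-silico construction of the
    four local conformations around each repeat, classification of long reads
    spanning a repeat and estimation of the recombination frequency with
    Wilson confidence intervals, MISA-compatible microsatellite (SSR)
    scanning, detection of plastid-derived insertions (MTPTs) by reciprocal
    homology search, and C-to-U RNA-editing calling from paired gDNA/cDNA
    sequences with codon-effect classification. A seeded synthetic-data
    generator produces circular multichromosomal genomes, conformational
    mixtures and error-prone long reads with full truth manifests for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: NCBI BLAST+ (blastn, makeblastdb on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
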