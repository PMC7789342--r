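Package: ssrpipe
Title: Genome Survey Sequencing and SSR Marker Development Toolkit
Version: 0.1.0
Authors@R: person("ssrpipe", "developers", role = c("aut", "cre"),
    email = "ssrpipe@example.org")
Description: Tools for developing simple sequence repeat (SSR) markers from
    low-coverage genome survey sequencing and for evaluating them on diploid
    accession panels. Covers paired-end read quality filtering, k-mer spectrum
    genome-size/heterozygosity/repeat estimation, perfect-SSR mining with
    motif canonicalization, primer candidate design with nearest-neighbor
    melting temperatures, in-silico PCR single/multi-locus classification,
    and a population-genetics evaluation suite (allelic diversity, PIC,
    Nei distance, UPGMA with bootstrap, PCoA, AMOVA/PhiPT/Nm, Mann-Whitney).
    Includes seeded simulators for genomes with planted SSRs, paired-end
    reads, and structured genotype/band panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    optparse,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
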