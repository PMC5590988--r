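Package: insfill
Title: Insertion Genotyping by Gap Filling on de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotypes insertion variants by local assembly: given a reference
    genome, insertion breakpoints with length estimates, and paired-end reads,
    the inserted sequence is reconstructed as a path of prescribed length
    between the flanking k-mers in a de Bruijn graph, found with an exact
    path-length dynamic program. An insert-size-based read filter restricts
    the graph to reads likely to cover each insertion, with a coverage-based
    fallback to all unmapped reads. Includes a paired-end read simulator,
    truth-mode alignment projection, normalized edit-distance scoring, and
    readers/writers for FASTA, FASTQ, SAM and VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
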