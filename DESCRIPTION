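Package: biofilters
Title: Pipe-Composable Command-Line Filters for Sequences, Alignments,
    Allele Samples and Phylogenetic Trees
Version: 1.0.0
Authors@R:
    person("Maintainer", "Biofilters", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Four UNIX-style utilities -- bioseq, bioaln, biopop and
    biotree -- exposed both as R functions and as command-line filters
    that read and write standard streams, so they compose with the shell
    pipe operator.  Covers FASTA/GenBank sequence manipulation
    (summaries, reverse-complement, pick/delete, sub-sequences,
    translation, degapping, restriction digestion),
    CLUSTAL/FASTA/PHYLIP alignment handling (slicing, concatenation,
    codon-aware back-translation of protein alignments, bootstrap and
    site permutations), population statistics over aligned alleles
    (segregating sites, nucleotide diversity, Watterson's theta,
    mismatch distribution, coding-SNP classification) and Newick tree
    surgery (midpoint and outgroup rerooting, OTU deletion, subtree
    extraction, support-threshold collapsing, patristic distances,
    ASCII preview).  Includes seeded generators for synthetic test
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
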