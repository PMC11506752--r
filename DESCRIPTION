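Package: mitoprofile
Title: Characterization Statistics for Annotated Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing annotated circular mitochondrial
    genomes in the way fish mitogenomics studies report them: partitioned
    base composition with AT/GC strand skews, gene-layout arithmetic
    (intergenic nucleotides, overlaps, start/stop codon classification
    including incomplete termination codons), relative synonymous codon
    usage under the vertebrate mitochondrial code, Nei-Gojobori (1986)
    pathway-counting Ka/Ks with Jukes-Cantor correction, sliding-window
    nucleotide diversity, transition/transversion saturation against
    Kimura 2-parameter distance, control-region conserved sequence block
    (CSB) motif scanning, a transparent tRNA cloverleaf arm heuristic, and
    concatenated protein-coding-gene supermatrix export with partition
    files. A deterministic synthetic mitogenome generator reproduces the
    canonical 37-gene vertebrate layout so every analysis stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
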