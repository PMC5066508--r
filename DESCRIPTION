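Package: minihelix
Title: Three-Minihelix Model of Cloverleaf tRNA Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cloverleaf tRNA architecture under the
    three-minihelix model of tRNA origins, in which the conserved 75-nt
    tRNA core arises by ligation of three 31-nt proto-tRNA minihelices
    followed by two symmetrical 9-nt deletions within the joined acceptor
    stems. Provides the fixed 75-nt coordinate scheme and tRNA
    segmentation onto it (acceptor stems, D/anticodon/T microhelices,
    acceptor-stem relics), normalisation of modified-nucleotide codes,
    antiparallel Watson-Crick and wobble pair counting, microhelix fold
    checking and anticodon decoding, per-position frequency and
    information-content profiles with consensus calling, a generative
    ligation-deletion and snapback-replication simulator, Kabsch
    superposition of RNA backbone selections read from PDB files, and a
    seeded synthetic-data generator for archaeal-like tRNA sets and
    idealized hairpin coordinates with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
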