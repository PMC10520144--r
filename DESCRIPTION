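Package: circrearr
Title: Algebraic Rearrangement Models for Signed Circular Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact arithmetic for signed permutations of circular genomes
    (the hyperoctahedral group), with circular symmetry handled through
    dihedral cosets.  Genomes are left cosets of the dihedral subgroup,
    rearrangement events are double cosets, and applying an event to a
    genome yields an exact outcome distribution.  Includes constructors for
    inversions and transpositions, cut-set and breakpoint computation,
    exact counting of k-cut rearrangements and rearrangement actions
    (brute-force coset enumeration and closed forms), and rearrangement
    models that induce Markov chains on genome space.  Reads and writes
    GRIMM-style signed gene-order files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
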