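Package: karyoband
Title: Comparative Cytogenetics of Polytene Chromosome Banding Sequences
Version: 0.1.0
Authors@R:
    person("Karyoband", "Developers", email = "karyoband@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of polytene chromosome banding
    sequences in Chironomus-style karyotypes. Banding sequences written in
    Keyl interval notation are parsed into oriented band intervals, pairs of
    sequences are reduced to signed permutations of common blocks, and exact
    minimal inversion-step (signed reversal) distances are computed with the
    breakpoint-graph method, including optimal reversal scenarios. Karyotypes
    are classified into cytocomplexes from their whole-arm combinations,
    species sequence pools are summarised (pool size, polymorphic arms,
    cosmopolitan-basic versus endemic sequences), and per-arm inversion-step
    networks and neighbor-joining trees are exported in DOT, PHYLIP and
    Newick formats. A seeded synthetic-evolution generator produces arms,
    species and whole studies with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
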