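Package: RNAMotifFold
Title: Joint RNA Secondary Structure and 3D Motif Prediction from Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts RNA consensus secondary structure jointly with RNA 3D
    motifs (hairpin-loop, bulge, internal-loop, three- and four-way junction,
    and branch-segment motifs) over a multiple sequence alignment. A single
    stochastic context-free grammar models canonical helices together with a
    library of motif sub-grammars whose sequence segments are scored by
    profile hidden Markov models. Folding is constrained by covarying base
    pairs supplied by an external covariation analysis (or by a built-in
    approximate statistic), with non-nested covarying pairs handled in
    additional pseudoknot layers. Includes a synthetic alignment generator
    with planted covarying helices and planted motifs for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
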