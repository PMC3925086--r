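Package: pdnovo
Title: De Novo Peptide Sequencing by Path Decomposition of Spectrum Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: De novo peptide sequencing from tandem mass spectra using an
    extended spectrum graph model. Peaks become vertices, single-residue mass
    differences become directed edges, and complementary ion pairs (masses
    summing to the precursor residue mass) become non-directed edges. The
    sequencer computes the longest antisymmetric partial path with a dynamic
    program over a path decomposition of the graph, so spectra with missing
    peaks or post-translationally modified residues still yield a sequence:
    inter-segment mass gaps are resolved by subset-sum search over residue and
    modified-residue masses. Includes MGF and peak-list readers, spectrum
    preprocessing, a pathwidth heuristic with an exact branch-and-bound
    oracle, a spectrum simulator with grouped noise for benchmarking, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
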