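Package: defevol
Title: Molecular Evolution Toolkit for Primate Alpha- and Theta-Defensin Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the birth-and-death evolution of the primate
    alpha-/theta-defensin (DEFA/DEFT) multigene family. Classifies coding
    sequences into functional genes and pseudogenes (premature stops,
    frameshifts, and the theta-defining nonsense site), validates the
    cysteine motifs of alpha- and theta-defensin mature peptides and models
    theta-defensin maturation into a cyclic octadecapeptide. Implements the
    Nei-Gojobori (1986) counting method for Ka/Ks with pathway averaging and
    Jukes-Cantor correction, sliding-window selection scans along codon
    alignments, and a directional bootstrap significance test against
    neutrality. Converts type-I functional-divergence coefficients into
    functional distances and solves per-cluster functional branch lengths by
    least squares on a star topology. Extracts dimer flexibility metrics
    (interface C-alpha distances and a four-point dihedral) from multi-model
    coordinate files after interface superposition. A seeded synthetic-data
    generator produces codon families evolving under region-specific dN/dS on
    a known tree, pseudogenization lesions, and jittered dimer trajectories,
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
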