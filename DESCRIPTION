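Package: qsarligand
Title: Ligand-Based 2D/3D-QSAR Modelling for Small-Molecule Antagonist Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based quantitative structure-activity
    relationship (QSAR) modelling of small-molecule inhibitor series, built
    around a five-descriptor multiple-linear-regression model of TLR7
    antagonist potency. Implements the graph-theoretic 2D descriptors of the
    model from first principles (distance/detour matrix eigenvector sums,
    Burden-matrix eigenvalues weighted by Kier-Hall intrinsic states,
    P_VSA-style van der Waals surface-area bins over atomic logP, dipole
    weighted edge-adjacency eigenvalues, CATS2D acceptor pair counts),
    ordinary-least-squares model fitting with genetic-algorithm variable
    subset selection, the full internal and external validation suite
    (leave-one-out, leave-many-out, y-scrambling, Q2F1/F2/F3, concordance
    correlation, rm2 metrics), leverage-based applicability-domain analysis
    (Williams and Insubria plots), a simplified CoMFA-style grid-field
    3D-QSAR with NIPALS partial least squares, activity class and
    pharmacophore cost arithmetic, and a synthetic dataset generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
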