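Package: polyqens
Title: Chemical-Shift Secondary Structure Propensity and Ensemble
    Reweighting for PolyQ Flanking Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for chemical-shift-based structural analysis of
    intrinsically disordered polyglutamine (polyQ) proteins such as the
    ataxin-7 N-terminal fragment. Computes secondary chemical shifts and
    the (delta-Ca - delta-Cb) helicity indicator from assigned backbone
    shifts, windowed secondary-structure-propensity (SSP) scores on a
    -1 (strand) to +1 (helix) scale, simplex-constrained least-squares
    reweighting of a conformer pool against experimental shifts to obtain
    per-residue helix/strand/coil probabilities, and classification of
    slow-exchanging backbone amides from hydrogen/deuterium-exchange peak
    intensities. A seeded synthetic-data module generates sequences,
    dihedral-based conformer pools, ensemble-averaged shift tables and
    HDX decay series so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
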