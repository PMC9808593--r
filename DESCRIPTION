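Package: g4hand
Title: Torsion-Angle Classification of DNA Handedness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies left-handed versus right-handed G-quadruplex and
    duplex DNA from backbone and glycosidic torsion angles. Computes the six
    backbone torsions (alpha-zeta) and the glycosidic angle (chi) directly
    from PDB coordinates, assembles labelled per-nucleotide feature tables,
    trains entropy-based (ID3) decision trees with minimal cost-complexity
    pruning, evaluates them by repeated random holdout validation including
    a cross-family transfer experiment between quadruplex and duplex data,
    and summarises the feature space with two-component PCA. A synthetic
    torsion-profile generator emulating the class-conditional angle
    distributions of left- and right-handed quadruplexes, Z-DNA and B-DNA
    makes the whole pipeline runnable and testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    mgcv,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
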