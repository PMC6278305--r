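Package: cunirgeom
Title: Geometric Analysis of Nitrite Binding at Type-2 Copper Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising how the nitrite ion binds the catalytic
    type-2 copper (T2Cu) centre of copper-containing nitrite reductases.
    Builds a ligand-local orthonormal frame on the nitrite ion, computes the
    altitudinal and azimuthal angles (theta, psi) that classify the binding
    mode (N-bound, top-hat, side-on and their azimuthal subclasses), the
    coordination twist angle phi separating tetragonal from trigonal copper
    geometries, per-frame distance and hydrogen-bond metrics over trajectory
    snapshots, and the paired conformer energy-difference statistic used to
    compare top-hat and N-bound binding preferences. Includes a synthetic
    active-site generator with known ground truth so every analysis stage can
    be exercised without molecular-dynamics or quantum-chemistry machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
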