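Package: tdcssim
Title: Forward Modeling of Transcranial Direct Current Stimulation on Voxelized Head Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel finite-volume forward modeling of transcranial direct
    current stimulation (tDCS). Generates synthetic multi-tissue head phantoms
    (layered and gyrated spheres, slabs), rasterizes sponge-pad and 4x1
    high-definition electrode montages onto the scalp, solves the
    volume-conduction Laplace equation div(sigma grad V) = 0 with a
    preconditioned conjugate-gradient solver, and derives cortical
    electric-field maps, focality/containment metrics, inter-individual
    fold-variation, and dose normalization by current scaling. Includes an
    independent multilayer-sphere Legendre-series solution for validating the
    numerical solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
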