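Package: photonfem
Title: Finite-Element Photon Modeling for Diffuse Optics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element forward modeling of near-infrared light propagation
    in scattering tissue via the diffusion approximation. Supports
    continuous-wave, frequency-domain and time-resolved data for standard and
    fluorescence problems, and electric-field autocorrelation (G1/g1) curves
    for diffuse correlation spectroscopy. Provides FSAI-preconditioned
    conjugate-gradient and BiCGStab solvers, Mellin-transform direct moment
    calculation, mesh-to-voxel interpolation with adjoint voxel-space
    Jacobians, Tikhonov reconstruction, classic ASCII NIRFAST mesh I/O,
    synthetic disk/slab mesh generators, and the semi-infinite-medium
    analytical solutions used for validation.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
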