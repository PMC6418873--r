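Package: dticnn
Title: 3D Convolutional Classification of Diffusion-Tensor Scalar Maps
Version: 0.1.0
Authors@R: person("The dticnn authors", role = c("aut", "cre"), email = "dticnn@example.org")
Description: Tools for group classification of whole-brain diffusion-tensor
    scalar maps (FA, MD, AD, RD) with a compact three-hidden-layer 3D
    convolutional network, together with the surrounding analysis pipeline:
    synthetic diffusion-tensor cohort generation with controlled group
    effects, tensor-derived scalar maps, volume rescaling and record stores,
    nested 10-fold cross-validation, a flattened-voxel linear SVM baseline,
    first-layer feature-map statistics (voxel means and Shannon entropy of
    quantized maps, with Bonferroni correction), and atlas-based per-region
    discriminability mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rhdf5,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
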