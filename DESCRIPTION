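Package: cardiomesh
Title: Conditional Generative Modelling of 3D+t Cardiac Mesh Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the shape and motion of the cardiac
    ventricles as sequences of triangulated surface meshes. Provides a
    conditional spatio-temporal variational autoencoder (graph-convolutional
    mesh encoder, temporal transformer with distribution parameter tokens,
    fully connected mesh decoder) trained with a Chamfer reconstruction loss,
    a beta-weighted KL term and a Laplacian smoothness penalty; surface
    distance metrics (Chamfer, Hausdorff, average symmetric surface distance);
    ventricular volume, ejection fraction and myocardial mass phenotyping;
    a seeded synthetic beating-heart population generator with
    condition-dependent phenotypes and disease perturbations; and a
    personalized normative deviation score (latent delta) with downstream
    classification and association harnesses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    MASS,
    e1071,
    xgboost,
    pROC
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
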