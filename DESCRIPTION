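Package: voxattrib
Title: Integrated Gradients Attribution for Voxel-Based Protein-Ligand
    Scoring Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interpretability toolkit for 3D convolutional neural networks
    that score protein-ligand complexes on pharmacophore voxel grids. Reads
    protein (PDB) and ligand (SDF) structures, voxelizes them into the
    16-channel (8 pharmacophore properties x protein/ligand) representation
    used by grid-based affinity and pose scorers, trains compact desk-scale
    3D CNN scorers (clash detector, docking pose classifier, affinity
    regressor) on built-in synthetic complexes, computes Integrated
    Gradients attributions with completeness diagnostics, exports
    attribution volumes as Gaussian cube files, and reproduces the
    reciprocity analyses: complementary-channel top-voxel distances against
    an occupancy-gated random baseline, Mann-Whitney U significance,
    attribution magnitude-distance correlation, and rotation/perturbation
    consistency of top-attributed atoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr,
    bio3d,
    ChemmineR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
Collate: 
    'voxattrib-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'voxelizer.R'
    'pharmacophore.R'
    'structio.R'
    'synthcomplex.R'
    'scorers.R'
    'igattrib.R'
    'reciprocity.R'
    'plots.R'
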