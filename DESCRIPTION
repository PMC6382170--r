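Package: voxrad
Title: Standardized Radiomic Feature Extraction from 3D Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes standardized (IBSI-style) radiomic features from 3D
    medical image volumes and aligned region-of-interest masks. Covers image
    and mask ingestion (NIfTI, NRRD, Analyze, DICOM series, raw with sidecar,
    RT-struct contours), PET SUV/SUL intensity scaling, preprocessing
    (interpolation, re-segmentation, outlier exclusion, fixed-bin-number and
    fixed-bin-size discretization), mesh-based morphology, local and global
    intensity peaks, first-order statistics, intensity-histogram and
    intensity-volume-histogram features, and the six texture-matrix families
    (GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM) under all 2D/3D matrix
    aggregation schemes. Includes phantom generators (NEMA-style voxelized
    spheres, seeded integer grids, a small digital phantom), an INI-driven
    configuration layer, a command-line interface, and CSV output with full
    provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    oro.nifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
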