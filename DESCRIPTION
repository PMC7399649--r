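Package: tractfilt
Title: Tractogram Filtering with Anatomical Bundle Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Filters diffusion-MRI tractograms by estimating non-negative
    per-streamline contributions that jointly explain a voxelwise
    intra-axonal signal-fraction map. Streamlines are grouped into
    anatomical bundles (pairs of gray-matter regions) and an adaptive
    group-lasso penalty promotes solutions that explain the data with the
    smallest number of bundles, removing spurious connections from
    structural connectomes. Includes a digital connectivity phantom
    generator with known ground truth, sparse streamline-to-voxel forward
    operators, accelerated proximal-gradient solvers with non-negativity,
    connectome construction, and sensitivity/specificity evaluation with
    thresholding and random-removal baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
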