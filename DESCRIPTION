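Package: symmreg
Title: Symmetric Unsupervised Deformable Registration via a Learned Pseudomean
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised symmetric deformable registration for 2D and 3D
    images. A light convolutional encoder-decoder predicts a single halfway
    displacement field that moves a template and a subject simultaneously into
    a learned pseudomean space; the full subject-to-template and
    template-to-subject deformations are recovered by field composition and
    fixed-point inversion. Includes a complete displacement-field algebra
    (negation, composition, inversion, Jacobian determinants, fold counting),
    differentiable linear-interpolation warping, the six-term training loss
    (pseudomean and end-space intensity similarity plus Laplacian, magnitude
    and antifolding regularizers), a two-stage Adam training schedule,
    Dice-overlap and fold-count evaluation, and a synthetic brain-phantom
    generator with known ground-truth deformations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
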