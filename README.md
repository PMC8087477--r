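# symmreg — symmetric unsupervised deformable registration

`symmreg` registers pairs of 2D or 3D images (brain MR being the motivating
case) without ground-truth deformations and without a one-sided bias toward
either image. A light convolutional encoder–decoder looks at a template, a
subject, and their difference map, and predicts a single **halfway
displacement field** φᵀ: the template moves by φᵀ, the subject by its exact
negation φˢ = −φᵀ, and the two meet in a learned **pseudomean** space. The
full deformations are then recovered by field composition and fixed-point
inversion,

    F    = φᵀ ∘ (φˢ)⁻¹   (warps the template onto the subject grid)
    F⁻¹  = φˢ ∘ (φᵀ)⁻¹   (warps the subject onto the template grid)

which makes the registration inverse-consistent by construction. Training is
unsupervised, with a six-term loss

    L = L_sim(pseudomean) + L_sim(S→T) + L_sim(T→S)
        + α·L_Laplace + β·L_zero + γ·L_antifold,      (α, β, γ) = (1, 0.01, 100)

combining SSD intensity similarity in the pseudomean and both end spaces
with curvature, magnitude, and antifolding regularizers on the halfway
field. Quality is scored by per-ROI Dice overlap and by the fold count
|{u : J_φ(u) < 0}| of the composed deformation's Jacobian determinant.

The package is self-contained scientific R: the displacement-field algebra
(negation, composition, fixed-point inversion, Jacobian determinants, fold
counts), the differentiable warp, the network with its hand-written backward
pass, Adam, the two-stage training schedule, the evaluation metrics, and a
synthetic brain-phantom generator with known ground-truth deformations. No
deep-learning runtime is needed; everything runs on one CPU at the bundled
problem sizes.

Who it is for: anyone studying symmetric/inverse-consistent registration
mechanics, teaching unsupervised registration, or needing a fully
inspectable reference implementation with honest, reproducible synthetic
experiments.

## Worked example

Generate a phantom pair with a known smooth deformation, train stage 1 on
it, and register:

```r
library(symmreg)

phantom <- make_phantom(shape = c(64L, 64L), seed = 1)
#> Phantom pair 64x64, 4 ROIs, amplitude 3 voxels (seed 1)

model <- build_snet(snet_config(spatial_dims = 2L), seed = 1)
#> Halfway-field registration network (2D)
#>   encoder: 16, 32, 32, 32
#>   decoder: 32, 32, 32, 32, 16
#>   parameters: 88962

fit <- train_snet(model,
                  list(template = phantom$template, subject = phantom$subject),
                  config = training_config(
                    stage1 = list(iterations_per_pair = 200L,
                                  template_id = "template",
                                  include_self = FALSE),
                    seed = 1))
#> Trained registration model: 200 steps
#>   total loss: 0.01083 (first) -> 0.0040769 (last)

res <- register_pair(fit$model, phantom$template, phantom$subject)
#> Symmetric registration result
#>   max |halfway displacement|: 0.611 voxels
#>   template-space SSD: 0.0036103 -> 0.0012877
#>   folds of composed forward field: 0

evaluate_registration(res, phantom$labels_subject, phantom$labels_template)$dice
#> Dice overlap over 4 ROIs: mean 0.8784

dice_overlap(phantom$labels_subject, phantom$labels_template)  # unregistered
#> Dice overlap over 4 ROIs: mean 0.8463
```

Reading the numbers: 200 unsupervised steps cut the total loss by 62% and
the template-space SSD to 36% of its pre-registration value; mean ROI Dice
rises from the unregistered 0.846 to 0.878; and the composed deformation has
zero folds — the map stays topology-preserving. `res` also carries the
halfway fields, both composed fields, the two pseudomean-space ("middle")
warps, and Jacobian diagnostics.

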