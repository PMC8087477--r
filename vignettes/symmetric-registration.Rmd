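---
title: "Symmetric registration via a learned pseudomean: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric registration via a learned pseudomean: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The registration model

Deformable registration estimates a dense displacement field aligning a
subject image to a template. `symmreg` takes the symmetric route: instead of
one long deformation pathway from subject to template, a convolutional
network predicts a single *halfway* field $\phi^T$ that moves the template
toward an intermediate *pseudomean* space, while the subject moves by the
exact negation $\phi^S = -\phi^T$. The pseudomean is never supervised; it
emerges because the training loss asks the two symmetrically warped images to
agree. Predicting two short pathways instead of one long one makes large
local deformations easier to estimate and keeps the field smoother, and the
full deformations in either direction come for free:

* forward, $F = \phi^T \circ (\phi^S)^{-1}$, resamples the template onto the
  subject grid;
* backward, $F^{-1} = \phi^S \circ (\phi^T)^{-1}$, resamples the subject onto
  the template grid.

Because both are built from one halfway field, the pair is inverse-consistent
by construction (up to interpolation and inversion error), with no auxiliary
inverse-consistency network or penalty.

All displacements are stored in voxel units. Warping is pull-back
resampling, $\mathcal{T}(I, \phi)(u) = I(u + \phi(u))$, with bilinear
(2D) / trilinear (3D) interpolation and coordinates clamped to the grid.

### Direction naming

The literature uses "forward" inconsistently for symmetric methods: the same
composed field is called forward whether one speaks of the point mapping
(subject points to template points) or of the image being resampled
(template into subject space). In this package the names are fixed by what
the field *does* under pull-back warping: `forward` ($\phi^T \circ
(\phi^S)^{-1}$) warps the **template** onto the subject grid, and `backward`
($\phi^S \circ (\phi^T)^{-1}$) warps the **subject** (and its ROI labels,
for Dice scoring) onto the template grid. `evaluate_registration()` and the
Dice numbers therefore use the backward field; both composed fields are
audited for folds.

## The six-term loss

Training is unsupervised, driven by intensity agreement plus field
regularity (`total_loss()`):

$$\mathcal{L} = \mathcal{L}^{sym}_{Sim} + \mathcal{L}^{S\to T}_{Sim} +
\mathcal{L}^{T\to S}_{Sim} + \alpha\,\mathcal{L}_{Lap} +
\beta\,\mathcal{L}_{Zero} + \gamma\,\mathcal{L}_{Anti}$$

* **Pseudomean similarity**: mean squared difference between
  $\mathcal{T}(I^S, -\phi^T)$ and $\mathcal{T}(I^T, \phi^T)$ — the symmetry
  constraint.
* **End-space similarities**: SSD of the fully composed warps against the
  unmoved images in template and subject space, anchoring the halves to a
  correct total deformation.
* **Laplacian smoothness** ($\alpha = 1$): squared discrete vector Laplacian,
  zero on affine fields; penalizes curvature.
* **Zero/magnitude constraint** ($\beta = 0.01$): mean squared displacement.
  The weight is deliberately small so genuine large deformations are not
  suppressed; it only discourages drift.
* **Antifolding** ($\gamma = 100$): for each axis $d$, penalizes
  $R(\partial\phi_d/\partial u_d + 1)$ where $R(Q) = |Q|$ for $Q \le 0$ and
  $0$ otherwise — active only where a same-axis derivative approaches a
  fold, so it costs nothing on healthy fields while pricing folds heavily.

Conventions chosen where the scalar formulas leave room:

* Every voxel sum is divided by the voxel count (per-voxel mean), so loss
  magnitudes — and hence the printed weights — carry across resolutions.
  Squared norms sum over vector components. With this pairing of
  conventions, the documented weights reproduce the intended balance at any
  grid size, and the closed forms in the tests (a constant intensity offset
  $c$ gives loss $c^2$; the field $\phi_x = x^2$ gives Laplacian loss 4) pin
  the convention down.
* Both images are min–max normalized to $[0, 1]$ at pair construction
  (`make_pair_input()`), before any SSD, so similarity scales are comparable
  across inputs. The loss operators themselves do not renormalize.
* The antifolding derivative is the same-axis forward difference — the
  diagonal of the Jacobian minus one. Off-diagonal terms do not enter the
  scalar penalty.

## Field algebra

* **Composition**: `compose_fields(outer, inner)(u) = inner(u) +
  outer(u + inner(u))`, so warping by the composite equals warping by
  `outer` first, then `inner` (deformation maps compose as
  $(\mathrm{id}+c) = (\mathrm{id}+\mathrm{outer}) \circ
  (\mathrm{id}+\mathrm{inner})$). The opposite ordering convention exists in
  other toolkits; serialized fields carry a JSON sidecar stating this one.
* **Inversion**: the fixed-point iteration $\psi_{k+1}(u) = -\phi(u +
  \psi_k(u))$, from $\psi_0 = -\phi$, standard for displacement inversion:
  simple, derivative-free, and accurate for the smooth halfway fields this
  model produces. Defaults: tolerance $10^{-3}$ voxels on the max update, 30
  sweeps. Non-convergence sets a `converged` attribute rather than raising —
  an approximate inverse is still a usable diagnostic input. Inside the
  training loss the inversion runs a fixed 5 sweeps to bound cost; full
  tolerance is used at inference. For smooth fields with displacements up to
  3 voxels on grids of 16 and larger, the interior residual of
  $\phi \circ \phi^{-1}$ stays below 0.1 voxel (asserted in the tests).
* **Jacobian and folds**: the determinant of $\partial(u + \phi(u))/\partial
  u$ uses central differences in the interior and one-sided differences at
  boundary slices; a *fold* is an interior voxel with negative determinant.
  Fold counting excludes the one-voxel boundary shell so one-sided stencils
  cannot fabricate folds. We take the determinant of the forward deformation
  map — the operationalization the fold count $|\{u : J_\phi(u) < 0\}|$
  presumes. Anisotropic spacing only rescales derivative terms and is off by
  default (all bundled data are isotropic).
* **Gradients for the antifold term** use forward differences with a zero
  derivative at the trailing slice (replicated edge).

### Interpolation details

Linear interpolation weights come from the floor-based corner cell; at
exactly-integer coordinates the weights select the integer voxel exactly, so
a zero field is a bit-exact identity. The typeset corner-weight product is
applied with absolute values, $\prod_d (1 - |x_d - v_d|)$ — without them
weights could go negative. Out-of-grid samples clamp to the border, keeping
warped intensities inside the input range and leaving gradients defined.
Label maps are warped with nearest-neighbour resampling (floor at +0.5,
clamped), which preserves label identity; how ROI maps should be resampled
is otherwise unspecified, and interpolating label codes would invent
tissue classes.

## Network and training

The predictor is a VoxelMorph-style fully convolutional encoder–decoder
taking the stacked (template, subject, difference) channels, where the
difference map is the signed difference of the normalized intensities
(template − subject). Encoder convolutions (kernel 3, stride 2, leaky ReLU
0.2) halve resolution per level; the decoder alternates convolutions,
nearest-neighbour ×2 upsampling and skip concatenations, and a final linear
convolution emits one displacement channel per axis. Exact layer counts for
the original architecture are unpublished; the defaults here — encoder
(16, 32, 32, 32), decoder (32, 32, 32, 32, 16), halved for grids of 48
voxels or less — are declared approximations sized for CPU training. The
final convolution is initialized near zero (weight sd $10^{-5}$, zero bias)
so an untrained model predicts an essentially-identity transform; training
then starts from a stable point, and the contract `max |phi| < 0.1` for a
fresh model is testable. Everything (convolutions via BLAS matrix products,
the backward pass, Adam) is implemented in plain R; no deep-learning runtime
is required, and the backward pass is verified against finite differences in
the test suite.

Training follows the two-stage schedule: stage 1 pretrains on
one-template-versus-all pairs, 200 Adam steps per pair at learning rate
$10^{-4}$; stage 2 sweeps all ordered pairs ($n \times n$, self-pairs
included — they act as identity-regularizing examples) for a configurable
number of epochs at $10^{-5}$, halving the rate every 2 epochs
($\mathrm{lr}(e) = 10^{-5} \cdot 0.5^{\lfloor e/2 \rfloor}$). Pair order in
stage 2 is reshuffled each epoch from the run seed; with a fixed seed and
single-threaded BLAS, two runs produce identical loss histories. "200
iterations per image pair" is interpreted as 200 consecutive gradient steps
on each pair, not 200 epochs. Adam uses the common constants
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), batch size 1
(pairwise registration). Held-out pair counts use the $n \times (n-1)$
(leave-self-out) convention.

The inverse fields inside the end-space losses are treated as
stopped-gradient inputs: whether the original training differentiates
through the inversion is unstated, and the fixed-point iteration is awkward
to differentiate; gradients flow through the direct appearance of $\phi^T$
in the composed field (via the resampling adjoint) and through the warp.
`total_loss_grad()` exposes the switch explicitly and refuses the
differentiated-inverse variant rather than silently approximating it.

## The phantom generator

`make_phantom()` builds a head-like template — outer ellipse/ellipsoid, a
bright rim as a skull/CSF analog, darker interior tissue, a low-intensity
ventricle analog, and labeled smooth blobs standing in for anatomical ROIs —
with tissue boundaries Gaussian-smoothed (sd 1.2 voxels) the way
preprocessed MR images have smooth gradients. The ground-truth deformation
is per-component white noise, Gaussian-smoothed at `smoothness_sigma`,
windowed by a smooth head mask, rescaled so the peak displacement magnitude
equals `deformation_amplitude`, and redrawn (bounded retries) until
fold-free. The head windowing matters: affinely pre-aligned brains deform
inside the head, not in the surrounding air, and without it the rescaling
peak can land on empty background, leaving the anatomy essentially static.
The subject is the warped template plus Gaussian intensity noise
(sd 0.02 by default), clipped back to the $[0, 1]$ tissue window so the
pair stays intensity-comparable, as preprocessed acquisitions are.
`make_cohort()` varies ellipse and blob parameters per subject around a
shared labeled base, so ROI identities correspond across the cohort.

Defaults — 2D $64 \times 64$ grids (3D $32^3$ supported throughout),
4 ROIs, amplitude 3 voxels, smoothness 6 voxels — are the study conditions
for the end-to-end experiment: a deformation large enough to displace
anatomy by 1–2 voxels on average at the ROIs yet smoothly invertible.

What the phantoms do *not* emulate: MRI texture and fine anatomical detail,
partial-volume effects, bias fields, Rician noise, or topology differences
between subjects. Passing the end-to-end tests therefore demonstrates that
the machinery — field prediction, symmetry, composition, inversion, loss
balance, training loop — works as specified on smooth, honest test
problems; it does not certify accuracy figures on clinical brain MRI, which
would require the full-scale datasets and GPU-scale training.

## Problem sizes and budgets

The bundled experiments are sized for a single CPU: the end-to-end
acceptance experiment trains stage 1 on one $64 \times 64$ phantom pair for
200 steps (under two minutes), and the algebra/oracle checks use $8^3$ to
$16^3$ grids. These sizes are the package's deliberate test scale; the same
code runs 3D volumes, limited only by patience.

## Known limitations

* Displacement fields only: no stationary-velocity or B-spline
  parameterizations, no scaling-and-squaring, no multiscale pyramid.
* SSD similarity only, as the method prescribes; no cross-correlation or
  mutual information.
* The fixed-point inversion assumes a smooth, fold-free field; it degrades
  (and flags itself) on fields with large derivatives.
* CPU-scale: full-resolution brain volumes ($192 \times 224 \times 192$)
  are out of reach of the plain-R training loop by design.
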