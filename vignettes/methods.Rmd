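---
title: "Diffusion-based lesion inpainting: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based lesion inpainting: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brain morphometry pipelines assume intact anatomy. Tumors, resection
cavities, and demyelinating lesions violate that assumption and corrupt
whole-brain segmentation and cortical surface reconstruction far beyond the
lesion itself. A general remedy is *inpainting*: given a T1-weighted volume
and a binary lesion mask, synthesize plausible healthy tissue inside the
mask — and only inside the mask — so that any downstream tool can process the
repaired image. `neuroinpaint` implements such an inpainter around a
denoising diffusion probabilistic model (DDPM), together with the synthetic
evaluation data, metrics, and lesion-to-surface post-processing needed to
validate it end to end without any external neuroimaging software.

## The diffusion model

The forward process corrupts a clean image $x_0$ (intensities mapped to
$[-1, 1]$ by $x = 2v/255 - 1$) over $T$ steps with variances
$\beta_1 \le \dots \le \beta_T$. Writing $\alpha_t = 1 - \beta_t$ and
$\bar\alpha_t = \prod_{s \le t} \alpha_s$ (with $\bar\alpha_0 = 1$), the
marginal has the closed form

$$x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1 - \bar\alpha_t}\, \varepsilon,
\qquad \varepsilon \sim \mathcal N(0, I).$$

A network $\hat\varepsilon_\theta(x_t, t, \rho)$ is trained to predict the
injected noise by plain MSE over uniformly sampled $t$; no lesion mask is
ever seen during training. Sampling inverts the chain with the ancestral
step

$$x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\Big(x_t -
\frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\hat\varepsilon\Big) + \sigma_t z,
\qquad \sigma_t^2 = \beta_t\,\frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t},$$

with $z = 0$ at $t = 1$ (so the final step is deterministic). Inpainting
constrains the chain to the mask: after each step the region *outside* the
mask is replaced by a fresh forward-noise draw of the true image at level
$t-1$, so the known region always carries the correct marginal and
information flows from intact tissue into the mask. At $t - 1 = 0$ the
outside region is the input itself, and a final `finalize()` pass copies the
original voxels bit-exactly and clamps the synthesized interior to
$[0, 255]$. Optional RePaint-style re-noising loops (`resample`) are
available but off by default.

Defaults: linear $\beta$ schedule from $10^{-4}$ to $0.02$; $T = 1000$ is
the canonical choice for this family of models, and $T = 200$ is the
desk-scale default used throughout the examples and the validation suite
(`run_config_defaults()`).

## The slab denoiser and voxel-size independence

Full 3D networks are impractical at sub-millimeter resolutions, so the
denoiser is 2D: it consumes a *slab* of 7 adjacent slices (as channels, with
full in-plane extent) cut orthogonal to one of the three anatomical planes,
and predicts noise for all 7 slices. Through-plane context enters via the
slab; long-range 3D coherence emerges from the inference scheme below.

The architecture is a small U-Net whose *first* down-sampling and *last*
up-sampling are voxel-size-adaptive (VINN) resampling layers: feature maps
are bilinearly rescaled by `voxel_size / internal_voxel_size` (corner-aligned,
shapes rounded half-up, original shape cached for an exact inverse), so a
0.7 mm input is shrunk to the 1.0 mm internal grid before the shared
convolutional trunk sees it. Deeper transitions are ordinary factor-2
average pooling and nearest-neighbor unpooling with skip connections. The
timestep enters through a sinusoidal embedding with the voxel size appended
as a scalar conditioning term, projected to a per-channel bias in every
residual block; the output convolution is zero-initialized. Parameter count
is independent of grid size and voxel size, which is what lets one set of
weights serve the 0.7–1.0 mm range.

Two readings of "latent" were possible for this family of architectures: a
separately trained autoencoder (latent diffusion proper) or the U-Net's own
internal feature maps. This package diffuses in image space and treats the
inner feature maps as the latent grid that VINN normalizes; a full
autoencoder would add a second training problem without changing any of the
properties tested here.

The network, its gradients (im2col convolutions, matrix-form resampling),
and the Adam optimizer are implemented directly on R's BLAS primitives; the
backward pass is verified against central finite differences in the test
suite.

## 2.5D multi-view inference with shifted slabs

For $t = T, \dots, 1$ the scheduler rotates through axial, coronal, and
sagittal views (`(T - t) mod 3`), chooses a slab offset (`t mod 7` under the
default cyclic policy, so all 7 offsets occur in any 7 consecutive steps),
tiles the chosen axis with non-overlapping slabs at that offset (boundary
slabs are clamped inward, never padded), and runs the view's denoiser *only
on slabs intersecting the lesion* — cost is therefore linear in lesion
extent. All 7 slices of each slab are written back; slabs within a step
never overlap, so no blending rule is needed. Compositing with the known
region happens once per step, after all slabs, keeping the known-region
distribution consistent across slabs within a step. One denoiser per view is
the default; `shared_weights = TRUE` trains a single model for all three
views for quick experiments.

## The synthetic phantoms

The phantom generator stands in for a multi-resolution corpus of lesion-free
scans with reliable segmentations. Geometry is defined in world millimetres
and sampled onto the voxel grid, so one seed renders consistently at 0.7,
0.8, 0.9, and 1.0 mm (per-class world volumes agree within 5% at matched
extents — a tested invariant). Anatomy is deliberately stylized: an
ellipsoidal head with a skull shell and CSF layer, a folded cortical ribbon
(sinusoidal undulation, ~2.8 mm thick, 2–4 voxels at 1 mm), a white-matter
interior, paired ventricles, and two subcortical nuclei per hemisphere
(eight classes total). Intensity is the class mean (T1-like contrast: CSF
dark, GM mid, WM bright on a 0–255 scale) modulated by a smooth
multiplicative bias field plus Gaussian noise (`noise_sd = 4`,
`bias_amplitude = 0.05` by default — values in the range of a well-shimmed
T1 acquisition after normalization).

Two lesion constructions mirror the two synthetic evaluation designs:

* **Tumor with mass effect.** A radial Gaussian displacement field
  $u(d) = A\,(d/\sigma)\,e^{-d^2/2\sigma^2}$ centered at a random
  brain-interior point ($\sigma$ = lesion radius) deforms intensity
  (linear interpolation) and labels (nearest) *jointly*, so the warped
  labels remain a valid reference segmentation of the warped image. $A$ is
  automatically reduced until the discrete Jacobian determinant stays
  positive (no folding) — a stand-in for a biophysical growth simulator,
  which is used in the original evaluation design only to supply a tumor
  mask and a warp field. The mask is a spheroid perturbed by smooth angular
  noise and warped by the same field; its interior is filled with a
  hyperintense tumor-like value. Implausible random placements (mostly
  outside brain tissue) are rejected after 10 retries; the plausibility
  threshold (≥ 50% of the sphere inside brain labels) is a package choice,
  as no quantitative criterion exists for it in the literature this design
  follows.
* **Multifocal MS-like lesions.** Small spheroids (1.5–4 mm) centered in
  white matter, intensity replaced, labels and geometry untouched (the mass
  effect of such lesions is negligible). The default fill is *hypointense*
  (60/255): on a T1-like contrast demyelinating lesions present as "black
  holes", and a hyperintense fill would sit nearest to the WM class mean,
  making the lesion invisible to any intensity-based segmenter and thereby
  degenerate as an evaluation target.

A deterministic stand-in segmenter (`reference_segment`: 3³ median filter,
then nearest-class-mean with ties to the lowest label) closes the loop so
Dice/Hausdorff evaluation of the full pipeline needs no external tool.

What the phantoms do *not* emulate: MR physics (no k-space, no partial
volume beyond grid sampling, no Rician noise floor), real cortical folding
complexity, lesion texture heterogeneity, or anisotropic acquisitions.
Passing the suite therefore demonstrates the *mechanics* of the method —
conservation, resolution independence, information propagation, metric
correctness — not clinical-grade inpainting fidelity, which requires
training at scale on real data.

## Metrics

* **SSIM** with Gaussian-weighted local moments (window 11, sd 1.5),
  $c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$, $L = 255$, valid windows only,
  verified against a brute-force sliding-window oracle.
* **PSNR**: the widely used squared-peak form
  $20\log_{10} M - 10\log_{10}\mathrm{MSE}$ is the default; the linear-peak
  form $10\log_{10}(M/\mathrm{MSE})$, which some texts print, is selectable,
  and every report records which convention produced it. Identical images
  report `Inf` rather than erroring.
* **Dice** and **HD95**: HD95 extracts face-adjacency boundary voxels,
  takes directed nearest-neighbor distances in mm, the 95th percentile with
  linear interpolation per direction, and the maximum of the two; verified
  against an all-pairs brute-force oracle on small random masks.
* **ICC(A,1)**: two-way random-effects, absolute-agreement,
  single-measurement ICC from the mean squares — equality, not mere
  correlation: identical pairs give exactly 1, a constant offset gives less,
  independent pairs give ~0. Cross-checked against base R ANOVA mean
  squares.
* `evaluate_inpainting()` computes SSIM/PSNR over the lesion bounding box
  padded by the SSIM kernel half-width — the only region where methods can
  differ, since the exterior is conserved bit-exactly — and Dice/HD95 per
  label restricted to the mask.

## Surface projection

After inpainting and segmentation, the lesion is re-inserted as an explicit
label (`relabel_segmentation`), dilated (default 1 iteration,
26-connectivity — the dilation radius is unspecified in the evaluation
design this follows, and 1 voxel is the smallest value that closes
vertex-voxel rounding gaps), projected to mesh vertices by nearest-voxel
containment through the volume affine, and smoothed with a mode filter
(majority of self + 1-ring, ties keep the current label, 3 iterations or
until a fixed point). Marked vertices are excluded per subject from
vertex-wise group statistics (`exclude_and_summarize`) and from vertex-wise
ICC maps (`vertex_icc_map`, requiring ≥ 3 unmasked subjects per vertex;
shorter vertices are flagged missing, never NaN-propagated). Thickness
smoothing and template resampling are upstream concerns; all maps here are
assumed vertex-aligned.

## Numerical choices and degenerate inputs

* Coordinates: 0-based voxel indices, voxel centers at integers, world =
  affine · (index, 1); rounding is half-up everywhere (never banker's).
* Masks are never resampled; a grid mismatch is an error.
* Empty mask: inpainting returns the input bitwise with zero network calls.
  Empty masks make Dice/HD95 undefined and raise errors rather than NaN.
* SSIM tie-down: images smaller than the kernel are rejected; the
  evaluation bounding box is grown to hold at least one window.
* Nearest-mean ties in `reference_segment` go to the lowest label id.
* The Jacobian cap shrinks the mass-effect amplitude by factors of 0.8
  until the minimum discrete determinant exceeds 0.05.
* All stochastic operations are pure functions of (inputs, seed); the
  caller's RNG stream is saved and restored around every seeded block.

## Problem sizes used in the validation suite

The suite trains three per-view denoisers (base width 8, depth 2, ~13k
parameters each) for 1200 Adam steps on slabs from three 48³ phantoms at
1 mm with a T = 200 schedule, then inpaints five held-out phantoms with a
tumor (radius 6 mm, mass effect 2 mm) and five with five MS lesions each.
Tumor-case inference uses three re-noising loops per step (`resample = 3`):
at this model scale the loops visibly improve how well the synthesized
interior harmonizes with its surroundings, and they matter most for large,
structure-poor masks.
These sizes were chosen so the whole suite runs on a single CPU in minutes
while still exercising every moving part at full fidelity; they are two
orders of magnitude below a realistic training run (hundreds of volumes,
256³ grids, wider networks, $T = 1000$).

On these conditions the diffusion inpainter beats a ring-mean constant fill
on SSIM and PSNR inside the lesion bounding box for the tumor cases, and
segmenting the inpainted volume recovers substantially more reference
tissue inside the mask than segmenting the lesioned input for both lesion
types (the suite asserts these, and the exact numbers it observed are
whatever it printed on your machine — they are recomputed on every run).

## Known limitations

* **Uniform-region ceiling.** Against a *noisy* reference, any generative
  sampler synthesizes noise uncorrelated with the reference noise, so its
  MSE inside homogeneous tissue is bounded below by twice the noise
  variance, while a constant ring-mean fill approaches the posterior mean
  and one noise variance. Inside uniform white matter the mean fill is
  therefore unbeatable on PSNR/SSIM by construction — which is why the
  perceptual comparison in the suite is made on the tumor cases, whose
  masks span real structure (ribbon, CSF, boundaries), and why the MS cases
  are evaluated through the segmentation route instead. This is a property
  of the metric pairing, not of the method.
* Desk-scale training produces visibly plausible but not radiologically
  convincing tissue; quality claims at scale require the full corpus.
* Only isotropic voxels in [0.5, 2.0] mm are supported; inputs are assumed
  grid-aligned (no conforming/reorientation step).
* The stand-in segmenter is intensity-based and cannot represent the
  boundary uncertainty of a learned segmenter; Dice values are optimistic
  near class boundaries.
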