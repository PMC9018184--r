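---
title: "Reconstructing occlusal surfaces from depth maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing occlusal surfaces from depth maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a molar is prepared for a full crown, the dentist grinds away the
occlusal (chewing) surface; the prosthesis that replaces it must restore the
patient's individual anatomy — cusps, the central groove that channels food,
and the occlusal fingerprint, i.e. the pattern of contact patches against the
opposing tooth. Template-based CAD workflows produce generic occlusal shapes
and require extensive manual adjustment. `occlurec` implements a
learning-based alternative: the missing surface is synthesized by a
conditional adversarial network operating on depth-map images of the
dentition, with the biological features supplied as explicit conditioning
channels.

The package covers the full pipeline — synthetic data generation, pose
standardization, a reversible depth encoding, the completion network, a dual
global/local discriminator, staged training, mesh reconstruction and quality
metrics — and runs entirely on the CPU with a small deterministic
convolution engine.

## Depth-map encoding of tooth geometry

A pose-standardized tooth mesh (occlusal direction along +z, mesiodistal
along +x, bounding-box centre at the origin; `standardize_pose()`) is
rendered by orthographic projection along −z. A surface point at distance
$d$ mm below the reference plane maps to the 8-bit level

$$p(d) = \operatorname{round}\!\left(255\,\frac{h^\alpha - d^\alpha}{h^\alpha}\right),
  \qquad 0 \le d \le h,$$

with visual distance $h = 6$ mm; anything deeper than $h$, and any pixel
with no surface beneath it, is encoded as 0. The mapping is invertible
(`pixel_to_depth()` is $h(1-p/255)^{1/\alpha}$ applied to the un-rounded
form), so a depth map plus its JSON sidecar reproduces 3-D geometry up to
quantization. `depth_quantization_step()` reports the worst-case depth
difference between adjacent levels by brute force over all 256 levels — for
$\alpha = 2, h = 6$ it is 0.376 mm, concentrated near $d = 0$ where the
mapping is flattest. Every geometric accuracy claim in the package is made
relative to this bound.

The enhancement factor $\alpha$ reweights gray levels. It is chosen by
rendering the same tooth at each candidate and keeping the value that
maximizes the Shannon entropy of the level histogram
($H = -\sum_t P_t \log_2 P_t$, `image_entropy()`), i.e. the rendering that
retains the most detail; ties break toward the smallest candidate. On our
synthetic crowns at 64×64 the flatter exponents ($\alpha \le 1$) often win,
because the synthetic height distribution differs from clinical scans — the
selector is the contract, not any particular winning value.

Numerical choices: rounding of the encoder is half-away-from-zero; the
reference plane sits at the z-maximum of the mesh (so the highest cusp has
$d = 0$) since nothing in the mapping anchors it otherwise; the principal-axis
sign ambiguity of pose standardization is resolved by rendering both
candidate occlusal directions at 32×32 and keeping the side with the higher
entropy (the detailed side faces the camera), with the x sign fixed by the
third moment and y completing a right-handed frame.

## Inverse mapping: depth maps back to meshes

`reconstruct_mesh()` back-projects every foreground pixel to
$(x, y, z_\mathrm{ref} - h(1-p/255)^{1/\alpha})$ and triangulates by region
growth over the pixel grid: a 2×2 cell contributes two triangles only when
all four pixels are foreground and their depth spread is below a
discontinuity threshold (default 0.5 mm — roughly the codec's own
quantization bound, so genuine surfaces are never split while walls and
background jumps are). Vertices isolated by this rule (typically the steep
tooth walls) are dropped: an unreferenced back-projected point is a
hallucinated spike, not surface. Round-trip accuracy is tested against the
quantization bound on planes and full crowns.

## The synthetic molar scene

The clinical dataset this class of model is trained on (occlusal scans of
prepared and intact mandibular first molars with dentist-annotated
morphology) is not publicly available, so the package ships a parametric
generator that emulates its *structure*:

* **Crown** (`crown_params()`, `generate_crown()`): a height field — a smooth
  base dome with `n_cusps` Gaussian cusps on a ring and a central groove
  valley. Defaults describe a plausible mandibular first molar: 10.5 mm
  diameter, five cusps in a 3+2 arrangement flanking the groove (as on the
  real tooth, where the mesiodistal central groove separates three buccal
  from two lingual cusps), 1.6 mm cusp relief, 0.9 mm groove depth, 0.6 mm
  groove width. Per-cusp jitter (8%) individualizes every seed.
* **Scene** (`generate_case()`): the target crown plus mesial and distal
  neighbours, an opposing crown mirrored above with a minimal inter-jaw
  clearance drawn from U(0.02, 0.12) mm — kept below the 0.15 mm contact
  threshold because opposing teeth do contact at maximum intercuspation, so
  every case has a non-empty fingerprint.
* **Channels**: the preparation image `x1` (crown cut by a hard horizontal
  margin at 50% of crown height — a hard cut, because the module guarantees
  `x1 == z1` exactly outside the defect mask, which a smoothed shoulder would
  violate), the opposing-tooth depth map `c1`, the morphology mask `c2`
  (fingerprint ∪ groove), the gap field `d` (per-pixel inter-jaw distance
  clipped to `[0, h]` and normalized), and the target `z1`. The local crop is
  the defect bounding box padded by 10% and resized with an explicit
  separable bilinear operator whose linear adjoint the training loop uses for
  backpropagation through the crop.

What the generator does **not** emulate: real enamel texture, scanning noise,
undercuts (crowns are single-valued height fields, which is all the occlusal
projection ever sees), anatomical shape statistics across patients, or
dentist-annotated fingerprints (ours are proximity-thresholded). Passing
tests therefore demonstrate that the pipeline's machinery is correct and that
training behaves as designed on data with this structure — not clinical
performance.

## The completion network

The generator is an encoder–decoder: two stride-2 convolutions reduce the
input to 1/4 resolution; a bottleneck of four dilated Conv–BN–LeakyReLU
blocks at rates [1, 2, 4, 8] (powers of two give exponential receptive-field
growth: $1 + \sum_i r_i(k-1) = 31$ px at kernel 3) processes it; the four
block outputs are concatenated channel-wise and merged by a 1×1 convolution,
so every scale of structural information reaches the decoder; two transposed
convolutions restore resolution and a 1×1 convolution + sigmoid emits the
surface in [0, 1]. All ReLUs in the package are leaky with slope 0.2. The
output is composited as `out * mask + preparation * (1 − mask)`: only the
defect is synthesized, which makes the "unchanged outside the defect"
invariant structural rather than learned.

Two discriminators judge the result: a *global* branch (5×5 stride-2
convolutions on the whole scene stack x1, c1, c2, d, crown) checks coherence
with the neighbours, and a *local* branch (exactly five convolutions plus a
fully connected layer on the defect crop) checks local realism. Each branch
ends in a feature vector; concatenating both feeds a fused real/fake
probability. Because the two adversarial objectives are also written
per-branch, both per-branch heads are exposed and the default training mode
backpropagates the per-branch probabilities (`adv_mode = "per-branch"`,
matching the sum-over-discriminators objective); `"fused"` uses the single
fused probability instead.

## Objectives and the staged schedule

The generator objective is
$L_\mathrm{total} = L_\mathrm{adv} + \lambda_{L1} L_{L1} +
\lambda_\mathrm{mse} L_\mathrm{mse} + \lambda_\mathrm{per} L_\mathrm{per}$
with $\lambda_{L1} = 100$, $\lambda_\mathrm{mse} = 50$,
$\lambda_\mathrm{per} = 50$; Adam uses learning rate 2e-4,
$\beta_1 = 0.5$, $\beta_2 = 0.999$. $L_\mathrm{adv}$ is the non-saturating
form $-\sum_k \log D_k(\text{fake})$ (the literal min–max form starves the
generator of gradient early on). Perceptual features come from the frozen
convolutional trunk of the global discriminator — the package is
download-free, so no external pretrained classifier is assumed; any layer
list can be substituted via `perceptual_loss()`'s `feature_net` argument.

Training proceeds in three stages of increasing complexity
(`train_staged()`):

1. **Stage I** — generator alone, $\lambda_{L1} L_{L1}$ plus two masked-L1
   constraint terms: the *occlusion spatial constraint* (L1 restricted to the
   fingerprint mask, where the gap-consistent target height is critical) and
   the *biological morphology constraint* (L1 on the groove mask). Both
   weights default to 1.
2. **Stage II** — generator frozen (asserted bit-identical before/after),
   discriminators train from scratch against its outputs while MSE and
   perceptual losses are logged on each minibatch. A printed description of
   this stage could also be read as the discriminators *minimizing* MSE and
   perceptual loss, but those terms contain no discriminator parameters, so
   that reading is not a trainable objective; it is available as
   `stage2_mode = "frozen-validation"` (measure only, no D updates).
3. **Stage III** — joint adversarial training, one discriminator and one
   generator update per batch (the update ratio is a free choice; 1:1 is the
   common default), with the full weighted objective.

Each loss is logged over the stages in which it participates in the
currently optimized objective — L1 and MSE from Stage I, perceptual from
Stage II, adversarial during Stage III, plus a separate discriminator-loss
column. `loss_trajectory()` smooths a series with a rolling mean and compares
the medians of its first and last quarters; that is the package's
operational definition of a decreasing trajectory. Divergence (non-finite or
loss above 1e4) aborts with the last stage snapshot retained.

Batch normalization running statistics are warm-started from the first
training batch, so eval-mode behaviour is meaningful from the first epoch —
with the (0, 1) initialization the validation loss would drift for several
epochs purely from statistic burn-in.

## Quality metrics

* `psnr()` — $10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$, peak 255 by
  default (depth maps are 8-bit; peak is configurable for [0, 1] images).
  Identical images return a documented 100 dB cap with an `identical` flag.
* `ssim()` — the original convention: 11×11 Gaussian window ($\sigma$ 1.5),
  $K_1 = 0.01$, $K_2 = 0.03$, valid-mode windows.
* `fsim()` — phase congruency (log-Gabor bank, 4 scales × 4 orientations,
  minimum wavelength 6, octave scaling, $\sigma_{onf} = 0.55$, noise
  threshold $k = 2$) and Scharr gradient magnitude, combined per pixel and
  weighted by the maximal phase congruency; constants $T_1 = 0.85$,
  $T_2 = 160$.
* `surface_deviation()` — signed point-to-surface distances from each vertex
  of the generated mesh to the target mesh; RMS and SD. No re-registration
  by default: generated and target crowns share the adjacent-teeth frame, so
  they are already registered (an optional rigid ICP pre-step exists but is
  off by default, since re-registration would hide systematic placement
  errors).

## Problem sizes and the scaled study

The package's end-to-end study — also what `scripts/acceptance.R`
recomputes — uses 60 synthetic cases at 64×64 (48 train / 6 validation /
6 test), generator width 8 (64 in the full-size configuration; width scales
the channel progression, not the architecture), and a 5+5+10 epoch schedule.
These sizes were chosen so a complete seeded study runs in minutes on one
CPU core while still exercising every mechanism: at this scale Stage III
improves test-split PSNR/SSIM/FSIM over Stage I and all four objective
losses show decreasing smoothed trajectories. Quantitative values from the
original clinical setting (e.g. PSNR near 34 dB, RMS near 0.11 mm) belong to
a private 1000-patient dataset and a far larger training regime; they are
not reproducible here and the package makes no claim about them. On the
synthetic study the observed RMS deviation (~0.36 mm at 64×64) sits at the
level of the $\alpha = 2$ quantization bound (0.376 mm), which is the floor
for any method evaluated through this codec at this resolution.

## Known limitations

* Single tooth type (stylized mandibular first molar), mandibular side only.
* Height-field geometry: no undercuts, no interproximal detail.
* The CPU engine is deliberately minimal (no GPU, no mixed precision, no
  learning-rate schedules); widths beyond ~32 base filters become slow.
* FSIM follows the published construction but is an independent
  implementation; absolute values on unusual inputs may differ slightly from
  other implementations while orderings are preserved.
* The occlusal fingerprint is a proximity threshold, not a dentist
  annotation; its statistics are simpler than clinical contact patterns.
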