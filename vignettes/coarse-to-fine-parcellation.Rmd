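---
title: "Coarse-to-fine brain parcellation from diffusion scalar maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine brain parcellation from diffusion scalar maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkparc)
```

## The problem

Anatomical brain parcellations in the Desikan-Killiany (DK) scheme are
usually produced from T1-weighted MRI and then projected into diffusion
space by cross-modal registration, which is slow and error-prone at tissue
boundaries. `dkparc` instead predicts a 101-label DK-style parcellation
*directly* from diffusion-MRI-derived scalar maps, so that at inference
time no anatomical scan and no subject-specific registration is needed.

Two structural facts shape the design. First, DK labels are extremely
imbalanced: the largest label (cerebral white matter) can be tens of times
larger than a typical label, so a single 101-class model spends most of its
capacity on a few giant classes. Second, the label set has a natural
hierarchy: every final label belongs to one of seven coarse anatomical
compartments — left/right cerebral white matter (1 final label each),
left/right deep/periventricular non-cortical structures (13 each),
left/right cortical parcels (34 each), and midline/central structures (5):

$$1 + 1 + 13 + 13 + 34 + 34 + 5 = 101.$$

The pipeline therefore runs in two stages: a *coarse* model segments the
seven compartments (a nearly balanced 8-class problem), and five
*fine* models — one per non-terminal compartment — refine each compartment
into its final labels. The two white-matter compartments are terminal:
their single labels pass straight from the coarse stage into the final
output. The stages are trained sequentially, never jointly.

## Input channels

Per voxel, the diffusion tensor $D$ is fitted from the signal model
$S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i)$ by ordinary least squares on
$\ln S_i$ over all volumes (baselines included as rows with $b = 0$). From
the sorted eigenvalues $E_1 \ge E_2 \ge E_3$ the package derives

$$FA = \sqrt{\frac{(E_1-E_2)^2 + (E_2-E_3)^2 + (E_1-E_3)^2}
                  {2\,(E_1^2+E_2^2+E_3^2)}},$$

the trace $T = E_1+E_2+E_3$, and the Westin shape measures
$CL = (E_1-E_2)/T$, $CP = 2(E_2-E_3)/T$, $CS = 3E_3/T$, which satisfy
$CL + CP + CS = 1$ identically. The default model input is the ordered
four-channel set $(T, F, CS, E_1)$ — trace, FA, sphericity, maximum
eigenvalue — which combines diffusion magnitude, anisotropy, isotropy and
dominant-direction diffusivity; `assemble_maps()` exposes any of the eight
maps so channel-subset ablations can be run with the same machinery. The
channel *order* is part of a trained model's contract and is stored with
the model; mismatched input triggers a warning because predictions are
undefined under permutation.

The fine models receive a fifth channel: the coarse segmentation mask
scaled linearly to $[0, 1]$ as `coarse_id / 7`. A single scalar channel is
the simplest reading of "a five-channel volume"; one-hot encoding would
contradict it, and the linear scaling keeps the label magnitudes from
dominating the intensity channels. The four intensity channels are
z-scored over foreground voxels before training and inference; the mask
channel is left on its native $[0,1]$ scale by construction.

## Numerical choices

* **Tensor fit.** Ordinary (unweighted) least squares on log-signal; no
  weighting or iteration. Voxels with any non-positive signal, or outside
  an optional mask, are flagged invalid and zeroed. Multiple baselines are
  simply extra rows of the system. A gradient scheme whose design matrix is
  rank-deficient (fewer than six independent outer products) is rejected
  outright rather than silently pseudo-inverted.
* **Eigenvalues.** The per-voxel symmetric $3\times 3$ eigensystem is
  solved with the closed-form trigonometric method, fully vectorized. The
  trig solution loses about half the working precision near double
  eigenvalues (exactly the axially symmetric tensors that dominate white
  matter), so the isolated root is Newton-polished on the characteristic
  cubic and the degenerate pair recovered from the deflated quadratic;
  this restores ~1e-12 accuracy across the whole eigenvalue simplex.
* **Degenerate voxels.** Where $T \le 0$ or all eigenvalues vanish, every
  derived map falls back to 0; negative fitted eigenvalues are preserved in
  the raw eigenvalue maps as fit diagnostics, and FA is clipped at 1 (it
  can only exceed 1 when an eigenvalue is negative).
* **Trace convention.** "Trace" is the eigenvalue sum, not mean
  diffusivity; MD, used only for RSD reporting, is $T/3$.
* **Argmax ties** break toward the lower class id, everywhere, for
  determinism.

## The training engine and the reference backbone

The engine is backbone-agnostic: any object implementing
`predict_scores()` (voxel-wise class simplex on a channel patch) and, for
training, `train_step()` can be plugged in. The objective is the composite
soft-Dice + cross-entropy loss with equal 1:1 weighting,
$\varepsilon = 10^{-5}$, per-sample Dice with background excluded from the
Dice mean, and an optional inverse-label-frequency class weighting of the
cross-entropy term (weights normalized to mean 1; absent classes receive
the maximum observed weight). Patches are sampled with at least 50%
probability of containing foreground; the learning rate follows polynomial
decay of power 0.9.

The shipped reference backbone is deliberately tiny: a voxel-wise
multilayer perceptron — equivalently a stack of $1^3$ convolutions — over
the channel intensities plus a Fourier positional encoding of the voxel's
patch-relative position (normalized coordinates and sin/cos at frequencies
1–16 cycles per patch; under 100k parameters). The positional encoding is
what lets a receptive-field-1 network separate compartments whose tissue
contrast is identical (left vs right hemisphere, angular sectors of a
cortical ribbon); it is the CPU-trainable stand-in for the spatial context
a 3-D encoder-decoder acquires through its receptive field. Two
consequences are worth stating plainly: the backbone is intended to be
trained and applied with a patch spanning the whole (conformed) volume, so
its positional code is globally consistent; and with `use_coords = FALSE`
it degenerates to a pure intensity classifier, which is what the
sliding-window equivalence tests use. Optimization is SGD with classical
momentum 0.9 — plain fixed-step descent converges too slowly for the
34-class fine stages at desk-scale iteration counts, and momentum mirrors
the schedule conventionally used with this loss family.

Sliding-window inference tiles the padded volume with 0.5 overlap per axis
and accumulates window scores under a separable Gaussian weight
($\sigma$ = patch edge / 8, an unstated convention chosen here as common
practice) before voxel-wise renormalization to a probability simplex. For
any receptive-field-1 model this is provably equivalent to full-volume
prediction, which the suite asserts; for contextual models it suppresses
window-boundary artifacts.

Whether fine models should be trained against the reference coarse mask or
the coarse model's own prediction is genuinely open; both are provided
(`fine_mask = "reference"` is the default — teacher forcing keeps the five
fine problems independent of coarse-stage errors during training, while
`"predicted"` matches the inference-time distribution).

## Post-processing

The cleanup chain runs in a fixed order: (1) *restrict* — fine voxels
outside their compartment's coarse mask are removed; (2) *dilate-fill* —
up to 3 passes in which background voxels inside the mask adopt the
majority label of their labeled 26-neighbors (tie to the lowest id),
never overwriting labels and never crossing the mask. Unconditional
morphological dilation is ill-defined for overlapping multi-label volumes,
so the constrained majority fill realizes the stated purpose (closing
small gaps) deterministically; (3) *largest component* — per label,
26-connected components are ranked by size and only the largest kept (size
ties go to the component reached first in x-fastest scan order), with no
minimum-size threshold; this runs per group *before* merging, a point on
which the narrative order is ambiguous and which is flagged as a choice,
not an inference; (4) *merge* — terminal white-matter labels come from the
coarse map, refined voxels take their fine label, fine wins where both
claim a voxel, and orphaned voxels stay background (no second fill pass);
(5) optional nearest-neighbor resampling to the native grid and a
bijective lookup-table remap to an external id scheme (e.g. FreeSurfer
ids). After the chain, every non-background voxel's final label belongs to
the compartment the coarse map assigns there, and every label is a single
26-connected component — both are asserted as invariants in the suite.

Spatial normalization deserves a note: full nonlinear template registration
is outside this package's scope. The `conform()` contract — isotropic
spacing, cubic shape, fixed LIA orientation, affine resampling (defaults
1 mm / $256^3$, configurable down to phantom-sized cubes) — supplies the
co-registered working space, and `to_native()` inverts it. Whether any
behavior of the full method depends on the *nonlinearity* of a template
warp cannot be probed with affine machinery.

## Evaluation

`dsc()` is the standard overlap $2|P\cap R|/(|P|+|R|)$ (1 when both masks
are empty, 0 when exactly one is). `hd95()` pools directed Euclidean
boundary distances both ways (boundary = mask voxels with a background
6-neighbor; spacing-aware) and takes the 95th percentile with linear
interpolation; it is undefined, and reported missing, when either mask is
empty. `rsd()` is std/mean over a region's voxels with the *population*
standard deviation — the sample/population choice is unstated in the
sources this follows; population makes single-voxel regions well defined —
and is scale-invariant, which the suite asserts as a property.
`confidence_maps()` derives confidence (max score), uncertainty
(1 − confidence) and margin (top minus second score) from any score
volume. Macro tables average over labels present in either volume, so
spurious predicted labels are penalized rather than ignored.

## The synthetic phantom: what it does and does not show

`generate_labels()` builds a deterministic brain-like geometry hosting the
full hierarchy on a small cube: a ball split by the midsagittal plane;
per hemisphere a cortical shell split into 34 angular sectors, a deep
torus split into 13 sectors, and a single white-matter core; a midline
column with 5 axial bands. `simulate_dwi()` assigns each compartment a
diffusion-tensor archetype — white-matter-like $(1.7, 0.3, 0.3)\times
10^{-3}$ mm²/s with radially oriented principal axis, gray-matter-like
$(0.9, 0.7, 0.7)\times 10^{-3}$ on fixed axes, fluid-like
$(3.0, 3.0, 3.0)\times 10^{-3}$, $S_0 = 100$; literature-typical values
chosen once for well-separated $(T, F, CS, E_1)$ contrasts — and evaluates
the forward model at $b = 1000$ s/mm² over 64 spiral directions plus one
baseline, mirroring a legacy single-shell clinical acquisition. Noise is
Gaussian by default (keeping the zero-noise analytic oracle exact), with a
Rician option for realism; the default `noise_sigma` is 0 and the
end-to-end recovery checks use 0.5 (SNR 200 at baseline, "low noise").
Everything is a pure function of the `phantom_spec()` object and its seed.

The phantom reproduces the *structural* conditions the method addresses —
the 7-compartment hierarchy, heavy final-label imbalance that collapses
under coarse grouping (at grid 48 the max-to-median ratio falls from ~27
to ~1.3, and the `skew` knob pushes the final ratio above 10 on demand),
compartments distinguishable only by geometry, and tissue-contrast
separations of realistic magnitude. It deliberately omits gyrification,
partial-volume mixing, susceptibility distortion and inter-subject
variability; passing its recovery tests shows the pipeline's machinery is
correct and trainable, not that any particular backbone reaches a
particular accuracy on real brains.

## Problem sizes and defaults

The shipped configurations are desk-scale by design: phantom cubes of
24–48 voxels per edge, full-volume patches, 400 coarse / 600 fine
training iterations, learning rate 0.1 with polynomial decay, 8192
sampled voxels per step. The corresponding published-scale constants
(patch $128^3$, batch 2, 250k iterations, $256^3$ conformed grids) are
recorded in the documentation of `train_config()` and `conform()` and are
reachable by configuration — nothing in the code hard-wires the small
sizes. On the 48-voxel phantom at these defaults the full six-model fit
takes a few minutes on one CPU core and recovers the coarse compartments
essentially perfectly and the 101 final labels with macro DSC well above
0.9 (the acceptance script recomputes these numbers end-to-end).

## Known limitations

Single-tensor diffusion only (no multi-shell or higher-order models);
affine spatial normalization only; the reference backbone's positional
encoding assumes whole-volume patches and brain-centered framing, so it
memorizes geometry per training distribution rather than generalizing
across poses the way a convolutional backbone would; the exact external
(FreeSurfer) id memberships of the seven compartments are configuration,
not shipped fact — the default namespace is the synthetic 1..101
assignment, and users with an external mapping supply it as a hierarchy
config with a lookup table.
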