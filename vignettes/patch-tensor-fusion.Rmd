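---
title: "Patch-tensor wavelet fusion: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-tensor wavelet fusion: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorfuse)
```

## The problem and the model

Two imaging modalities of the same anatomy see different things: CT renders
dense structure with sharp, high-amplitude boundaries and an almost
featureless interior, while MR renders low-contrast soft-tissue texture and a
comparatively dim skull. Fusion aims at a single image that keeps both. The
package works in the wavelet domain: after a K-level separable 2-D DWT of
each source, the *approximation* band is fused by a fixed affine average and
every *detail* coefficient by a data-driven convex combination

$$W_F = \omega\, W_A + (1-\omega)\, W_B, \qquad
  \omega = \frac{\varphi_A}{\varphi_A + \varphi_B},$$

where $\varphi$ scores the local oriented structure of the corresponding
detail plane. The score is built in three stages, each exposed as a tested
function:

1. **Initial structure tensor** (`initial_structure_tensor`). Per pixel,
   $J_0 = \nabla I\, \nabla I^\top$ from central-difference gradients. Each
   $2\times 2$ matrix is positive semidefinite of rank $\le 1$: eigenvalues
   $|\nabla I|^2$ and $0$. Averaging tensors rather than gradients avoids the
   sign-cancellation that plain gradient averaging suffers on oscillating
   structure.

2. **Nonlocal-means filtering** (`patch_structure_tensor`). Plain Gaussian
   smoothing of $J_0$ (also available, `gaussian_structure_tensor`) blurs and
   dislocates structure because its weights depend only on distance. Instead
   each tensor plane is averaged with nonlocal-means weights
   $\omega(X,Y) \propto \exp(-d(X,Y)/h^2)$, where $d$ is the
   Gaussian-weighted squared difference of the image patches around $X$ and
   $Y$. Pixels on the same structure — however far within the search window —
   support each other; pixels across a boundary do not. One weight set per
   pixel, computed from the image intensities, is applied to all three tensor
   planes, so the filtered tensor is a convex combination of PSD rank-1
   tensors and stays symmetric PSD.

3. **Coherence** (`subband_coherence`). Closed-form eigenvalues
   $\mu_1 \ge \mu_2$ of the filtered tensor give the geometry taxonomy —
   $\mu_1\!\approx\!\mu_2\!\approx\!0$ flat, $\mu_1\!\gg\!\mu_2\!\approx\!0$
   edge, $\mu_1\!\ge\!\mu_2\!\gg\!0$ corner — and the coherence
   $\varphi = (\mu_1-\mu_2)^2$.

Assumptions: the two inputs are single-channel, co-registered, equally sized,
and normalized to $[0,1]$ (the loader enforces the last). Registration is the
caller's responsibility; even one pixel of misalignment degrades any
per-coefficient rule.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `wavelet` | `db3` | — | filter bank; db1–db4 available, all orthogonal with perfect reconstruction |
| `levels` | 3 | — | decomposition depth; deeper levels fuse coarser structure |
| `k1`, `k2` | 0.75 / 0.25 | — | approximation-band weights; favour the CT-like source A, whose mean brightness should dominate |
| `search_radius` | 5 | px | NLM search window $11\times11$ |
| `patch_radius` | 2 | px | similarity patches $5\times5$ |
| `h` | 0.15 | intensity | NLM decay; since images live in $[0,1]$ this is a fraction of the full range. Smaller h = more selective averaging |
| `rho` | `patch_radius/2` | px | std-dev of the Gaussian patch weighting, so the patch spans about $2\sigma$; kernel normalized to sum 1 |

`h` and `rho` have no single canonical value; the defaults are the common
heuristics stated above and both are exposed through `nlm_params()`. The
low-band weights are plain configuration: whether 0.75/0.25 "should" favour
CT is a data question, so the package attaches no modality semantics to A/B
beyond the default.

## Design choices where the design was open

* **High-band rule orientation.** The fused detail coefficient is
  $\omega W_A + (1-\omega) W_B$ with $\omega$ the A-share of coherence — the
  only reading under which the rule is a weighted sum of the *source*
  coefficients.
* **Coherence per sub-band, not per source image.** $\varphi$ is computed on
  each detail plane of each level independently, matching its per-sub-band
  indexing; the alternative (full-resolution $\varphi$, downsampled) would
  blur scale separation. NLM window sizes stay fixed across levels; where a
  coarse band is smaller than the window, the window clips to the band.
* **NLM normalizer and guide.** Weights are normalized over the (clipped)
  search window so they always sum to 1, with the same $h^2$ scaling in
  numerator and normalizer; weights come from the intensities of the plane's
  own image, shared across the three tensor planes (this is what preserves
  PSD).
* **Weighted-average baseline.** `fuse_wa` needs an activity measure; the
  canonical choice — local mean of squared coefficients over a $3\times3$
  window, $\omega = s_A/(s_A+s_B)$ — is implemented and documented as an
  interpretation. `fuse_cgm` compares central-difference gradient magnitudes
  of the sub-band planes themselves and takes A on ties.
* **EOG definition.** Defined here as $\mathrm{mean}(g_x^2+g_y^2)$ on the
  normalized image. Published absolute EOG values for clinical pairs are not
  comparable across normalizations; only the ordering of schemes on one pair
  is used.

## Numerical conventions

* Coordinates are row-major and 1-based in R; $x$ is the column index, $y$
  the row, so `gx` differentiates across columns.
* All boundary handling — gradients, NLM patches, Gaussian smoothing, DWT —
  uses half-sample symmetric (edge-repeating) reflection. One convention
  everywhere keeps every brute-force oracle three lines long.
* The DWT keeps $\lfloor (n+L-1)/2 \rfloor$ coefficients per band (redundant
  for odd $n$), records per-level shapes, and crops on synthesis: round trips
  are exact to ~1e-15 for any size down to the filter length $L$. Requesting
  a deeper decomposition than the image supports is an error that names the
  feasible depth.
* Eigenvectors at (near-)isotropic pixels, $(j_{11}-j_{22})^2+4j_{12}^2 <
  10^{-12}$, are pinned to $(1,0)/(0,1)$; any orthonormal pair is valid
  there, and a deterministic choice makes runs bit-reproducible.
  Where both coherences vanish the fusion weight is the symmetric limit 0.5.
* Fused reconstructions are clipped to $[0,1]$ (orthogonal synthesis can
  overshoot by a few ULPs to a few percent near hard edges); file output
  quantizes with round-half-to-even at 8 or 16 bits.
* The pipeline contains no randomness: fusing the same inputs twice is
  bit-identical.

## What the phantom emulates — and what it does not

`make_phantom_pair` generates the study conditions for all tests: one
128×128 pair (seed 1) with a bright elliptical rim and near-flat interior
(CT-like) versus a dim rim and textured interior — smoothed band-limited
noise plus three soft inclusions (MR-like) — identical geometry, small
seed-driven jitter of the layout, additive Gaussian noise of sd 0.01.
Defaults: rim intensity 0.9, texture amplitude 0.35. The pair reproduces the
*statistical* complementarity fusion exploits (rim detail lives in A,
interior detail in B — a tested invariant), which is what the fusion rules
actually consume.

It does not emulate: anatomy, MR physics (bias fields, Rician noise),
partial-volume effects, or registration error. Passing tests therefore
demonstrate correctness of the operators and the expected qualitative
behaviour of the rules, not clinical image quality.

## Problem sizes and verification strategy

Unit tests verify every operator against an independent brute-force loop
oracle (gradients, patch distances, NLM weights and filtering, per-pixel
eigen-decomposition via base R's solver, both baselines, EOG) on random
images up to 16×16 — small enough that the oracles stay literal triple
loops — plus analytic fixtures (ramps, steps, corners, impulses) with
closed-form answers. The wavelet transform is checked against coefficients
computed with an independent reference DWT implementation on a closed-form
12×10 fixture, frozen into the test, and by exact round trips on odd and
even sizes. End-to-end properties (self-fusion identity, scheme ordering of
EOG, the eigenvalue taxonomy) run on the 128×128 phantom; the whole suite
completes in a few seconds.

```{r example}
ph  <- make_phantom_pair(size = c(128, 128), seed = 1)
fusion_metrics(ph$ct, ph$mr)
```

## Known limitations

* Two sources only, grayscale only, 2-D only.
* PNG and TIFF input; no DICOM reader (no suitable R dependency), so clinical
  slices must be exported to 8/16-bit PNG/TIFF first — with the caveat that
  window/level choices made at export time change the normalized intensities.
* EOG is the only built-in metric; it rewards sharpness, not fidelity, which
  is why `cgm` can out-score the patch-tensor rule on it while producing
  selection artifacts near edges.
* NLM cost grows with the squared search radius; the default window is
  comfortable for slices up to a few hundred pixels a side on one CPU.
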