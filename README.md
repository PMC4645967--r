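# tensorfuse

Wavelet-domain fusion of two co-registered single-channel medical images —
typically a CT slice, which renders dense structure (bone, implants) with
high contrast, and an MR slice of the same anatomy, which renders soft-tissue
detail the CT lacks. The fused image keeps both: the per-coefficient decision
of *which* modality to trust is driven by the local geometry of each image,
measured with a **patch-based (nonlocal-means-filtered) structure tensor**.

## Method

Both images are decomposed with a K-level 2-D discrete wavelet transform
(default `db3`, 3 levels, symmetric extension, perfect reconstruction). The
approximation bands are combined with a fixed weighted average,

    W_F^L = k1 · W_A^L + k2 · W_B^L,        k1 = 0.75, k2 = 0.25.

Every detail band (LH/HL/HH at every level) is combined coefficient-wise as

    W_F = ω · W_A + (1 − ω) · W_B,          ω = φ_A / (φ_A + φ_B),

where φ is the **local coherence** of that sub-band: per pixel, form the
initial structure tensor J0 = ∇I ∇Iᵀ, filter each of its three component
planes with nonlocal-means weights (patch similarity over an 11×11 search
window with 5×5 Gaussian-weighted patches, shared weights per pixel so the
tensor stays symmetric positive semidefinite),

    J_NLM = NLM(J0),

take its closed-form eigenvalues μ1 ≥ μ2, and set φ = (μ1 − μ2)². φ is large
on edges and flow-like structure, zero in flat regions, so each fused detail
coefficient leans toward the modality with the stronger oriented structure.
The eigenvalue pair also classifies local geometry: μ1 ≈ μ2 ≈ 0 flat,
μ1 ≫ μ2 ≈ 0 edge, μ1 ≥ μ2 ≫ 0 corner.

Two classical baselines run inside the same wavelet framework for
comparison: an adaptive **weighted average** (`wa`, weights from local
activity) and **choose gradient max** (`cgm`, per-coefficient selection).
Results are scored with the **energy of image gradient**,
EOG = mean(gx² + gy²), a no-reference sharpness metric (defined here on
[0, 1]-normalized images; only the ranking across schemes is meaningful).

## Worked example

No clinical image pair ships with the package; a synthetic phantom pair with
the same CT/MR complementarity (bright rigid rim + flat interior vs. dim rim
+ textured interior) is generated in-package:

```r
library(tensorfuse)

ph    <- make_phantom_pair(size = c(128, 128), seed = 1)
fused <- fuse_images(ph$ct, ph$mr, fusion_config("patch_tensor"))
round(c(ct = eog(ph$ct), mr = eog(ph$mr), fused = eog(fused)), 6)
#>       ct       mr    fused
#> 0.014053 0.003817 0.013596

fusion_metrics(ph$ct, ph$mr)
#>         scheme       eog
#> 1           wa 0.0124997
#> 2          cgm 0.0140806
#> 3 patch_tensor 0.0135957
```

The fused image is nearly as sharp as the CT (whose EOG is dominated by the
rim) while also carrying the MR interior texture; the patch-tensor rule beats
the weighted average, which blurs detail wherever the two sources disagree.
`cgm` scores highest on raw EOG by construction — it always takes the larger
local gradient — at the price of selection artifacts near edges.

The same pipeline runs from a shell:

```sh
Rscript inst/scripts/tensorfuse phantom --output-a ct.png --output-b mr.png --seed 1
Rscript inst/scripts/tensorfuse fuse --input-a ct.png --input-b mr.png \
    --output fused.png --scheme patch --levels 3
Rscript inst/scripts/tensorfuse metrics --input-a ct.png --input-b mr.png
```

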