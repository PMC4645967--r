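#' Fusion pipeline configuration
#'
#' Collects every tunable of [fuse_images()]. Defaults are the standard
#' operating point of the method: `db3` wavelet, 3 levels, low-band weights
#' `k1 = 0.75` / `k2 = 0.25` favouring the first (CT-like) image, and an
#' 11x11 search window with 5x5 similarity patches for the nonlocal-means
#' tensor filter.
#'
#' @param scheme High-frequency fusion rule: `"patch_tensor"` (coherence
#'   weighting from the patch-based structure tensor), `"wa"` (adaptive
#'   weighted average), or `"cgm"` (choose gradient max).
#' @param wavelet Wavelet name. Default `"db3"`.
#' @param levels Decomposition depth. Default 3.
#' @param k1,k2 Low-band weights for images A and B; must sum to 1 and lie in
#'   \[0, 1\]. Defaults 0.75 / 0.25.
#' @param nlm [nlm_params()] for the patch-tensor scheme.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(scheme = c("patch_tensor", "wa", "cgm"),
                          wavelet = "db3", levels = 3L,
                          k1 = 0.75, k2 = 0.25,
                          nlm = nlm_params()) {
  scheme <- match.arg(scheme)
  if (abs(k1 + k2 - 1) > 1e-8 || k1 < 0 || k1 > 1 || k2 < 0 || k2 > 1) {
    stop("`k1` and `k2` must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  stopifnot(inherits(nlm, "nlm_params"))
  wavelet_filters(wavelet)  # fail early on unknown names
  structure(list(scheme = scheme, wavelet = wavelet, levels = levels,
                 k1 = k1, k2 = k2, nlm = nlm),
            class = "fusion_config")
}

#' Low-frequency sub-band fusion (fixed weighted average)
#'
#' `W_F = k1 * W_A + k2 * W_B`, elementwise.
#'
#' @param wlA,wlB Approximation planes of the two sources, same shape.
#' @param k1,k2 Weights summing to 1.
#' @return Fused plane.
#' @export
fuse_low <- function(wlA, wlB, k1 = 0.75, k2 = 0.25) {
  check_same_shape(wlA, wlB, c("wlA", "wlB"))
  k1 * wlA + k2 * wlB
}

#' Coherence-based high-frequency weights
#'
#' `omega = phiA / (phiA + phiB)`, elementwise, with `omega = 0.5` wherever
#' both coherences vanish (the symmetric, continuous limit).
#'
#' @param phiA,phiB Nonnegative coherence planes, same shape.
#' @return Weight plane in \[0, 1\].
#' @export
coherence_weight <- function(phiA, phiB) {
  check_same_shape(phiA, phiB, c("phiA", "phiB"))
  if (any(phiA < 0) || any(phiB < 0)) {
    stop("coherence planes must be nonnegative", call. = FALSE)
  }
  den <- phiA + phiB
  out <- matrix(0.5, nrow(phiA), ncol(phiA))
  pos <- den > 0
  out[pos] <- phiA[pos] / den[pos]
  out
}

#' High-frequency sub-band fusion by per-coefficient convex combination
#'
#' `W_F = omega * W_A + (1 - omega) * W_B`, elementwise.
#'
#' @param wA,wB Detail planes, same shape.
#' @param omega Weight plane in \[0, 1\], same shape.
#' @return Fused plane.
#' @export
fuse_high <- function(wA, wB, omega) {
  check_same_shape(wA, wB, c("wA", "wB"))
  check_same_shape(wA, omega, c("wA", "omega"))
  omega * wA + (1 - omega) * wB
}

#' Coherence map of one wavelet sub-band
#'
#' Runs the patch-tensor pipeline on a single detail plane: patch-based
#' structure tensor, closed-form eigen-decomposition, squared eigenvalue gap.
#' This is the per-coefficient geometry score that drives the patch-tensor
#' fusion rule; it is computed on each sub-band of each level independently.
#'
#' @param band Detail plane, at least 2x2.
#' @param p [nlm_params()].
#' @return Nonnegative matrix `phi`, same shape as `band`.
#' @export
subband_coherence <- function(band, p = nlm_params()) {
  coherence(eigen_decompose(patch_structure_tensor(band, p)))
}

fuse_detail_planes <- function(dA, dB, cfg) {
  fuse_one <- switch(cfg$scheme,
    patch_tensor = function(bA, bB) {
      omega <- coherence_weight(subband_coherence(bA, cfg$nlm),
                                subband_coherence(bB, cfg$nlm))
      fuse_high(bA, bB, omega)
    },
    wa = fuse_wa,
    cgm = fuse_cgm)
  lapply(stats::setNames(nm = c("LH", "HL", "HH")),
         function(o) fuse_one(dA[[o]], dB[[o]]))
}

#' Fuse two co-registered images in the wavelet domain
#'
#' Decomposes both images, combines the approximation planes with
#' [fuse_low()], combines every detail plane at every level with the rule
#' selected by `cfg$scheme`, and reconstructs. For `"patch_tensor"` the
#' detail weights come from the sub-band coherence of the patch-based
#' structure tensor, so at each coefficient the source with the stronger
#' oriented structure dominates. The reconstruction is clipped to \[0, 1\]
#' (it can overshoot the input range slightly).
#'
#' The images must already be co-registered; no alignment is performed.
#'
#' @param imgA,imgB Numeric matrices in \[0, 1\], identical dimensions.
#' @param cfg A [fusion_config()].
#' @return Fused image, same dimensions, values in \[0, 1\].
#' @export
#' @examples
#' ph <- make_phantom_pair(size = c(64, 64), seed = 7)
#' f <- fuse_images(ph$ct, ph$mr, fusion_config(levels = 2))
#' eog(f)
fuse_images <- function(imgA, imgB, cfg = fusion_config()) {
  validate_image(imgA, min_dim = 2L, arg = "imgA")
  validate_image(imgB, min_dim = 2L, arg = "imgB")
  check_same_shape(imgA, imgB, c("imgA", "imgB"))
  stopifnot(inherits(cfg, "fusion_config"))

  pA <- wavelet_decompose(imgA, cfg$wavelet, cfg$levels)
  pB <- wavelet_decompose(imgB, cfg$wavelet, cfg$levels)

  fused <- pA
  fused$low <- fuse_low(pA$low, pB$low, cfg$k1, cfg$k2)
  fused$details <- lapply(seq_len(cfg$levels), function(k) {
    fuse_detail_planes(pA$details[[k]], pB$details[[k]], cfg)
  })
  out <- wavelet_reconstruct(fused)
  pmin(pmax(out, 0), 1)
}
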