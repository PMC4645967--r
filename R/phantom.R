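#' Synthetic co-registered CT/MR-like phantom pair
#'
#' Builds two perfectly registered images of one simulated head-like object,
#' mimicking the complementarity the fusion method exploits:
#' \describe{
#'   \item{`ct`}{a bright elliptical rim (dense bone-like shell) around a
#'     near-flat interior — strong high-contrast boundary, little interior
#'     detail;}
#'   \item{`mr`}{a dim rim around a textured interior (smoothed band-limited
#'     noise plus a few elliptical soft-tissue inclusions) — rich low-contrast
#'     interior detail.}
#' }
#' The geometry (ellipse axes, center, inclusion placement) is a fixed layout
#' with small seed-driven jitter, so repeated calls with the same seed are
#' bit-identical. Optional zero-mean Gaussian noise is added to both images
#' before clipping to \[0, 1\].
#'
#' @param size `c(H, W)`, each at least 32 (so a 3-level pyramid fits).
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @param noise_sigma Additive Gaussian noise standard deviation, \[0, 1\]
#'   intensity units. Default 0.01.
#' @param rim_intensity Intensity of the CT-like rim. Default 0.9.
#' @param texture_amplitude Amplitude of the MR-like interior texture and
#'   inclusion contrast; 0 gives a flat interior. Default 0.35.
#' @return Object of class `phantom_pair`: list with images `ct` and `mr`
#'   plus logical masks `rim` and `interior` marking the shell and the
#'   enclosed region.
#' @export
make_phantom_pair <- function(size = c(128L, 128L), seed = 1L,
                              noise_sigma = 0.01, rim_intensity = 0.9,
                              texture_amplitude = 0.35) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 32L || W < 32L) {
    stop("phantom must be at least 32x32 to support a 3-level pyramid",
         call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)

  with_seed(seed, {
    jit <- stats::runif(4, -0.02, 0.02)
    a <- (0.40 + jit[1]) * W
    b <- (0.44 + jit[2]) * H
    cx <- (0.5 + jit[3] / 2) * W
    cy <- (0.5 + jit[4] / 2) * H
    x <- matrix(seq_len(W), H, W, byrow = TRUE)
    y <- matrix(seq_len(H), H, W)
    re <- sqrt(((x - cx) / a)^2 + ((y - cy) / b)^2)
    rim <- re >= 0.85 & re <= 1.0
    interior <- re < 0.85

    ct <- matrix(0.05, H, W)
    ct[interior] <- 0.25
    ct[rim] <- rim_intensity

    mr <- matrix(0.05, H, W)
    mr[rim] <- 0.20
    tex <- matrix(stats::rnorm(H * W), H, W)
    tex <- conv2_sep(tex, gaussian_kernel1d(1.5))
    tex <- tex / stats::sd(tex)
    mr[interior] <- 0.45 + texture_amplitude * 0.4 * tex[interior]

    # soft-tissue inclusions at fixed fractions of the interior, jittered
    inc <- cbind(fx = c(0.38, 0.60, 0.50), fy = c(0.40, 0.55, 0.68),
                 fr = c(0.10, 0.08, 0.06),
                 dv = texture_amplitude * c(0.55, -0.45, 0.65))
    inc_jit <- stats::runif(nrow(inc), -0.015, 0.015)
    for (i in seq_len(nrow(inc))) {
      dx <- x - ((inc[i, "fx"] + inc_jit[i]) * W)
      dy <- y - (inc[i, "fy"] * H)
      rad <- inc[i, "fr"] * min(H, W)
      blob <- (dx^2 + dy^2 <= rad^2) & interior
      mr[blob] <- mr[blob] + inc[i, "dv"]
    }

    if (noise_sigma > 0) {
      ct <- ct + matrix(stats::rnorm(H * W, sd = noise_sigma), H, W)
      mr <- mr + matrix(stats::rnorm(H * W, sd = noise_sigma), H, W)
    }
    structure(list(ct = pmin(pmax(ct, 0), 1),
                   mr = pmin(pmax(mr, 0), 1),
                   rim = rim, interior = interior),
              class = "phantom_pair")
  })
}

#' Analytic test patterns
#'
#' Deterministic single-feature images used as fixtures for the tensor
#' pipeline: `constant` (all 0.5), `ramp` (intensity rises linearly with the
#' column index from 0 to 1), `step` (left half 0, right half 1), `corner`
#' (top-left quadrant 1, rest 0), and `impulse` (single bright center pixel).
#'
#' @param kind Pattern name.
#' @param size `c(H, W)`.
#' @return Numeric matrix in \[0, 1\].
#' @export
make_test_pattern <- function(kind = c("constant", "ramp", "step",
                                       "corner", "impulse"),
                              size = c(32L, 32L)) {
  kind <- match.arg(kind)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  stopifnot(H >= 1L, W >= 1L)
  col_idx <- matrix(seq_len(W), H, W, byrow = TRUE)
  row_idx <- matrix(seq_len(H), H, W)
  switch(kind,
    constant = matrix(0.5, H, W),
    ramp = (col_idx - 1) / max(W - 1, 1),
    step = (col_idx > W / 2) * 1.0,
    corner = ((row_idx <= H / 2) & (col_idx <= W / 2)) * 1.0,
    impulse = {
      m <- matrix(0, H, W)
      m[(H + 1L) %/% 2L, (W + 1L) %/% 2L] <- 1
      m
    })
}
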