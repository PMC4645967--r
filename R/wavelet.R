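# Daubechies decomposition low-pass filters (orthonormal; standard taps).
# The remaining filters of the bank follow from the quadrature-mirror
# relations: rec_lo = rev(dec_lo), dec_hi = (-1)^k * rec_lo, rec_hi = rev(dec_hi).
.wavelet_dec_lo <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db1  = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(-0.12940952255126037, 0.2241438680420134,
           0.8365163037378079, 0.48296291314453416),
  db3  = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
           0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4  = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
           -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
           0.7148465705529157, 0.2303778133088965)
)

#' Filter bank of a named orthogonal wavelet
#'
#' @param name One of `"haar"`, `"db1"`--`"db4"`.
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and filter
#'   length `length`.
#' @export
wavelet_filters <- function(name = "db3") {
  dec_lo <- .wavelet_dec_lo[[tolower(name)]]
  if (is.null(dec_lo)) {
    stop(sprintf("unknown wavelet '%s' (available: %s)", name,
                 paste(names(.wavelet_dec_lo), collapse = ", ")),
         call. = FALSE)
  }
  rec_lo <- rev(dec_lo)
  dec_hi <- rec_lo * (-1)^seq_along(rec_lo)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rec_lo, rec_hi = rev(dec_hi),
       length = length(dec_lo))
}

# One analysis step down each column: symmetric extension by L-1 samples,
# full convolution with the filter, downsample by 2 keeping samples
# L+1, L+3, ... — floor((n + L - 1)/2) coefficients per column.
dwt_step_cols <- function(m, f) {
  n <- nrow(m); L <- length(f)
  mp <- m[reflect_index(seq.int(2L - L, n + L - 1L), n), , drop = FALSE]
  np <- nrow(mp)
  y <- matrix(0, np + L - 1L, ncol(m))
  for (k in seq_len(L)) {
    y[k:(k + np - 1L), ] <- y[k:(k + np - 1L), ] + f[k] * mp
  }
  y[seq.int(L + 1L, by = 2L, length.out = (n + L - 1L) %/% 2L), ,
    drop = FALSE]
}

# One synthesis step along columns: upsample both coefficient sets, full
# convolution with the reconstruction filters, trim L-2 samples per end,
# crop to the target length.
idwt_step_cols <- function(ca, cd, flt, out_len) {
  n <- nrow(ca); L <- flt$length
  up <- function(c0) {
    u <- matrix(0, 2L * n - 1L, ncol(c0))
    u[seq.int(1L, 2L * n - 1L, 2L), ] <- c0
    u
  }
  conv_full <- function(x, f) {
    nx <- nrow(x)
    y <- matrix(0, nx + L - 1L, ncol(x))
    for (k in seq_len(L)) {
      y[k:(k + nx - 1L), ] <- y[k:(k + nx - 1L), ] + f[k] * x
    }
    y
  }
  y <- conv_full(up(ca), flt$rec_lo) + conv_full(up(cd), flt$rec_hi)
  y <- y[(L - 1L):(nrow(y) - L + 2L), , drop = FALSE]
  y[seq_len(out_len), , drop = FALSE]
}

# Single-level separable 2-D analysis. Returns LL and the detail triple in
# the orientation convention: LH responds to variation along y (horizontal
# edges), HL along x (vertical edges), HH to diagonal detail.
dwt2_step <- function(img, flt) {
  loy <- dwt_step_cols(img, flt$dec_lo)        # low-pass along y
  hiy <- dwt_step_cols(img, flt$dec_hi)
  t_dwt <- function(m, f) t(dwt_step_cols(t(m), f))
  list(LL = t_dwt(loy, flt$dec_lo),
       LH = t_dwt(hiy, flt$dec_lo),
       HL = t_dwt(loy, flt$dec_hi),
       HH = t_dwt(hiy, flt$dec_hi))
}

idwt2_step <- function(bands, flt, out_dim) {
  H <- out_dim[1]; W <- out_dim[2]
  t_idwt <- function(ca, cd, len) t(idwt_step_cols(t(ca), t(cd), flt, len))
  loy <- t_idwt(bands$LL, bands$HL, W)
  hiy <- t_idwt(bands$LH, bands$HH, W)
  idwt_step_cols(loy, hiy, flt, H)
}

#' Multilevel 2-D discrete wavelet decomposition
#'
#' Separable multilevel DWT with half-sample symmetric boundary extension and
#' perfect reconstruction (see [wavelet_reconstruct()]). Detail levels are
#' ordered finest first; each holds the `LH`, `HL` and `HH` orientation
#' planes.
#'
#' @param img Numeric matrix.
#' @param wavelet Wavelet name, see [wavelet_filters()]. Default `"db3"`.
#' @param levels Decomposition depth `K >= 1`. Default 3.
#' @return Object of class `wavelet_pyramid`: list with `low` (the coarsest
#'   approximation plane), `details` (list of `K` lists of `LH`/`HL`/`HH`
#'   matrices, finest first), `wavelet`, `levels`, and the per-level input
#'   shapes needed for reconstruction.
#' @export
wavelet_decompose <- function(img, wavelet = "db3", levels = 3L) {
  validate_image(img, min_dim = 2L)
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  flt <- wavelet_filters(wavelet)

  feasible <- function(H, W) {
    d <- 0L
    while (min(H, W) >= flt$length) {
      H <- (H + flt$length - 1L) %/% 2L
      W <- (W + flt$length - 1L) %/% 2L
      d <- d + 1L
    }
    d
  }
  dmax <- feasible(nrow(img), ncol(img))
  if (levels > dmax) {
    stop(sprintf(
      "image %dx%d supports at most %d level(s) of '%s' decomposition, %d requested",
      nrow(img), ncol(img), dmax, wavelet, levels), call. = FALSE)
  }

  cur <- img
  details <- vector("list", levels)
  shapes <- vector("list", levels)
  for (k in seq_len(levels)) {
    shapes[[k]] <- dim(cur)
    s <- dwt2_step(cur, flt)
    details[[k]] <- list(LH = s$LH, HL = s$HL, HH = s$HH)
    cur <- s$LL
  }
  structure(list(low = cur, details = details, wavelet = wavelet,
                 levels = levels, shapes = shapes),
            class = "wavelet_pyramid")
}

#' Inverse multilevel 2-D wavelet transform
#'
#' Reconstructs the image from a [wavelet_decompose()] pyramid. The
#' round trip `wavelet_reconstruct(wavelet_decompose(img))` reproduces `img`
#' to floating-point accuracy.
#'
#' @param pyr A `wavelet_pyramid`.
#' @return Numeric matrix with the original image dimensions.
#' @export
wavelet_reconstruct <- function(pyr) {
  stopifnot(inherits(pyr, "wavelet_pyramid"))
  flt <- wavelet_filters(pyr$wavelet)
  cur <- pyr$low
  for (k in rev(seq_len(pyr$levels))) {
    d <- pyr$details[[k]]
    cur <- idwt2_step(list(LL = cur, LH = d$LH, HL = d$HL, HH = d$HH),
                      flt, pyr$shapes[[k]])
  }
  cur
}
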