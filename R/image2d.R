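#' tensorfuse: patch-tensor wavelet fusion of multimodal images
#'
#' Images are plain numeric matrices indexed `img[row, col]`. The x axis is
#' the column index and the y axis is the row index, so `gx` is the
#' derivative across columns and `gy` across rows. All pipeline functions
#' expect intensities normalized to \[0, 1\] (what [load_image()] produces).
#'
#' @keywords internal
"_PACKAGE"

# Half-sample symmetric ("mirror with edge repeat") index reflection.
# Maps any integer index, however far outside 1..n, back into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Pad a matrix by pr rows / pc columns on every side with symmetric reflection.
pad_matrix <- function(m, pr, pc = pr) {
  m[reflect_index(seq.int(1L - pr, nrow(m) + pr), nrow(m)),
    reflect_index(seq.int(1L - pc, ncol(m) + pc), ncol(m)),
    drop = FALSE]
}

validate_image <- function(img, min_dim = 1L, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("`%s` must be at least %dx%d, got %dx%d",
                 arg, min_dim, min_dim, nrow(img), ncol(img)), call. = FALSE)
  }
  invisible(img)
}

check_same_shape <- function(a, b, what = c("a", "b")) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("`%s` (%dx%d) and `%s` (%dx%d) must have identical dimensions",
                 what[1], nrow(a), ncol(a), what[2], nrow(b), ncol(b)),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Rescale an image to the unit intensity range
#'
#' Linearly maps intensities to \[0, 1\]. A constant image maps to all zeros.
#'
#' @param img Numeric matrix.
#' @return Numeric matrix with `min >= 0`, `max <= 1`.
#' @export
normalize_image <- function(img) {
  validate_image(img)
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable 2-D convolution with a symmetric odd-length 1-D kernel applied
# along both axes, symmetric boundary extension, output same size as input.
conv2_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  mp <- pad_matrix(m, r)
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, W + 2L * r)
  for (u in seq_along(k)) {
    tmp <- tmp + k[u] * mp[u:(u + H - 1L), , drop = FALSE]
  }
  out <- matrix(0, H, W)
  for (u in seq_along(k)) {
    out <- out + k[u] * tmp[, u:(u + W - 1L), drop = FALSE]
  }
  out
}

# Sampled Gaussian kernel, radius 3*sigma, normalized to sum 1.
gaussian_kernel1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  stopifnot(sigma > 0)
  t <- seq.int(-radius, radius)
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

#' Display a grayscale image
#'
#' Thin wrapper around [graphics::image()] with the row/column orientation
#' used throughout the package (row 1 at the top).
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `img`.
#' @export
plot_image <- function(img, main = "", ...) {
  validate_image(img)
  graphics::image(t(img)[, nrow(img):1, drop = FALSE],
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  axes = FALSE, asp = nrow(img) / ncol(img), main = main, ...)
  invisible(img)
}
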