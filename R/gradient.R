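#' Central-difference image gradient
#'
#' Computes the two first-order derivatives of an image with central
#' differences and half-sample symmetric boundary extension. `gx` is the
#' derivative along columns (the x axis), `gy` along rows (the y axis).
#'
#' @param img Numeric matrix, at least 2x2.
#' @return An object of class `gradient_field`: a list with matrices `gx`
#'   and `gy`, each the size of `img`.
#' @export
#' @examples
#' g <- compute_gradient(make_test_pattern("ramp", c(8, 8)))
#' g$gx[4, 4]  # unit slope (in normalized column units)
compute_gradient <- function(img) {
  validate_image(img, min_dim = 2L)
  H <- nrow(img); W <- ncol(img)
  ip <- pad_matrix(img, 1L)
  gx <- (ip[2:(H + 1), 3:(W + 2), drop = FALSE] -
         ip[2:(H + 1), 1:W, drop = FALSE]) / 2
  gy <- (ip[3:(H + 2), 2:(W + 1), drop = FALSE] -
         ip[1:H, 2:(W + 1), drop = FALSE]) / 2
  structure(list(gx = gx, gy = gy), class = "gradient_field")
}

#' Energy of image gradient (EOG)
#'
#' A no-reference sharpness score: the mean over pixels of the squared
#' gradient magnitude, `mean(gx^2 + gy^2)`, using the package-wide
#' central-difference gradient. Zero only for a constant image. The absolute
#' scale depends on the intensity normalization (images here live in
#' \[0, 1\]); the score is used to *rank* fusion schemes, not as an absolute
#' quantity.
#'
#' @param img Numeric matrix, at least 2x2.
#' @return Nonnegative scalar.
#' @export
eog <- function(img) {
  g <- compute_gradient(img)
  mean(g$gx^2 + g$gy^2)
}
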