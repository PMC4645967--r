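#' Initial structure tensor
#'
#' Per-pixel outer product of the image gradient with itself,
#' `J0 = grad(I) grad(I)^T`. Each pixel's 2x2 matrix
#' `[[j11, j12], [j12, j22]]` is positive semidefinite with rank at most 1:
#' its eigenvalues are the squared gradient magnitude and 0.
#'
#' @param grad A `gradient_field` from [compute_gradient()].
#' @return An object of class `tensor_field`: a list with matrices `j11`,
#'   `j12`, `j22`.
#' @export
initial_structure_tensor <- function(grad) {
  stopifnot(inherits(grad, "gradient_field"))
  if (!all(is.finite(grad$gx)) || !all(is.finite(grad$gy))) {
    stop("gradient field contains non-finite values", call. = FALSE)
  }
  structure(list(j11 = grad$gx^2,
                 j12 = grad$gx * grad$gy,
                 j22 = grad$gy^2),
            class = "tensor_field")
}

#' Gaussian-smoothed (linear) structure tensor
#'
#' Convolves each tensor component with a normalized Gaussian kernel of
#' standard deviation `rho` pixels. Smoothing with nonnegative normalized
#' weights preserves symmetry and positive semidefiniteness.
#'
#' @param t A `tensor_field`.
#' @param rho Positive Gaussian standard deviation in pixels.
#' @return A smoothed `tensor_field`.
#' @export
gaussian_structure_tensor <- function(t, rho) {
  stopifnot(inherits(t, "tensor_field"))
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("`rho` must be a positive scalar", call. = FALSE)
  }
  k <- gaussian_kernel1d(rho)
  structure(list(j11 = conv2_sep(t$j11, k),
                 j12 = conv2_sep(t$j12, k),
                 j22 = conv2_sep(t$j22, k)),
            class = "tensor_field")
}

#' Closed-form eigen-decomposition of a symmetric 2x2 tensor field
#'
#' Per pixel, for the matrix `[[j11, j12], [j12, j22]]`:
#' `mu1,2 = (j11 + j22 +/- sqrt((j11 - j22)^2 + 4 j12^2)) / 2`, with
#' `mu1 >= mu2`, and unit orthogonal eigenvectors. At (near-)isotropic pixels
#' where `(j11 - j22)^2 + 4 j12^2 < 1e-12` the eigenvector pair is fixed to
#' `v1 = (1, 0)`, `v2 = (0, 1)` for reproducibility.
#'
#' Eigenvector components are (x, y) = (column, row) direction cosines.
#'
#' @param t A `tensor_field`.
#' @return An object of class `eigen_field`: list with matrices `mu1`, `mu2`,
#'   `v1x`, `v1y`, `v2x`, `v2y`.
#' @export
eigen_decompose <- function(t) {
  stopifnot(inherits(t, "tensor_field"))
  a <- t$j11; b <- t$j12; c <- t$j22
  tr <- a + c
  disc2 <- (a - c)^2 + 4 * b^2
  disc <- sqrt(disc2)
  mu1 <- (tr + disc) / 2
  mu2 <- (tr - disc) / 2
  theta <- 0.5 * atan2(2 * b, a - c)
  v1x <- cos(theta); v1y <- sin(theta)
  iso <- disc2 < 1e-12
  v1x[iso] <- 1; v1y[iso] <- 0
  structure(list(mu1 = mu1, mu2 = mu2,
                 v1x = v1x, v1y = v1y,
                 v2x = -v1y, v2y = v1x),
            class = "eigen_field")
}

#' Local coherence measure
#'
#' The squared eigenvalue gap `phi = (mu1 - mu2)^2`. Large where one
#' orientation dominates (edges, flow-like structure), zero in homogeneous
#' regions where the eigenvalues coincide.
#'
#' @param e An `eigen_field` from [eigen_decompose()].
#' @return Nonnegative matrix `phi`.
#' @export
coherence <- function(e) {
  stopifnot(inherits(e, "eigen_field"))
  (e$mu1 - e$mu2)^2
}
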