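#' Nonlocal-means parameters
#'
#' @param search_radius Search-window radius in pixels; the window is
#'   `(2*search_radius+1)` squared. Default 5 (an 11x11 window).
#' @param patch_radius Similarity-patch radius `r`; patches are
#'   `(2*patch_radius+1)` squared. Default 2 (5x5 patches).
#' @param h Filtering strength in normalized intensity units; weights are
#'   `exp(-d/h^2)`. Default 0.15, a common fraction of the unit intensity
#'   range.
#' @param rho Standard deviation (pixels) of the Gaussian weighting of the
#'   patch difference. Default `max(patch_radius, 1) / 2`, so roughly two
#'   standard deviations cover the patch.
#' @return An object of class `nlm_params`.
#' @export
nlm_params <- function(search_radius = 5L, patch_radius = 2L,
                       h = 0.15, rho = NULL) {
  search_radius <- as.integer(search_radius)
  patch_radius <- as.integer(patch_radius)
  if (is.null(rho)) rho <- max(patch_radius, 1L) / 2
  if (patch_radius < 0L || search_radius < patch_radius) {
    stop("need search_radius >= patch_radius >= 0", call. = FALSE)
  }
  if (!is.numeric(h) || h <= 0) stop("`h` must be > 0", call. = FALSE)
  if (!is.numeric(rho) || rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  structure(list(search_radius = search_radius, patch_radius = patch_radius,
                 h = h, rho = rho),
            class = "nlm_params")
}

# Gaussian patch-weighting kernel G_rho over a (2r+1)^2 patch, sum 1.
patch_kernel <- function(p) {
  r <- p$patch_radius
  if (r == 0L) return(matrix(1, 1, 1))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * p$rho^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Gaussian-weighted squared patch distance
#'
#' `d(X, Y) = sum_u G_rho(u) * (I(X+u) - I(Y+u))^2` over patch offsets `u`,
#' with patches read from the symmetrically padded image and `G_rho`
#' normalized to sum 1. Symmetric in its arguments and zero when `X == Y`.
#'
#' @param img Numeric matrix.
#' @param X,Y Integer `c(row, col)` pixel coordinates (1-based).
#' @param p [nlm_params()].
#' @return Nonnegative scalar.
#' @export
patch_distance <- function(img, X, Y, p = nlm_params()) {
  validate_image(img)
  r <- p$patch_radius
  G <- patch_kernel(p)
  ip <- pad_matrix(img, r)
  px <- ip[(X[1]):(X[1] + 2 * r), (X[2]):(X[2] + 2 * r), drop = FALSE]
  py <- ip[(Y[1]):(Y[1] + 2 * r), (Y[2]):(Y[2] + 2 * r), drop = FALSE]
  sum(G * (px - py)^2)
}

#' Nonlocal-means weight map at one pixel
#'
#' Weights `w(X, Y) = exp(-d(X, Y)/h^2) / Z(X)` for every pixel `Y` of the
#' search window centered on `X`, with `Z(X)` the sum of the unnormalized
#' weights over the window. Window positions falling outside the image carry
#' weight 0 (the window is clipped to the image), so the returned map always
#' sums to 1.
#'
#' @inheritParams patch_distance
#' @param X Integer `c(row, col)` center pixel.
#' @return A `(2*search_radius+1)` square matrix of weights in \[0, 1\];
#'   entry `[a, b]` is the weight of the pixel at offset
#'   `(a - search_radius - 1, b - search_radius - 1)` from `X`.
#' @export
nlm_weights <- function(img, X, p = nlm_params()) {
  validate_image(img)
  s <- p$search_radius
  n <- 2L * s + 1L
  w <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      Y <- c(X[1] + a - s - 1L, X[2] + b - s - 1L)
      if (Y[1] >= 1L && Y[1] <= nrow(img) && Y[2] >= 1L && Y[2] <= ncol(img)) {
        w[a, b] <- exp(-patch_distance(img, X, Y, p) / p$h^2)
      }
    }
  }
  w / sum(w)
}

# Valid-region separable convolution of E with the outer product of g with
# itself; output is smaller than E by length(g)-1 along each axis.
conv2_valid_sep <- function(E, g) {
  L <- length(g)
  n1 <- nrow(E) - L + 1L
  tmp <- matrix(0, n1, ncol(E))
  for (u in seq_len(L)) {
    tmp <- tmp + g[u] * E[u:(u + n1 - 1L), , drop = FALSE]
  }
  n2 <- ncol(E) - L + 1L
  out <- matrix(0, n1, n2)
  for (u in seq_len(L)) {
    out <- out + g[u] * tmp[, u:(u + n2 - 1L), drop = FALSE]
  }
  out
}

# Core NLM engine: filter several planes with one shared weight set computed
# from `guide`. Offset (shifted-image) formulation: for each search offset t,
# patch distances d(x, x+t) for all x at once via a valid convolution of the
# squared shifted difference with the Gaussian patch kernel.
nlm_apply <- function(planes, guide, p) {
  s <- p$search_radius; r <- p$patch_radius
  H <- nrow(guide); W <- ncol(guide)
  g1 <- {
    if (r == 0L) 1
    else {
      t <- seq.int(-r, r)
      k <- exp(-t^2 / (2 * p$rho^2))
      k / sum(k)
    }
  }
  P <- s + r
  A <- pad_matrix(guide, P)
  planes_p <- lapply(planes, pad_matrix, pr = s)
  num <- lapply(planes, function(x) matrix(0, H, W))
  den <- matrix(0, H, W)
  rows0 <- (P + 1L - r):(P + H + r)
  cols0 <- (P + 1L - r):(P + W + r)
  h2 <- p$h^2
  for (dr in -s:s) {
    # rows x of the image for which x+dr stays inside the image
    vr <- max(1L, 1L - dr):min(H, H - dr)
    for (dc in -s:s) {
      vc <- max(1L, 1L - dc):min(W, W - dc)
      E <- (A[rows0, cols0] - A[rows0 + dr, cols0 + dc])^2
      D <- conv2_valid_sep(E, g1)
      wgt <- matrix(0, H, W)
      wgt[vr, vc] <- exp(-D[vr, vc, drop = FALSE] / h2)
      den <- den + wgt
      for (i in seq_along(planes)) {
        shifted <- planes_p[[i]][(s + 1L + dr):(s + H + dr),
                                 (s + 1L + dc):(s + W + dc), drop = FALSE]
        num[[i]] <- num[[i]] + wgt * shifted
      }
    }
  }
  lapply(num, function(x) x / den)
}

#' Nonlocal-means filtering of one plane with weights from a guide signal
#'
#' Each output pixel is the weighted average of `plane` over the search
#' window, with weights computed from patch similarity in `guide` (weights as
#' in [nlm_weights()]). Filtering a constant plane returns that constant; as
#' `h` grows the output approaches the box mean of the (clipped) window.
#'
#' @param plane Numeric matrix of values to filter.
#' @param guide Numeric matrix defining the patch-similarity weights; must
#'   match `plane` in shape.
#' @param p [nlm_params()].
#' @return Filtered matrix, same shape.
#' @export
nlm_filter_plane <- function(plane, guide, p = nlm_params()) {
  validate_image(plane, arg = "plane")
  validate_image(guide, arg = "guide")
  check_same_shape(plane, guide, c("plane", "guide"))
  nlm_apply(list(plane), guide, p)[[1]]
}

#' Patch-based (nonlocal-means-filtered) structure tensor
#'
#' Builds the initial structure tensor of the image, then filters each of its
#' three component planes by nonlocal means. The weights are computed once
#' per pixel from the image intensities and the same weight set is applied to
#' all three planes, so symmetry and positive semidefiniteness are preserved
#' (each pixel's tensor becomes a convex combination of rank-1 PSD tensors).
#'
#' @param img Numeric matrix, at least 2x2.
#' @param p [nlm_params()].
#' @return A `tensor_field`.
#' @export
patch_structure_tensor <- function(img, p = nlm_params()) {
  j0 <- initial_structure_tensor(compute_gradient(img))
  f <- nlm_apply(list(j0$j11, j0$j12, j0$j22), img, p)
  structure(list(j11 = f[[1]], j12 = f[[2]], j22 = f[[3]]),
            class = "tensor_field")
}
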