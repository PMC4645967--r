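# 3x3 box mean with symmetric boundary extension.
box3_mean <- function(m) {
  conv2_sep(m, rep(1 / 3, 3))
}

#' Adaptive weighted-average (WA) detail fusion
#'
#' Per-coefficient convex combination with weights proportional to local
#' activity, measured as the 3x3 box mean of the squared coefficients:
#' `omega = sA / (sA + sB)`, with `omega = 0.5` where both activities vanish.
#'
#' @param wA,wB Detail planes, same shape.
#' @return Fused plane.
#' @export
fuse_wa <- function(wA, wB) {
  check_same_shape(wA, wB, c("wA", "wB"))
  sA <- box3_mean(wA^2)
  sB <- box3_mean(wB^2)
  den <- sA + sB
  omega <- matrix(0.5, nrow(wA), ncol(wA))
  pos <- den > 0
  omega[pos] <- sA[pos] / den[pos]
  omega * wA + (1 - omega) * wB
}

#' Choose-gradient-max (CGM) detail fusion
#'
#' Per coefficient, selects the source whose sub-band plane has the larger
#' local gradient magnitude (central differences on the plane itself,
#' `sqrt(gx^2 + gy^2)`); ties go to image A. Every output coefficient is
#' exactly one of the two inputs.
#'
#' @param wA,wB Detail planes, same shape, at least 2x2.
#' @return Fused plane.
#' @export
fuse_cgm <- function(wA, wB) {
  check_same_shape(wA, wB, c("wA", "wB"))
  gA <- compute_gradient(wA)
  gB <- compute_gradient(wB)
  takeA <- sqrt(gA$gx^2 + gA$gy^2) >= sqrt(gB$gx^2 + gB$gy^2)
  out <- wB
  out[takeA] <- wA[takeA]
  out
}
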