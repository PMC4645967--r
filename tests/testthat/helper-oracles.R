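# Independent brute-force oracles. Everything here is written as literal
# per-pixel loops (or calls into base R solvers) so that it shares no code
# with the vectorized implementations it checks.

# Half-sample symmetric reflection by explicit bouncing.
o_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

o_at <- function(img, r, c) img[o_reflect(r, nrow(img)), o_reflect(c, ncol(img))]

oracle_gradient <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    gx[i, j] <- (o_at(img, i, j + 1) - o_at(img, i, j - 1)) / 2
    gy[i, j] <- (o_at(img, i + 1, j) - o_at(img, i - 1, j)) / 2
  }
  list(gx = gx, gy = gy)
}

oracle_eog <- function(img) {
  g <- oracle_gradient(img)
  s <- 0
  for (i in 1:nrow(img)) for (j in 1:ncol(img)) {
    s <- s + g$gx[i, j]^2 + g$gy[i, j]^2
  }
  s / (nrow(img) * ncol(img))
}

oracle_patch_kernel <- function(r, rho) {
  k <- matrix(0, 2 * r + 1, 2 * r + 1)
  for (u in -r:r) for (v in -r:r) {
    k[u + r + 1, v + r + 1] <- exp(-(u^2) / (2 * rho^2)) *
                               exp(-(v^2) / (2 * rho^2))
  }
  k / sum(k)
}

oracle_patch_distance <- function(img, X, Y, p) {
  r <- p$patch_radius
  if (r == 0) return((o_at(img, X[1], X[2]) - o_at(img, Y[1], Y[2]))^2)
  G <- oracle_patch_kernel(r, p$rho)
  d <- 0
  for (u in -r:r) for (v in -r:r) {
    d <- d + G[u + r + 1, v + r + 1] *
      (o_at(img, X[1] + u, X[2] + v) - o_at(img, Y[1] + u, Y[2] + v))^2
  }
  d
}

oracle_nlm_weights <- function(img, X, p) {
  s <- p$search_radius
  w <- matrix(0, 2 * s + 1, 2 * s + 1)
  for (a in -s:s) for (b in -s:s) {
    Y <- c(X[1] + a, X[2] + b)
    if (Y[1] >= 1 && Y[1] <= nrow(img) && Y[2] >= 1 && Y[2] <= ncol(img)) {
      w[a + s + 1, b + s + 1] <-
        exp(-oracle_patch_distance(img, X, Y, p) / p$h^2)
    }
  }
  w / sum(w)
}

oracle_nlm_filter <- function(plane, guide, p) {
  s <- p$search_radius
  out <- matrix(0, nrow(plane), ncol(plane))
  for (i in 1:nrow(plane)) for (j in 1:ncol(plane)) {
    w <- oracle_nlm_weights(guide, c(i, j), p)
    acc <- 0
    for (a in -s:s) for (b in -s:s) {
      if (i + a >= 1 && i + a <= nrow(plane) &&
          j + b >= 1 && j + b <= ncol(plane)) {
        acc <- acc + w[a + s + 1, b + s + 1] * plane[i + a, j + b]
      }
    }
    out[i, j] <- acc
  }
  out
}

# Per-pixel symmetric 2x2 eigen-decomposition through base R's solver.
oracle_eigen <- function(tf) {
  H <- nrow(tf$j11); W <- ncol(tf$j11)
  mu1 <- matrix(0, H, W); mu2 <- matrix(0, H, W)
  v1 <- array(0, c(H, W, 2))
  for (i in 1:H) for (j in 1:W) {
    e <- eigen(matrix(c(tf$j11[i, j], tf$j12[i, j],
                        tf$j12[i, j], tf$j22[i, j]), 2, 2),
               symmetric = TRUE)
    mu1[i, j] <- e$values[1]
    mu2[i, j] <- e$values[2]
    v1[i, j, ] <- e$vectors[, 1]
  }
  list(mu1 = mu1, mu2 = mu2, v1 = v1)
}

oracle_fuse_wa <- function(wA, wB) {
  H <- nrow(wA); W <- ncol(wA)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    sA <- 0; sB <- 0
    for (a in -1:1) for (b in -1:1) {
      sA <- sA + o_at(wA, i + a, j + b)^2 / 9
      sB <- sB + o_at(wB, i + a, j + b)^2 / 9
    }
    om <- if (sA + sB > 0) sA / (sA + sB) else 0.5
    out[i, j] <- om * wA[i, j] + (1 - om) * wB[i, j]
  }
  out
}

oracle_fuse_cgm <- function(wA, wB) {
  H <- nrow(wA); W <- ncol(wA)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    gA <- sqrt(((o_at(wA, i, j + 1) - o_at(wA, i, j - 1)) / 2)^2 +
               ((o_at(wA, i + 1, j) - o_at(wA, i - 1, j)) / 2)^2)
    gB <- sqrt(((o_at(wB, i, j + 1) - o_at(wB, i, j - 1)) / 2)^2 +
               ((o_at(wB, i + 1, j) - o_at(wB, i - 1, j)) / 2)^2)
    out[i, j] <- if (gA >= gB) wA[i, j] else wB[i, j]
  }
  out
}

random_image <- function(H, W = H) matrix(runif(H * W), H, W)
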