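grad_field <- function(gx, gy) {
  structure(list(gx = gx, gy = gy), class = "gradient_field")
}

test_that("initial structure tensor is the gradient outer product", {
  t1 <- initial_structure_tensor(grad_field(matrix(3, 1, 1), matrix(4, 1, 1)))
  expect_equal(t1$j11[1, 1], 9)
  expect_equal(t1$j12[1, 1], 12)
  expect_equal(t1$j22[1, 1], 16)

  t0 <- initial_structure_tensor(grad_field(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_true(all(t0$j11 == 0 & t0$j12 == 0 & t0$j22 == 0))
})

test_that("initial tensor has rank one: eigenvalues |grad|^2 and 0", {
  set.seed(21)
  for (rep in 1:5) {
    img <- random_image(10)
    g <- compute_gradient(img)
    tf <- initial_structure_tensor(g)
    expect_true(max(abs(tf$j11 * tf$j22 - tf$j12^2)) < 1e-10)
    e <- eigen_decompose(tf)
    expect_true(max(abs(e$mu2)) < 1e-10)
    expect_equal(e$mu1, g$gx^2 + g$gy^2, tolerance = 1e-10)
  }
})

test_that("Gaussian tensor smoothing preserves constants, mass and PSD", {
  const <- structure(list(j11 = matrix(2, 8, 8), j12 = matrix(0.5, 8, 8),
                          j22 = matrix(1, 8, 8)), class = "tensor_field")
  sm <- gaussian_structure_tensor(const, rho = 1.2)
  expect_equal(sm$j11, const$j11, tolerance = 1e-12)
  expect_equal(sm$j12, const$j12, tolerance = 1e-12)

  # impulse spreads into the sampled, normalized kernel
  imp <- structure(list(j11 = make_test_pattern("impulse", c(15, 15)),
                        j12 = matrix(0, 15, 15), j22 = matrix(0, 15, 15)),
                   class = "tensor_field")
  rho <- 0.8
  sm <- gaussian_structure_tensor(imp, rho)
  k1 <- exp(-(-3:3)^2 / (2 * rho^2)); k1 <- k1 / sum(k1)
  expect_equal(sm$j11[5:11, 5:11], outer(k1, k1), tolerance = 1e-12)

  # near-identity limit
  sm0 <- gaussian_structure_tensor(imp, rho = 0.05)
  expect_equal(sm0$j11, imp$j11, tolerance = 1e-8)

  set.seed(22)
  tf <- initial_structure_tensor(compute_gradient(random_image(12)))
  sm <- gaussian_structure_tensor(tf, rho = 1.5)
  expect_true(all(sm$j11 >= -1e-12) && all(sm$j22 >= -1e-12))
  expect_true(min(sm$j11 * sm$j22 - sm$j12^2) > -1e-10)

  expect_error(gaussian_structure_tensor(tf, rho = 0), "positive")
})

test_that("patch distance is a Gaussian-weighted squared patch difference", {
  p <- nlm_params(search_radius = 3, patch_radius = 2, h = 0.2)
  img <- matrix(0, 15, 15)
  img[4, 4] <- 0.3
  img[11, 11] <- 0.3 + 0.25  # same patch up to a center offset of delta
  expect_equal(patch_distance(img, c(4, 4), c(4, 4), p), 0)
  d <- patch_distance(img, c(4, 4), c(11, 11), p)
  expect_equal(d, patch_distance(img, c(11, 11), c(4, 4), p))
  g1 <- exp(-(-2:2)^2 / (2 * p$rho^2)); g1 <- g1 / sum(g1)
  expect_equal(d, g1[3]^2 * 0.25^2, tolerance = 1e-12)

  set.seed(23)
  img <- random_image(9)
  for (rep in 1:10) {
    X <- sample(9, 2, replace = TRUE); Y <- sample(9, 2, replace = TRUE)
    expect_equal(patch_distance(img, X, Y, p),
                 oracle_patch_distance(img, X, Y, p), tolerance = 1e-12)
  }
})

test_that("NLM weights are uniform on constant images and always sum to 1", {
  p <- nlm_params(search_radius = 2, patch_radius = 1, h = 0.1)
  w <- nlm_weights(matrix(0.7, 9, 9), c(5, 5), p)
  expect_equal(w, matrix(1 / 25, 5, 5))

  # clipped at a corner: uniform over the surviving window positions
  wc <- nlm_weights(matrix(0.7, 9, 9), c(1, 1), p)
  expect_equal(sum(wc), 1)
  expect_equal(max(wc), 1 / 9)

  set.seed(24)
  for (rep in 1:5) {
    img <- random_image(11)
    X <- c(sample(11, 1), sample(11, 1))
    w <- nlm_weights(img, X, nlm_params(5, 2, h = 0.1))
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("NLM weight map matches the triple-loop oracle", {
  set.seed(25)
  p <- nlm_params(search_radius = 5, patch_radius = 2, h = 0.1)
  img <- random_image(11)
  for (X in list(c(6, 6), c(1, 1), c(2, 10), c(11, 5))) {
    expect_equal(nlm_weights(img, X, p), oracle_nlm_weights(img, X, p),
                 tolerance = 1e-12)
  }
})

test_that("NLM filtering is a convex combination and matches its oracle", {
  p <- nlm_params(search_radius = 3, patch_radius = 1, h = 0.15)
  const <- matrix(0.42, 9, 9)
  expect_equal(nlm_filter_plane(const, const, p), const, tolerance = 1e-12)

  set.seed(26)
  plane <- random_image(9); guide <- random_image(9)
  out <- nlm_filter_plane(plane, guide, p)
  expect_true(all(out >= min(plane) - 1e-12 & out <= max(plane) + 1e-12))
  expect_equal(out, oracle_nlm_filter(plane, guide, p), tolerance = 1e-10)

  # h -> Inf: every surviving weight is equal, so the filter is the box mean
  phuge <- nlm_params(search_radius = 3, patch_radius = 1, h = 1e8)
  expect_equal(nlm_filter_plane(plane, guide, phuge),
               oracle_nlm_filter(plane, guide, phuge), tolerance = 1e-10)
  box <- nlm_filter_plane(plane, guide, phuge)
  expect_equal(box[5, 5], mean(plane[2:8, 2:8]), tolerance = 1e-8)

  expect_error(nlm_filter_plane(plane, random_image(8), p), "dimensions")
})

test_that("patch structure tensor composes J0 with guided NLM filtering", {
  p <- nlm_params(search_radius = 2, patch_radius = 1, h = 0.12)
  img <- make_test_pattern("constant", c(8, 8))
  tf <- patch_structure_tensor(img, p)
  expect_true(all(tf$j11 == 0 & tf$j12 == 0 & tf$j22 == 0))

  set.seed(27)
  img <- random_image(9)
  tf <- patch_structure_tensor(img, p)
  go <- oracle_gradient(img)
  j0 <- list(j11 = go$gx^2, j12 = go$gx * go$gy, j22 = go$gy^2)
  expect_equal(tf$j11, oracle_nlm_filter(j0$j11, img, p), tolerance = 1e-10)
  expect_equal(tf$j12, oracle_nlm_filter(j0$j12, img, p), tolerance = 1e-10)
  expect_equal(tf$j22, oracle_nlm_filter(j0$j22, img, p), tolerance = 1e-10)
  expect_true(min(tf$j11 * tf$j22 - tf$j12^2) > -1e-10)
})

test_that("at a vertical step edge the dominant eigenvector is horizontal", {
  img <- make_test_pattern("step", c(16, 16))
  e <- eigen_decompose(patch_structure_tensor(img, nlm_params(3, 1, h = 0.1)))
  edge_cols <- c(8, 9)  # step sits between columns 8 and 9
  expect_true(all(abs(e$v1x[5:12, edge_cols]) > 0.99))
  expect_true(all(abs(e$v1y[5:12, edge_cols]) < 0.1))
})

test_that("closed-form eigen-decomposition matches base R's solver", {
  tf <- structure(list(j11 = matrix(9, 1, 1), j12 = matrix(12, 1, 1),
                       j22 = matrix(16, 1, 1)), class = "tensor_field")
  e <- eigen_decompose(tf)
  expect_equal(e$mu1[1, 1], 25)
  expect_equal(e$mu2[1, 1], 0)
  expect_equal(abs(c(e$v1x[1, 1], e$v1y[1, 1])), c(0.6, 0.8))

  dg <- structure(list(j11 = matrix(5, 1, 1), j12 = matrix(0, 1, 1),
                       j22 = matrix(2, 1, 1)), class = "tensor_field")
  ed <- eigen_decompose(dg)
  expect_equal(c(ed$mu1[1, 1], ed$mu2[1, 1]), c(5, 2))
  expect_equal(c(ed$v1x[1, 1], ed$v1y[1, 1]), c(1, 0))

  set.seed(28)
  for (rep in 1:5) {
    tf <- structure(list(j11 = random_image(6), j12 = random_image(6) - 0.5,
                         j22 = random_image(6)), class = "tensor_field")
    e <- eigen_decompose(tf)
    o <- oracle_eigen(tf)
    expect_equal(e$mu1, o$mu1, tolerance = 1e-10)
    expect_equal(e$mu2, o$mu2, tolerance = 1e-10)
    # eigenvectors agree up to sign
    dots <- abs(e$v1x * o$v1[, , 1] + e$v1y * o$v1[, , 2])
    expect_true(max(abs(dots - 1)) < 1e-8)
    # trace and determinant conservation, orthonormality
    expect_equal(e$mu1 + e$mu2, tf$j11 + tf$j22, tolerance = 1e-10)
    expect_equal(e$mu1 * e$mu2, tf$j11 * tf$j22 - tf$j12^2, tolerance = 1e-10)
    expect_true(max(abs(e$v1x * e$v2x + e$v1y * e$v2y)) < 1e-12)
    expect_true(max(abs(e$v1x^2 + e$v1y^2 - 1)) < 1e-12)
  }
})

test_that("isotropic pixels get the deterministic eigenvector pair", {
  tf <- structure(list(j11 = matrix(0.3, 2, 2), j12 = matrix(0, 2, 2),
                       j22 = matrix(0.3, 2, 2)), class = "tensor_field")
  e <- eigen_decompose(tf)
  expect_true(all(e$v1x == 1 & e$v1y == 0 & e$v2x == 0 & e$v2y == 1))
})

test_that("coherence is the squared eigenvalue gap", {
  tf <- structure(list(j11 = matrix(c(3, 1, 2), 1, 3),
                       j12 = matrix(0, 1, 3),
                       j22 = matrix(c(1, 1, 2), 1, 3)), class = "tensor_field")
  phi <- coherence(eigen_decompose(tf))
  expect_equal(phi[1, ], c(4, 0, 0))
  expect_true(all(phi >= 0))
})

test_that("transposing the image transposes and swaps the tensor planes", {
  set.seed(29)
  img <- random_image(10, 12)
  p <- nlm_params(search_radius = 2, patch_radius = 1, h = 0.1)
  tf <- patch_structure_tensor(img, p)
  tt <- patch_structure_tensor(t(img), p)
  expect_equal(tt$j11, t(tf$j22), tolerance = 1e-12)
  expect_equal(tt$j22, t(tf$j11), tolerance = 1e-12)
  expect_equal(tt$j12, t(tf$j12), tolerance = 1e-12)
  phi <- coherence(eigen_decompose(tf))
  phit <- coherence(eigen_decompose(tt))
  expect_equal(phit, t(phi), tolerance = 1e-12)
})
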