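test_that("shape PCA matches a direct eigendecomposition oracle", {
  d <- toy_species_dataset(n_species = 5, n_images = 2, asym_sd = 0.02,
                           seed = 101)
  s <- decompose_symmetry(d)
  m <- shape_pca(s, orient = FALSE)
  # oracle: assemble the residual matrix explicitly, use prcomp
  flat <- t(apply(s$symmetric, 3L, as.vector))
  resid <- sweep(flat, 2L, as.vector(s$consensus))
  pr <- prcomp(resid, center = TRUE, scale. = FALSE)
  expect_equal(m$eigenvalues[seq_along(pr$sdev)], pr$sdev^2,
               tolerance = 1e-9)
  for (j in 1:3) {
    expect_equal(abs(sum(m$eigenvectors[, j] * pr$rotation[, j])), 1,
                 tolerance = 1e-9)
  }
  # scores centered on the column means agree up to sign
  sc <- sweep(m$scores, 2L, colMeans(m$scores))
  for (j in 1:3) {
    expect_equal(abs(sc[, j]), abs(pr$x[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("single-direction variation loads entirely on PC1", {
  d <- toy_species_dataset(seed = 103)
  s <- decompose_symmetry(d)
  k <- dim(s$symmetric)[1]
  # overwrite the symmetric components with exactly 1-D variation
  u <- as.vector(random_shape(seed = 104))
  u <- u - as.vector(s$consensus) * sum(u * as.vector(s$consensus))
  u <- u / sqrt(sum(u^2))
  t_vals <- seq(-0.2, 0.2, length.out = dim(s$symmetric)[3])
  for (i in seq_along(t_vals)) {
    s$symmetric[, , i] <- s$consensus + matrix(t_vals[i] * u, k, 2L)
  }
  m <- shape_pca(s, orient = FALSE)
  expect_equal(m$variance_fraction[1L], 1, tolerance = 1e-12)
  expect_lt(max(m$eigenvalues[-1L]), 1e-15)
})

test_that("eigenvectors are orthonormal and score covariance is diagonal", {
  d <- toy_species_dataset(n_species = 4, n_images = 6, seed = 107)
  m <- shape_pca(decompose_symmetry(d))
  v <- m$eigenvectors
  expect_equal(crossprod(v), diag(ncol(v)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(m$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(m$eigenvalues) <= 1e-15))
  sc <- sweep(m$scores, 2L, colMeans(m$scores))
  cv <- crossprod(sc) / (nrow(sc) - 1)
  expect_equal(cv, diag(m$eigenvalues), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("project and reconstruct are mutually inverse", {
  d <- toy_species_dataset(n_species = 4, n_images = 5, seed = 109)
  s <- decompose_symmetry(d)
  m <- shape_pca(s)
  expect_equal(project(m$consensus, m),
               rep(0, ncol(m$eigenvectors)), tolerance = 1e-12)
  expect_equal(reconstruct(numeric(0), m), m$consensus,
               ignore_attr = TRUE)
  v <- c(0.1, -0.05, 0.02)
  expect_equal(project(reconstruct(v, m), m)[1:3], v, tolerance = 1e-12)
  # full-basis reconstruction of a held-out specimen is lossless
  i <- dim(s$symmetric)[3]
  sc_i <- project(s$symmetric[, , i], m)
  expect_equal(reconstruct(sc_i, m), s$symmetric[, , i],
               tolerance = 1e-9, ignore_attr = TRUE)
  # truncation error decreases monotonically with added components
  errs <- vapply(seq_along(sc_i), function(p) {
    sqrt(sum((reconstruct(sc_i[seq_len(p)], m) - s$symmetric[, , i])^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_error(project(matrix(0, 4L, 2L), m), "wrong landmark count")
})

test_that("reconstruction is linear in the scores", {
  d <- toy_species_dataset(seed = 113)
  m <- shape_pca(decompose_symmetry(d))
  a <- c(0.1, 0.02); b <- c(-0.03, 0.08)
  expect_equal(reconstruct(a, m) + reconstruct(b, m) - m$consensus,
               reconstruct(a + b, m), tolerance = 1e-12,
               ignore_attr = TRUE)
  path <- morph_path(m, a, b, n_steps = 5L)
  expect_length(path, 5L)
  expect_equal(path[[1L]], reconstruct(a, m))
  expect_equal(path[[5L]], reconstruct(b, m))
  expect_equal(path[[3L]], reconstruct((a + b) / 2, m), tolerance = 1e-12)
  expect_equal(morph_path(m, a, b, n_steps = 2L),
               list(reconstruct(a, m), reconstruct(b, m)))
})

test_that("axis orientation fixes the documented sign conventions", {
  d <- toy_species_dataset(n_species = 5, n_images = 5, between_sd = 8,
                           seed = 127)
  s <- decompose_symmetry(d)
  m <- shape_pca(s)   # oriented automatically
  up <- inter_petal_angles(reconstruct(c(0.2, 0), m))$dorsal_separation
  dn <- inter_petal_angles(reconstruct(c(-0.2, 0), m))$dorsal_separation
  expect_gt(up, dn)
  lat_up <- inter_petal_angles(reconstruct(c(0, 0.2), m))$lateral_separation
  lat_dn <- inter_petal_angles(reconstruct(c(0, -0.2), m))$lateral_separation
  expect_lt(lat_up, lat_dn)
  # flipping an eigenvector together with its scores is a pure gauge change
  m2 <- m
  m2$eigenvectors[, 1L] <- -m2$eigenvectors[, 1L]
  m2$scores[, 1L] <- -m2$scores[, 1L]
  i <- 3L
  expect_equal(reconstruct(m2$scores[i, ], m2),
               reconstruct(m$scores[i, ], m), tolerance = 1e-12)
})

test_that("inter-petal angles: pentagon, conservation, error cases", {
  pent <- config_from_angles(36, 108)
  ang <- inter_petal_angles(pent)
  expect_equal(unname(ang$adjacent), rep(72, 5L), tolerance = 1e-9)
  expect_equal(ang$dorsal_separation, 72, tolerance = 1e-9)
  set.seed(131)
  for (i in 1:5) {
    cfg <- config_from_angles(runif(1, 25, 85), runif(1, 95, 155)) +
      matrix(rnorm(10, 0, 0.02), 5L, 2L)
    expect_equal(sum(inter_petal_angles(cfg)$adjacent), 360,
                 tolerance = 1e-9)
  }
  fan <- config_from_angles(archetype("fan")$dorsal_angle,
                            archetype("fan")$lateral_angle)
  expect_gte(inter_petal_angles(fan)$dorsal_separation, 120)
  # a landmark equal to the mean of the others sits exactly at the centroid
  degenerate <- pent
  degenerate[3L, ] <- colMeans(pent[-3L, ])
  expect_error(inter_petal_angles(degenerate), "centroid")
})
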