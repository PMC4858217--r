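test_that("archetype geometry satisfies the documented angle criteria", {
  pr <- archetype("pseudo_radial")
  ang <- inter_petal_angles(config_from_angles(pr$dorsal_angle,
                                               pr$lateral_angle))
  expect_equal(unname(ang$adjacent), rep(72, 5L), tolerance = 1e-9)
  fan <- archetype("fan")
  # fan petal directions are 170 degrees apart at the flower center; the
  # angle at the landmark centroid (the measurement convention) is smaller
  # but still satisfies the fan criterion
  expect_equal(fan$dorsal_angle * 2, 170)
  ang_f <- inter_petal_angles(config_from_angles(fan$dorsal_angle,
                                                 fan$lateral_angle))
  expect_gte(ang_f$dorsal_separation, 120)
  bil <- archetype("bilabiate")
  ang_b <- inter_petal_angles(config_from_angles(bil$dorsal_angle,
                                                 bil$lateral_angle))
  # wide dorsal-to-lateral gap relative to the regular pentagon
  expect_gt(unname(ang_b$adjacent["D_left-L_left"]), 100)
  expect_error(archetype("spiral"), "unknown archetype")
})

test_that("identical seeds give bit-identical datasets", {
  cfg <- simulation_config(n_species = c(fan = 3L, bilabiate = 3L),
                           images_per_species = 4, seed = 99L)
  s1 <- simulate_flowers(cfg)
  s2 <- simulate_flowers(cfg)
  expect_identical(s1$dataset$coords, s2$dataset$coords)
  expect_identical(s1$truth$images, s2$truth$images)
  s3 <- simulate_flowers(simulation_config(
    n_species = c(fan = 3L, bilabiate = 3L), images_per_species = 4,
    seed = 100L))
  expect_false(identical(s1$dataset$coords, s3$dataset$coords))
})

test_that("noise-free generation yields exact archetypes and zero asymmetry", {
  cfg <- simulation_config(n_species = c(bilabiate = 2L),
                           images_per_species = 3, images_sd = 0,
                           between_species_sd = c(0, 0),
                           within_species_sd = c(0, 0),
                           asymmetric_noise_sd = 0,
                           rotation_range = c(0, 0),
                           translation_range = c(0, 0),
                           scale_range = c(1, 1), seed = 5L)
  sim <- simulate_flowers(cfg)
  base <- config_from_angles(30, 150)
  for (i in seq_len(n_specimens(sim$dataset))) {
    expect_equal(sim$dataset$coords[, , i], base, tolerance = 1e-12,
                 ignore_attr = TRUE)
    # exact mirror symmetry (fixed point of reflect_relabel)
    expect_equal(reflect_relabel(sim$dataset$coords[, , i]),
                 sim$dataset$coords[, , i], tolerance = 0)
  }
  s <- decompose_symmetry(sim$dataset)
  expect_lt(max(abs(s$asymmetric)), 1e-9)
})

test_that("pure nuisance variation is removed by superimposition", {
  cfg <- simulation_config(n_species = c(pseudo_radial = 3L),
                           images_per_species = 5, images_sd = 0,
                           between_species_sd = c(0, 0),
                           within_species_sd = c(0, 0),
                           asymmetric_noise_sd = 0, seed = 8L)
  sim <- simulate_flowers(cfg)
  g <- gpa(sim$dataset)
  expect_lt(procrustes_variance(g), 1e-12)
})

test_that("within-species spread increases within-species Procrustes variance", {
  for (seed in 1:3) {
    v <- vapply(c(1, 4, 8), function(sdw) {
      sim <- simulate_flowers(simulation_config(
        n_species = c(pseudo_radial = 1L), images_per_species = 10,
        images_sd = 0, between_species_sd = c(0, 0),
        within_species_sd = c(sdw, sdw), asymmetric_noise_sd = 0,
        seed = seed))
      procrustes_variance(gpa(sim$dataset))
    }, numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("truth metrics report perfect and chance-level recovery", {
  sim <- simulate_flowers(simulation_config(
    n_species = c(fan = 4L, bilabiate = 4L, pseudo_radial = 4L),
    images_per_species = 5, images_sd = 0,
    between_species_sd = c(1, 1), within_species_sd = c(0.5, 0.5),
    asymmetric_noise_sd = 0.005, seed = 12L))
  s <- decompose_symmetry(sim$dataset)
  m <- shape_pca(s)
  cl <- cluster_morphotypes(m)
  tm <- truth_metrics(m, cl, s, sim$truth)
  expect_equal(tm$ari, 1)
  # shuffled assignments drop to chance-level agreement
  set.seed(13)
  cl_sh <- cl
  cl_sh$assignments <- sample(cl$assignments)
  tm_sh <- truth_metrics(m, cl_sh, s, sim$truth)
  expect_lt(abs(tm_sh$ari), 0.1)
  # id mismatch is an error
  truth_bad <- sim$truth
  truth_bad$images$specimen_id[1L] <- "someone_else"
  expect_error(truth_metrics(m, cl, s, truth_bad), "ids do not match")
})

test_that("estimated asymmetric noise tracks the injected level", {
  sim <- simulate_flowers(simulation_config(
    n_species = c(pseudo_radial = 8L), images_per_species = 8,
    images_sd = 0, asymmetric_noise_sd = 0.02, seed = 21L))
  s <- decompose_symmetry(sim$dataset)
  m <- shape_pca(s)
  cl <- cluster_morphotypes(m)
  tm <- truth_metrics(m, cl, s, sim$truth)
  expect_equal(tm$asym_sd_ratio, 1, tolerance = 0.15)
})
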