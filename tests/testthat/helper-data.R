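# Fixture builders shared across test files. Everything is generated in
# code; no data files are read except the packaged species summary table.

# a small random (non-symmetric) configuration, centered and unit-size
random_shape <- function(k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(2L * k), k, 2L)
  x <- sweep(x, 2L, colMeans(x))
  x / sqrt(sum(x^2))
}

# apply a random similarity transform (proper rotation, scale, translation)
nuisance_transform <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- stats::runif(1L, -pi, pi)
  sc <- stats::runif(1L, 0.5, 2)
  tr <- stats::runif(2L, -3, 3)
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep((x %*% t(r)) * sc, 2L, tr, `+`)
}

# dataset of n noisy copies of one base flower (asymmetric noise only)
copies_dataset <- function(n = 6L, asym_sd = 0, seed = 1L,
                           dorsal = 36, lateral = 108) {
  set.seed(seed)
  base <- config_from_angles(dorsal, lateral)
  configs <- lapply(seq_len(n), function(i) {
    x <- base + matrix(stats::rnorm(10L, 0, asym_sd), 5L, 2L)
    nuisance_transform(x)
  })
  landmark_dataset(configs, species_id = rep("sp1", n))
}

# small multi-species symmetric dataset with controllable noise
toy_species_dataset <- function(n_species = 3L, n_images = 4L,
                                between_sd = 6, within_sd = 2,
                                asym_sd = 0.01, seed = 1L) {
  sim <- simulate_flowers(simulation_config(
    n_species = c(pseudo_radial = n_species),
    images_per_species = n_images, images_sd = 0,
    between_species_sd = c(between_sd, between_sd),
    within_species_sd = c(within_sd, within_sd),
    asymmetric_noise_sd = asym_sd, seed = seed))
  sim$dataset
}

tps_text_minimal <- c(
  "LM=5",
  "0.1 1.0", "-0.9 0.3", "0.0 -1.0", "0.9 0.3", "-0.1 1.0",
  "ID=flower1")
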