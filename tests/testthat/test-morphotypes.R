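make_cluster_obj <- function(centers, assignments) {
  structure(list(k = nrow(centers), centers = centers,
                 assignments = assignments, code_names = NULL,
                 within_ss = 0, seed = 42L, restarts = 1L),
            class = "morphotype_clusters")
}

make_pca_obj <- function(scores, species_id) {
  structure(list(scores = scores, species_id = species_id,
                 specimen_id = rownames(scores),
                 consensus = config_from_angles(36, 108),
                 roles = standard_roles(), n_retained = 2L),
            class = "shape_pca")
}

test_that("k-means recovers well-separated blobs and is weight-invariant", {
  set.seed(201)
  blobs <- rbind(matrix(rnorm(60, 0, 0.05), ncol = 2L) +
                   matrix(c(3, 0), 30L, 2L, byrow = TRUE),
                 matrix(rnorm(60, 0, 0.05), ncol = 2L) +
                   matrix(c(-3, 3), 30L, 2L, byrow = TRUE),
                 matrix(rnorm(60, 0, 0.05), ncol = 2L) +
                   matrix(c(-3, -3), 30L, 2L, byrow = TRUE))
  truth <- rep(1:3, each = 30L)
  cl <- cluster_morphotypes(blobs, k = 3L, seed = 1L, restarts = 20L)
  expect_equal(mclust::adjustedRandIndex(cl$assignments, truth), 1)
  # duplicating every point leaves the centers unchanged
  cl2 <- cluster_morphotypes(rbind(blobs, blobs), k = 3L, seed = 1L,
                             restarts = 20L)
  ord <- function(m) m[order(m[, 1L], m[, 2L]), ]
  expect_equal(ord(cl2$centers), ord(cl$centers), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(cluster_morphotypes(blobs[1:2, ], k = 3L), "exceeds")
})

test_that("k-means attains the exhaustive-partition optimum for small n", {
  set.seed(203)
  for (rep in 1:3) {
    pts <- matrix(rnorm(12), 6L, 2L)
    cl <- cluster_morphotypes(pts, k = 2L, seed = rep, restarts = 50L)
    # enumerate all 2^5 - 1 = 31 nonempty bipartitions
    best <- Inf
    for (mask in 1:31) {
      grp <- as.logical(bitwAnd(mask, 2^(0:5)) > 0)
      wss <- sum(sweep(pts[grp, , drop = FALSE], 2L,
                       colMeans(pts[grp, , drop = FALSE]))^2) +
        sum(sweep(pts[!grp, , drop = FALSE], 2L,
                  colMeans(pts[!grp, , drop = FALSE]))^2)
      best <- min(best, wss)
    }
    expect_equal(cl$within_ss, best, tolerance = 1e-9)
  }
})

test_that("clusters are named by geometry, independent of input order", {
  centers <- rbind(c(0.3, 0), c(-0.2, 0.15), c(-0.2, -0.1))
  colnames(centers) <- c("PC1", "PC2")
  cl <- name_clusters(make_cluster_obj(centers, c(1L, 2L, 3L)))
  expect_equal(rownames(cl$centers), c("fan", "pseudo_radial", "bilabiate"))
  expect_equal(unname(cl$centers["fan", ]), c(0.3, 0))
  expect_equal(unname(cl$centers["bilabiate", ]), c(-0.2, 0.15))
  # the original assignment 1 (center (0.3,0)) must now carry code 1 = fan
  expect_equal(unname(cl$assignments), c(1L, 3L, 2L))
  # permuting cluster order keeps names attached to the same centers
  perm <- c(3L, 1L, 2L)
  cl_p <- name_clusters(make_cluster_obj(centers[perm, ],
                                         match(c(1L, 2L, 3L), perm)))
  expect_equal(cl_p$centers, cl$centers)
  expect_equal(unname(cl_p$assignments), unname(cl$assignments))
  tied <- rbind(c(0.3, 0), c(0.3, 0.2), c(-0.2, -0.1))
  colnames(tied) <- c("PC1", "PC2")
  expect_error(name_clusters(make_cluster_obj(tied, c(1L, 2L, 3L))),
               "tie")
})

test_that("species summaries reproduce the documented arithmetic", {
  # one single-image species and one 13-image species split 12/1
  scores <- cbind(PC1 = c(0.136, rep(-0.16, 13L)),
                  PC2 = c(0.066, rep(-0.07, 13L)))
  rownames(scores) <- sprintf("im%02d", 1:14)
  species_id <- c("solo", rep("split", 13L))
  m <- make_pca_obj(scores, species_id)
  cl <- make_cluster_obj(rbind(c(0.3, 0), c(-0.2, -0.1), c(-0.2, 0.15)),
                         c(1L, rep(2L, 12L), 3L))
  cl$code_names <- c(`1` = "fan", `2` = "pseudo_radial", `3` = "bilabiate")
  ss <- species_summaries(m, cl)
  solo <- ss[ss$species_id == "solo", ]
  expect_equal(solo$pc1_mean, 0.136)
  expect_equal(solo$pc2_mean, 0.066)
  expect_equal(solo$cluster_mean, 1)
  expect_equal(solo$majority, "fan")
  split <- ss[ss$species_id == "split", ]
  expect_equal(split$cluster_mean, (12 * 2 + 3) / 13, tolerance = 1e-12)
  expect_equal(round(split$cluster_mean, 2), 2.08)
  expect_equal(split$majority, "pseudo_radial")
})

test_that("grouping comparison finds discordance and confusion margins", {
  summaries <- data.frame(
    species_id = c("a", "b", "c", "d"),
    n_images = c(3L, 3L, 3L, 3L),
    pc1_mean = c(0.3, -0.2, -0.25, -0.1),
    pc2_mean = c(0, 0.2, -0.1, -0.05),
    cluster_mean = c(1, 3, 2, 2),
    majority = c("fan", "bilabiate", "pseudo_radial", "pseudo_radial"),
    stringsAsFactors = FALSE)
  species <- data.frame(
    species_id = c("a", "b", "c", "d"),
    clade = "goodenia_sl",
    subjective_label = c("fan", "bilabiate", "pseudo_radial", "bilabiate"),
    stringsAsFactors = FALSE)
  cmp <- compare_groupings(summaries, species)
  expect_equal(cmp$discordant_species, "d")
  expect_equal(sum(cmp$confusion), 4)
  expect_equal(unname(rowSums(cmp$confusion)), c(1, 2, 1))
  # identical labelings: zero discordance, diagonal confusion
  species2 <- species
  species2$subjective_label <- summaries$majority
  cmp2 <- compare_groupings(summaries, species2)
  expect_length(cmp2$discordant_species, 0L)
  expect_equal(sum(diag(cmp2$confusion)), 4)
  # unknown labels are excluded and counted
  species3 <- species
  species3$subjective_label[1L] <- "unknown"
  cmp3 <- compare_groupings(summaries, species3)
  expect_equal(cmp3$n_unknown, 1L)
  expect_equal(sum(cmp3$confusion), 3)
})

test_that("adjusted R-squared: exact partition, null calibration, errors", {
  score <- rep(c(0, 5, 9), each = 10L)
  grouping <- rep(letters[1:3], each = 10L)
  expect_equal(adjusted_r2(score, grouping), 1)
  set.seed(211)
  null_vals <- replicate(100L, {
    adjusted_r2(rnorm(300L), sample(rep(letters[1:3], each = 100L)))
  })
  expect_lt(abs(mean(null_vals)), 0.02)
  expect_error(adjusted_r2(rnorm(10), rep("a", 10L)), "2 groups")
})
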