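#' k-means clustering of morphospace scores
#'
#' Clusters individual flowers by their leading PC scores. This is a thin,
#' seeded wrapper over [stats::kmeans()]: the best of \code{restarts} random
#' starts by total within-cluster sum of squares, deterministic for a given
#' seed. With \code{k = 3} the clusters parallel the three subjective
#' corolla morphologies and can be named by geometry with [name_clusters()].
#'
#' @param scores \code{n x d} score matrix, or a \code{shape_pca} (its first
#'   \code{n_retained} score columns are used).
#' @param k number of clusters (default 3).
#' @param seed RNG seed (default 42).
#' @param restarts number of random starts (default 100).
#' @return Object of class \code{"morphotype_clusters"}: list with \code{k},
#'   \code{centers}, \code{assignments} (integer codes), \code{code_names}
#'   (filled by [name_clusters()]), \code{within_ss}, \code{seed},
#'   \code{restarts}.
#' @export
cluster_morphotypes <- function(scores, k = 3L, seed = 42L, restarts = 100L) {
  specimen_id <- NULL
  if (inherits(scores, "shape_pca")) {
    specimen_id <- scores$specimen_id
    scores <- scores$scores[, seq_len(scores$n_retained), drop = FALSE]
  }
  scores <- as.matrix(scores)
  if (nrow(scores) < k) stop("cluster_morphotypes: k exceeds the number of specimens")
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = restarts, iter.max = 100L)
  assignments <- km$cluster
  if (!is.null(specimen_id)) names(assignments) <- specimen_id
  structure(list(k = as.integer(k), centers = km$centers,
                 assignments = assignments, code_names = NULL,
                 within_ss = km$tot.withinss,
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "morphotype_clusters")
}

#' Name clusters by their morphospace geometry
#'
#' With \code{k = 3} and 2-D centers: the cluster whose center has the
#' largest PC1 is the fan morphotype; of the remaining two, the one with the
#' larger center PC2 is bilabiate and the other pseudo-radial. Numeric codes
#' are then reassigned as 1 = fan, 2 = pseudo_radial, 3 = bilabiate so that
#' species-level mean cluster codes are comparable across runs. Exact ties
#' in the deciding center coordinate raise an error asking for manual
#' naming.
#'
#' @param cl a \code{morphotype_clusters} with \code{k = 3}.
#' @return The model with \code{code_names}, renumbered \code{assignments}
#'   and reordered \code{centers}.
#' @export
name_clusters <- function(cl) {
  stopifnot(inherits(cl, "morphotype_clusters"))
  if (cl$k != 3L || ncol(cl$centers) < 2L) {
    stop("name_clusters: requires k = 3 and at least 2 score dimensions")
  }
  pc1 <- cl$centers[, 1L]; pc2 <- cl$centers[, 2L]
  # ties matter only for the deciding comparisons: the PC1 maximum, and PC2
  # between the two remaining centers
  if (sum(pc1 == max(pc1)) > 1L) {
    stop("name_clusters: exact tie in cluster center coordinates; name manually")
  }
  fan <- which.max(pc1)
  rest <- setdiff(seq_len(3L), fan)
  if (pc2[rest[1L]] == pc2[rest[2L]]) {
    stop("name_clusters: exact tie in cluster center coordinates; name manually")
  }
  bilabiate <- rest[which.max(pc2[rest])]
  pseudo <- setdiff(rest, bilabiate)
  old_order <- c(fan, pseudo, bilabiate)   # new code 1, 2, 3
  remap <- integer(3L)
  remap[old_order] <- 1:3
  cl$assignments[] <- remap[cl$assignments]
  cl$centers <- cl$centers[old_order, , drop = FALSE]
  rownames(cl$centers) <- c("fan", "pseudo_radial", "bilabiate")
  cl$code_names <- c(`1` = "fan", `2` = "pseudo_radial", `3` = "bilabiate")
  cl
}

#' @export
print.morphotype_clusters <- function(x, ...) {
  cat("k-means morphotype clustering: k =", x$k, "\n")
  cat(sprintf("  seed %d, %d restarts, within-SS %.5g\n",
              x$seed, x$restarts, x$within_ss))
  print(round(x$centers, 4))
  if (!is.null(x$code_names)) {
    cat("  codes:", paste(sprintf("%s = %s", names(x$code_names),
                                  x$code_names), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Species-level morphospace summaries
#'
#' Per-species means of the first two PC scores, the mean numeric cluster
#' code across the species' images, and the majority morphotype (modal
#' cluster, ties broken toward the lower code with a warning). Single-image
#' species reproduce their only image's values.
#'
#' @param m a \code{shape_pca}.
#' @param cl a named \code{morphotype_clusters} (after [name_clusters()]).
#' @param species_id per-specimen species labels; defaults to the model's.
#' @return \code{data.frame} with columns \code{species_id},
#'   \code{n_images}, \code{pc1_mean}, \code{pc2_mean}, \code{cluster_mean},
#'   \code{majority}.
#' @export
species_summaries <- function(m, cl, species_id = NULL) {
  stopifnot(inherits(m, "shape_pca"), inherits(cl, "morphotype_clusters"))
  if (is.null(cl$code_names)) stop("species_summaries: run name_clusters() first")
  if (is.null(species_id)) species_id <- m$species_id
  stopifnot(length(species_id) == nrow(m$scores),
            length(cl$assignments) == nrow(m$scores))
  sp <- sort(unique(species_id))
  out <- data.frame(species_id = sp, n_images = NA_integer_,
                    pc1_mean = NA_real_, pc2_mean = NA_real_,
                    cluster_mean = NA_real_, majority = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sp)) {
    idx <- species_id == sp[i]
    codes <- cl$assignments[idx]
    tab <- table(codes)
    modal <- as.integer(names(tab)[tab == max(tab)])
    if (length(modal) > 1L) {
      warning("species ", sp[i], ": tie in modal cluster; using lower code")
      modal <- min(modal)
    }
    out$n_images[i] <- sum(idx)
    out$pc1_mean[i] <- mean(m$scores[idx, 1L])
    out$pc2_mean[i] <- mean(m$scores[idx, 2L])
    out$cluster_mean[i] <- mean(codes)
    out$majority[i] <- unname(cl$code_names[as.character(modal)])
  }
  out
}

#' Compare subjective labels with k-means morphotypes
#'
#' Species-level confusion table of subjective symmetry label against
#' majority k-means morphotype, the list of discordant species, and (when
#' individual scores and assignments are supplied) the adjusted R-squared of
#' each PC axis under each grouping scheme. Species with an unknown
#' subjective label are excluded from the confusion table and counted
#' separately.
#'
#' @param summaries output of [species_summaries()].
#' @param species species metadata with \code{species_id} and
#'   \code{subjective_label} (see [read_species_table()]).
#' @param m optional \code{shape_pca} for the per-axis adjusted R-squared.
#' @param cl optional named \code{morphotype_clusters} (same purpose).
#' @return Object of class \code{"group_comparison"}: list with
#'   \code{confusion} (subjective x majority), \code{discordant_species},
#'   \code{n_unknown} and \code{adjusted_r2} (axis x grouping matrix or
#'   \code{NULL}).
#' @export
compare_groupings <- function(summaries, species, m = NULL, cl = NULL) {
  merged <- merge(summaries, species[, c("species_id", "subjective_label")],
                  by = "species_id", all.x = TRUE)
  merged$subjective_label[is.na(merged$subjective_label)] <- "unknown"
  known <- merged$subjective_label != "unknown"
  lev <- c("fan", "bilabiate", "pseudo_radial")
  confusion <- table(subjective = factor(merged$subjective_label[known], lev),
                     majority = factor(merged$majority[known], lev))
  discordant <- merged$species_id[known &
                                    merged$subjective_label != merged$majority]
  r2 <- NULL
  if (!is.null(m) && !is.null(cl)) {
    subj_by_sp <- stats::setNames(species$subjective_label, species$species_id)
    subj_ind <- unname(subj_by_sp[m$species_id])
    keep <- !is.na(subj_ind) & subj_ind != "unknown"
    r2 <- rbind(
      PC1 = c(subjective = adjusted_r2(m$scores[keep, 1L], subj_ind[keep]),
              kmeans = adjusted_r2(m$scores[, 1L], cl$assignments)),
      PC2 = c(subjective = adjusted_r2(m$scores[keep, 2L], subj_ind[keep]),
              kmeans = adjusted_r2(m$scores[, 2L], cl$assignments)))
  }
  structure(list(confusion = confusion,
                 discordant_species = sort(discordant),
                 n_unknown = sum(!known), adjusted_r2 = r2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Subjective label vs k-means majority morphotype (species level)\n")
  print(x$confusion)
  cat(length(x$discordant_species), "discordant species")
  if (length(x$discordant_species)) {
    cat(":", paste(x$discordant_species, collapse = ", "))
  }
  cat("\n")
  if (x$n_unknown) cat(x$n_unknown, "species with unknown label excluded\n")
  if (!is.null(x$adjusted_r2)) {
    cat("Adjusted R-squared by axis and grouping:\n")
    print(round(x$adjusted_r2, 3))
  }
  invisible(x)
}

#' Adjusted R-squared of a score under a grouping
#'
#' One-way ANOVA coefficient of determination, adjusted for the number of
#' groups: \eqn{1 - (1 - R^2)(N - 1)/(N - g)}.
#'
#' @param score numeric vector.
#' @param grouping labels of the same length, at least 2 distinct groups.
#' @return Scalar adjusted R-squared.
#' @export
adjusted_r2 <- function(score, grouping) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop("adjusted_r2: need at least 2 groups")
  n <- length(score)
  g <- nlevels(grouping)
  ss_tot <- sum((score - mean(score))^2)
  ss_res <- sum(unlist(tapply(score, grouping,
                              function(v) (v - mean(v))^2)))
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - g)
}
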