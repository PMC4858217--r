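#' Bilateral pairing scheme for object symmetry
#'
#' Declares which landmark roles swap under reflection about the midline and
#' which lie on the midline itself. Every role must appear exactly once
#' across the mirror pairs and the midline set.
#'
#' @param mirror_pairs list of length-2 character vectors of paired roles.
#' @param midline_roles character vector of self-paired (midline) roles.
#' @return Object of class \code{"pairing_scheme"}.
#' @export
pairing_scheme <- function(mirror_pairs, midline_roles) {
  all_roles <- c(unlist(mirror_pairs), midline_roles)
  if (anyDuplicated(all_roles)) {
    stop("pairing_scheme: each role may appear only once")
  }
  if (!all(lengths(mirror_pairs) == 2L)) {
    stop("pairing_scheme: mirror_pairs must be pairs")
  }
  structure(list(mirror_pairs = mirror_pairs, midline_roles = midline_roles),
            class = "pairing_scheme")
}

#' Pairing scheme of the five-landmark corolla
#'
#' Dorsal and lateral petal apices are mirror pairs; the ventral petal apex
#' lies on the midline.
#'
#' @return A \code{pairing_scheme}.
#' @export
pentamerous_pairing <- function() {
  pairing_scheme(list(c("D_left", "D_right"), c("L_left", "L_right")),
                 "V")
}

# permutation of landmark rows implied by a pairing, given role order
pairing_permutation <- function(roles, pairing) {
  all_roles <- c(unlist(pairing$mirror_pairs), pairing$midline_roles)
  if (!setequal(roles, all_roles)) {
    stop("pairing scheme roles do not match configuration roles")
  }
  perm <- seq_along(roles)
  for (pr in pairing$mirror_pairs) {
    i <- match(pr[1L], roles); j <- match(pr[2L], roles)
    perm[i] <- j; perm[j] <- i
  }
  perm
}

#' Reflect and relabel a configuration
#'
#' The reflection step of the object-symmetry method: x-coordinates are
#' negated (reflection about the vertical midline) and the members of each
#' mirror pair are swapped so that roles keep their anatomical meaning.
#' Midline roles keep their (x-negated) position. The operation is an exact
#' involution.
#'
#' @param config \code{k x 2} matrix with rows ordered as \code{roles}.
#' @param pairing a \code{pairing_scheme}.
#' @param roles role labels of the rows; defaults to the row names of
#'   \code{config} or [standard_roles()].
#' @return \code{k x 2} matrix, same role order.
#' @export
reflect_relabel <- function(config, pairing = pentamerous_pairing(),
                            roles = NULL) {
  if (is.null(roles)) {
    roles <- rownames(config)
    if (is.null(roles) && nrow(config) == 5L) roles <- standard_roles()
  }
  if (is.null(roles)) stop("reflect_relabel: landmark roles are required")
  perm <- pairing_permutation(roles, pairing)
  out <- config
  out[, 1L] <- -out[, 1L]
  out <- out[perm, , drop = FALSE]
  rownames(out) <- roles
  out
}

#' Decompose flowers into symmetric and asymmetric shape components
#'
#' Object-symmetry decomposition: a joint generalized Procrustes analysis is
#' run over the doubled set of all original configurations together with
#' their reflected-and-relabelled copies. The consensus of the doubled set
#' is exactly symmetrized, each specimen's symmetric component is the mean
#' of its two aligned copies, and the asymmetric component is the deviation
#' of the aligned original from that mean, so that symmetric + asymmetric
#' reconstructs the aligned original exactly and the symmetric component is
#' an exact fixed point of [reflect_relabel()].
#'
#' Component centroid sizes are reported in the specimen's original units:
#' the symmetric centroid size is the ordinary centroid size of the
#' symmetric component scaled back by the specimen's original centroid
#' size, and the asymmetric centroid size is the root summed squared
#' asymmetric displacement, scaled the same way (the displacement field
#' treated as landmarks about the origin).
#'
#' @param d a \code{landmark_dataset}.
#' @param pairing a \code{pairing_scheme}; default [pentamerous_pairing()].
#' @param tol,max_iter,tangent_projection passed to the joint GPA.
#' @return Object of class \code{"symmetry_decomposition"}: list with
#'   \code{symmetric}, \code{asymmetric}, \code{aligned} (originals) and
#'   \code{aligned_reflected} (\code{k x 2 x n} arrays), \code{consensus}
#'   (exactly symmetric), \code{centroid_sizes},
#'   \code{symmetric_centroid_sizes}, \code{asymmetric_centroid_sizes},
#'   ids, roles, pairing and GPA convergence information.
#' @export
decompose_symmetry <- function(d, pairing = pentamerous_pairing(),
                               tol = 1e-8, max_iter = 100L,
                               tangent_projection = TRUE) {
  stopifnot(inherits(d, "landmark_dataset"))
  k <- dim(d$coords)[1]; n <- dim(d$coords)[3]
  perm <- pairing_permutation(d$roles, pairing)
  refl <- function(x) {
    x[, 1L] <- -x[, 1L]
    x[perm, , drop = FALSE]
  }
  doubled <- array(NA_real_, c(k, 2L, 2L * n))
  doubled[, , seq_len(n)] <- d$coords
  for (i in seq_len(n)) doubled[, , n + i] <- refl(d$coords[, , i])
  dimnames(doubled) <- list(d$roles, c("x", "y"),
                            c(d$specimen_id, paste0(d$specimen_id, "_refl")))
  g <- gpa(doubled, tol = tol, max_iter = max_iter,
           tangent_projection = FALSE, standardize_orientation = FALSE)
  # exact symmetrization of the consensus, then one final alignment pass
  consensus <- (g$consensus + refl(g$consensus)) / 2
  consensus <- center_config(consensus)
  consensus <- consensus / sqrt(sum(consensus^2))
  # canonical orientation: for a symmetric consensus the midline vector is
  # already along the y-axis; flip by pi if it points downwards
  if (all(standard_roles() %in% d$roles)) {
    m <- (consensus[match("D_left", d$roles), ] +
            consensus[match("D_right", d$roles), ]) / 2 -
      consensus[match("V", d$roles), ]
    if (m[2L] < 0) consensus <- -consensus
  }
  aligned <- array(NA_real_, c(k, 2L, n),
                   dimnames = list(d$roles, c("x", "y"), d$specimen_id))
  for (i in seq_len(n)) {
    aligned[, , i] <- align_pair(g$aligned[, , i], consensus)$aligned
  }
  if (tangent_projection) {
    cvec <- flatten_config(consensus)
    for (i in seq_len(n)) {
      v <- flatten_config(aligned[, , i])
      aligned[, , i] <- unflatten_config(v + (1 - sum(v * cvec)) * cvec, k)
    }
  }
  # with an exactly symmetric consensus the optimally aligned reflected copy
  # equals the reflection of the aligned original, so enforce that identity
  # exactly (reflection and row swap are exact floating-point operations)
  aligned_reflected <- aligned
  for (i in seq_len(n)) aligned_reflected[, , i] <- refl(aligned[, , i])
  symmetric <- (aligned + aligned_reflected) / 2
  asymmetric <- aligned - symmetric
  cs <- g$centroid_sizes[seq_len(n)]
  sym_cs <- vapply(seq_len(n),
                   function(i) centroid_size(symmetric[, , i]) * cs[i],
                   numeric(1))
  asym_cs <- vapply(seq_len(n),
                    function(i) sqrt(sum(asymmetric[, , i]^2)) * cs[i],
                    numeric(1))
  structure(list(symmetric = symmetric, asymmetric = asymmetric,
                 aligned = aligned, aligned_reflected = aligned_reflected,
                 consensus = consensus, centroid_sizes = cs,
                 symmetric_centroid_sizes = sym_cs,
                 asymmetric_centroid_sizes = asym_cs,
                 iterations = g$iterations, converged = g$converged,
                 tangent_projected = tangent_projection,
                 roles = d$roles, specimen_id = d$specimen_id,
                 species_id = d$species_id, species = d$species,
                 pairing = pairing),
            class = "symmetry_decomposition")
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  cat("Object-symmetry decomposition:", dim(x$symmetric)[3], "specimens,",
      dim(x$symmetric)[1], "landmarks\n")
  s <- asymmetry_summary(x)
  cat(sprintf("  symmetric centroid size  %.4g (SD %.3g)\n",
              s$symmetric_mean, s$symmetric_sd))
  cat(sprintf("  asymmetric centroid size %.4g (SD %.3g) = %.2f%% of symmetric\n",
              s$asymmetric_mean, s$asymmetric_sd, s$ratio_pct))
  invisible(x)
}

#' Summary of symmetric and asymmetric component sizes
#'
#' Mean and standard deviation of the symmetric and asymmetric component
#' centroid sizes, plus their ratio (mean asymmetric / mean symmetric) as a
#' percentage — the scale-free measure of how much of a flower's form is
#' asymmetric.
#'
#' @param s a \code{symmetry_decomposition}.
#' @return List with \code{symmetric_mean}, \code{symmetric_sd},
#'   \code{asymmetric_mean}, \code{asymmetric_sd} and \code{ratio_pct}.
#' @export
asymmetry_summary <- function(s) {
  stopifnot(inherits(s, "symmetry_decomposition"))
  sm <- mean(s$symmetric_centroid_sizes)
  am <- mean(s$asymmetric_centroid_sizes)
  list(symmetric_mean = sm,
       symmetric_sd = stats::sd(s$symmetric_centroid_sizes),
       asymmetric_mean = am,
       asymmetric_sd = stats::sd(s$asymmetric_centroid_sizes),
       ratio_pct = 100 * am / sm)
}

component_rank <- function(mat, tol = 1e-8) {
  ev <- eigen(stats::cov(mat), symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(ev, 0))
}

#' Procrustes ANOVA over species and side
#'
#' Goodall-style decomposition of the summed squared Procrustes deviations
#' of the doubled aligned set (originals plus reflected copies) into a
#' species effect (variation among species mean symmetric shapes), a side
#' effect (the reflection main effect, i.e. directional asymmetry) and a
#' residual (within-species symmetric variation plus fluctuating
#' asymmetry). Degrees of freedom multiply the effect's level count minus
#' one by the dimension of the relevant shape subspace, obtained numerically
#' as the rank of the corresponding component covariance matrix. F ratios
#' are Goodall-type, each effect tested against the residual mean square;
#' an optional permutation test (species labels permuted over specimens)
#' gives a self-contained nonparametric p for the species effect.
#'
#' @param s a \code{symmetry_decomposition}.
#' @param grouping specimen-to-group labels; defaults to the dataset's
#'   species ids.
#' @param permutations number of permutations for the species-effect
#'   permutation p (0 = parametric only).
#' @param seed RNG seed used when permuting.
#' @return Object of class \code{"procrustes_anova"}: a \code{data.frame}
#'   with columns effect, SS, df, MS, F, p and pct_variance, plus attributes
#'   \code{perm_p} when permutations were requested.
#' @export
procrustes_anova <- function(s, grouping = NULL, permutations = 0L,
                             seed = 1L) {
  stopifnot(inherits(s, "symmetry_decomposition"))
  if (is.null(grouping)) grouping <- s$species_id
  grouping <- as.character(grouping)
  n <- dim(s$aligned)[3]
  stopifnot(length(grouping) == n)
  groups <- unique(grouping)
  if (length(groups) < 2L) {
    stop("procrustes_anova: need at least 2 species/groups")
  }
  k <- dim(s$aligned)[1]
  flat <- function(a) t(apply(a, 3L, flatten_config))
  orig <- flat(s$aligned)          # n x 2k
  refl <- flat(s$aligned_reflected)
  sym <- (orig + refl) / 2
  all2n <- rbind(orig, refl)
  g <- colMeans(all2n)
  ss_total <- sum(sweep(all2n, 2L, g)^2)
  # species effect: among-group variation of the symmetric components
  ss_species <- 0
  for (sp in groups) {
    idx <- grouping == sp
    m_s <- colMeans(sym[idx, , drop = FALSE])
    ss_species <- ss_species + 2 * sum(idx) * sum((m_s - g)^2)
  }
  # side effect: originals vs reflected copies (directional asymmetry)
  o <- colMeans(orig); r <- colMeans(refl)
  ss_side <- n * sum((o - g)^2) + n * sum((r - g)^2)
  ss_res <- ss_total - ss_species - ss_side
  d_sym <- component_rank(sym)
  d_asym <- component_rank((orig - refl) / 2)
  df_species <- (length(groups) - 1L) * d_sym
  df_side <- d_asym
  df_res <- (n - length(groups)) * d_sym + (n - 1L) * d_asym
  ms <- c(ss_species / df_species, ss_side / df_side, ss_res / df_res)
  f <- c(ms[1L] / ms[3L], ms[2L] / ms[3L], NA_real_)
  p <- c(stats::pf(f[1L], df_species, df_res, lower.tail = FALSE),
         stats::pf(f[2L], df_side, df_res, lower.tail = FALSE),
         NA_real_)
  tab <- data.frame(effect = c("species", "side", "residual"),
                    SS = c(ss_species, ss_side, ss_res),
                    df = c(df_species, df_side, df_res),
                    MS = ms, F = f, p = p,
                    pct_variance = 100 *
                      c(ss_species, ss_side, ss_res) / ss_total,
                    stringsAsFactors = FALSE)
  class(tab) <- c("procrustes_anova", "data.frame")
  if (permutations > 0L) {
    f_obs <- f[1L]
    set.seed(seed)
    f_perm <- replicate(permutations, {
      gp <- sample(grouping)
      ssp <- 0
      for (sp in groups) {
        idx <- gp == sp
        m_s <- colMeans(sym[idx, , drop = FALSE])
        ssp <- ssp + 2 * sum(idx) * sum((m_s - g)^2)
      }
      ssr <- ss_total - ssp - ss_side
      (ssp / df_species) / (ssr / df_res)
    })
    attr(tab, "perm_p") <- (1 + sum(f_perm >= f_obs)) / (permutations + 1)
    attr(tab, "permutations") <- permutations
  }
  tab
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA (doubled original + reflected set)\n")
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 5); df$MS <- signif(df$MS, 5)
  df$F <- signif(df$F, 4); df$p <- signif(df$p, 3)
  df$pct_variance <- round(df$pct_variance, 2)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "perm_p"))) {
    cat(sprintf("Permutation p (species, %d permutations): %.4g\n",
                attr(x, "permutations"), attr(x, "perm_p")))
  }
  invisible(x)
}
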