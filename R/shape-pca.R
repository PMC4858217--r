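#' Principal component analysis of symmetric shape
#'
#' PCA of the covariance matrix of the flattened symmetric shape components
#' about the Procrustes consensus. All \eqn{2k} components are retained
#' internally (zero eigenvalues are kept, not dropped); \code{n_retained}
#' only marks how many axes downstream reports and clustering use. Scores
#' are the eigenvector-basis coordinates of each specimen's symmetric
#' residual from the consensus. Axis signs are fixed by [orient_axes()],
#' which is applied automatically when the dataset uses the standard
#' five-petal roles.
#'
#' @param s a \code{symmetry_decomposition}.
#' @param n_retained number of leading axes used in reports and clustering
#'   (default 2).
#' @param orient fix axis signs by the petal-angle convention when possible
#'   (default \code{TRUE}).
#' @return Object of class \code{"shape_pca"}: list with \code{consensus}
#'   (\code{k x 2}), \code{eigenvectors} (\code{2k x 2k}, orthonormal
#'   columns), \code{eigenvalues} (descending, nonnegative),
#'   \code{variance_fraction}, \code{scores} (\code{n x 2k}), ids, roles and
#'   \code{n_retained}.
#' @export
shape_pca <- function(s, n_retained = 2L, orient = TRUE) {
  stopifnot(inherits(s, "symmetry_decomposition"))
  n <- dim(s$symmetric)[3]
  if (n <= 2L) stop("shape_pca: need more than 2 specimens")
  k <- dim(s$symmetric)[1]
  flat <- t(apply(s$symmetric, 3L, flatten_config))   # n x 2k
  cvec <- flatten_config(s$consensus)
  resid <- sweep(flat, 2L, cvec)
  e <- eigen(stats::cov(resid), symmetric = TRUE)
  values <- pmax(e$values, 0)
  vectors <- e$vectors
  scores <- resid %*% vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- s$specimen_id
  m <- structure(list(consensus = s$consensus, eigenvectors = vectors,
                      eigenvalues = values,
                      variance_fraction = values / sum(values),
                      scores = scores, roles = s$roles,
                      specimen_id = s$specimen_id,
                      species_id = s$species_id,
                      n_retained = as.integer(n_retained)),
                 class = "shape_pca")
  if (orient && !is.null(s$roles) && all(standard_roles() %in% s$roles) &&
      k == 5L) {
    m <- orient_axes(m)
  }
  m
}

#' Fix the signs of the first two shape axes
#'
#' The sign of an eigenvector is arbitrary; this fixes the convention used
#' throughout: moving in the +PC1 direction increases the separation angle
#' between the two dorsal petals (ventralizing them, towards the fan form),
#' and moving in the +PC2 direction decreases the separation angle between
#' the two lateral petals (ventralizing them, towards the bilabiate form).
#' Scores are flipped together with their eigenvectors, so all
#' reconstructions are unchanged. An axis with no effect on its reference
#' angle is left untouched with a message.
#'
#' @param m a \code{shape_pca} fitted on the standard five-petal roles.
#' @param delta score perturbation used to probe the angle response.
#' @return The reoriented \code{shape_pca}.
#' @export
orient_axes <- function(m, delta = 0.1) {
  stopifnot(inherits(m, "shape_pca"))
  if (!all(standard_roles() %in% m$roles)) {
    stop("orient_axes: requires the standard five-petal roles")
  }
  probe <- function(axis, what) {
    sc <- numeric(axis); sc[axis] <- delta
    ang_p <- inter_petal_angles(reconstruct(sc, m), m$roles)[[what]]
    sc[axis] <- -delta
    ang_m <- inter_petal_angles(reconstruct(sc, m), m$roles)[[what]]
    ang_p - ang_m
  }
  d1 <- probe(1L, "dorsal_separation")
  if (abs(d1) < 1e-12) {
    message("orient_axes: PC1 does not affect the dorsal separation; sign unchanged")
  } else if (d1 < 0) {
    m$eigenvectors[, 1L] <- -m$eigenvectors[, 1L]
    m$scores[, 1L] <- -m$scores[, 1L]
  }
  d2 <- probe(2L, "lateral_separation")
  if (abs(d2) < 1e-12) {
    message("orient_axes: PC2 does not affect the lateral separation; sign unchanged")
  } else if (d2 > 0) {
    m$eigenvectors[, 2L] <- -m$eigenvectors[, 2L]
    m$scores[, 2L] <- -m$scores[, 2L]
  }
  m
}

#' Project a symmetric shape onto the shape axes
#'
#' Returns the eigenvector-basis coordinates of a configuration's deviation
#' from the consensus: the inverse of [reconstruct()] on the retained span.
#'
#' @param config \code{k x 2} matrix in the model's alignment frame (a
#'   symmetric component), or a \code{k x 2 x n} array.
#' @param m a \code{shape_pca}.
#' @return Numeric score vector (or \code{n x 2k} matrix for an array).
#' @export
project <- function(config, m) {
  stopifnot(inherits(m, "shape_pca"))
  k <- nrow(m$consensus)
  if (is.array(config) && length(dim(config)) == 3L) {
    return(t(apply(config, 3L, project, m = m)))
  }
  if (!is.matrix(config) || nrow(config) != k || ncol(config) != 2L) {
    stop("project: configuration has wrong landmark count for this model")
  }
  as.vector((flatten_config(config) - flatten_config(m$consensus)) %*%
              m$eigenvectors)
}

#' @export
predict.shape_pca <- function(object, newdata, ...) {
  project(newdata, object)
}

#' Reconstruct a landmark configuration from PC scores
#'
#' The consensus plus the score-weighted sum of eigenvectors, reshaped to a
#' \code{k x 2} configuration: the map from morphospace position back to a
#' five-landmark flower shape. A short score vector addresses the leading
#' axes; the rest are held at zero.
#'
#' @param scores numeric vector of PC scores.
#' @param m a \code{shape_pca}.
#' @return \code{k x 2} matrix with the model's role labels as row names.
#' @export
reconstruct <- function(scores, m) {
  stopifnot(inherits(m, "shape_pca"))
  p <- ncol(m$eigenvectors)
  if (length(scores) > p) stop("reconstruct: too many scores")
  sc <- numeric(p)
  sc[seq_along(scores)] <- scores
  out <- unflatten_config(flatten_config(m$consensus) +
                            as.vector(m$eigenvectors %*% sc),
                          nrow(m$consensus))
  dimnames(out) <- list(m$roles, c("x", "y"))
  out
}

#' Interpolated shapes between two morphospace positions
#'
#' Configurations reconstructed at equally spaced score interpolants between
#' two positions, e.g. between the mean fan-flower and the mean non-fan
#' flower. Endpoints equal the reconstructions of the two inputs.
#'
#' @param m a \code{shape_pca}.
#' @param from_scores,to_scores score vectors.
#' @param n_steps number of configurations returned (>= 2).
#' @return List of \code{k x 2} matrices of length \code{n_steps}.
#' @export
morph_path <- function(m, from_scores, to_scores, n_steps = 5L) {
  stopifnot(n_steps >= 2L)
  p <- max(length(from_scores), length(to_scores))
  f <- numeric(p); f[seq_along(from_scores)] <- from_scores
  t_ <- numeric(p); t_[seq_along(to_scores)] <- to_scores
  lapply(seq(0, 1, length.out = n_steps),
         function(w) reconstruct((1 - w) * f + w * t_, m))
}

#' Angles between adjacent petals
#'
#' For the standard five-petal scheme: the angles, at the configuration
#' centroid, between the direction vectors of adjacent petal apices. Going
#' counter-clockwise the petal order is D_right, D_left, L_left, V, L_right;
#' the five adjacent angles sum to 360 degrees. The dorsal separation is the
#' angle between the two dorsal petals measured through the dorsal midline
#' (the side with the dorsal slit); the lateral separation is the angle
#' between the two lateral petals measured through the ventral petal.
#'
#' @param config \code{k x 2} matrix (k = 5) with the standard roles.
#' @param roles role labels of the rows; defaults to row names or
#'   [standard_roles()].
#' @return List with \code{adjacent} (named 5-vector of angles, degrees),
#'   \code{dorsal_separation} and \code{lateral_separation}.
#' @export
inter_petal_angles <- function(config, roles = NULL) {
  if (is.null(roles)) {
    roles <- rownames(config)
    if (is.null(roles) && nrow(config) == 5L) roles <- standard_roles()
  }
  if (nrow(config) != 5L || !all(standard_roles() %in% roles)) {
    stop("inter_petal_angles: requires the standard five-petal roles")
  }
  ctr <- colMeans(config)
  v <- sweep(config, 2L, ctr)
  if (any(sqrt(rowSums(v^2)) < 1e-12)) {
    stop("inter_petal_angles: a landmark coincides with the centroid")
  }
  gamma <- atan2(v[, 2L], v[, 1L]) * 180 / pi
  names(gamma) <- roles
  ccw <- c("D_right", "D_left", "L_left", "V", "L_right")
  g <- gamma[ccw]
  gaps <- (g[c(2:5, 1L)] - g) %% 360
  names(gaps) <- paste(ccw, ccw[c(2:5, 1L)], sep = "-")
  list(adjacent = gaps,
       dorsal_separation = unname(gaps["D_right-D_left"]),
       lateral_separation = unname(gaps["L_left-V"] + gaps["V-L_right"]))
}

#' @export
print.shape_pca <- function(x, ...) {
  nr <- x$n_retained
  cat("Symmetric-shape PCA:", nrow(x$scores), "specimens,",
      nrow(x$consensus), "landmarks\n")
  vf <- 100 * x$variance_fraction
  cat(sprintf("  %s (cumulative %.1f%% in first %d)\n",
              paste(sprintf("PC%d: %.1f%%", seq_len(nr), vf[seq_len(nr)]),
                    collapse = ", "),
              sum(vf[seq_len(nr)]), nr))
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  data.frame(component = paste0("PC", seq_along(object$eigenvalues)),
             eigenvalue = object$eigenvalues,
             variance_pct = 100 * object$variance_fraction,
             cumulative_pct = 100 * cumsum(object$variance_fraction))
}

#' Morphospace biplot of PC scores
#'
#' Scatter of the first two PC scores, optionally coloured by a grouping
#' (species, cluster or subjective label).
#'
#' @param x a \code{shape_pca}.
#' @param groups optional per-specimen labels used for colour.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_pca <- function(x, groups = NULL, ...) {
  vf <- 100 * x$variance_fraction
  col <- if (is.null(groups)) "black" else as.integer(factor(groups)) + 1L
  graphics::plot(x$scores[, 1L], x$scores[, 2L], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", vf[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", vf[2L]), ...)
  graphics::abline(h = 0, v = 0, col = "grey", lty = 3)
  if (!is.null(groups)) {
    lv <- levels(factor(groups))
    graphics::legend("topleft", legend = lv, col = seq_along(lv) + 1L,
                     pch = 19, bty = "n")
  }
  invisible(x)
}
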