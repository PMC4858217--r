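# Internal geometry helpers ------------------------------------------------

center_config <- function(x) {
  sweep(x, 2L, colMeans(x))
}

rotate2d <- function(x, theta) {
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  x %*% t(r)
}

flatten_config <- function(x) as.vector(x)

unflatten_config <- function(v, k) matrix(v, k, 2L)

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard geometric-morphometrics size measure. It is
#' invariant to translation and rotation and scales linearly under uniform
#' scaling.
#'
#' @param config numeric \code{k x 2} matrix.
#' @return Nonnegative scalar; 0 for a degenerate (all-identical) configuration.
#' @export
centroid_size <- function(config) {
  stopifnot(is.matrix(config), ncol(config) == 2L, all(is.finite(config)))
  sqrt(sum(center_config(config)^2))
}

#' Optimal rotation of one shape onto another
#'
#' Ordinary Procrustes rotation subproblem in 2-D: both configurations must
#' already be centered and scaled to unit centroid size. The optimal proper
#' rotation has the closed form
#' \eqn{\theta = \mathrm{atan2}(\sum_i (x_i y'_i - y_i x'_i),
#' \sum_i (x_i x'_i + y_i y'_i))} where \eqn{(x, y)} is the source and
#' \eqn{(x', y')} the target. Reflections are never used.
#'
#' @param source,target centered, unit-size \code{k x 2} matrices.
#' @return List with \code{aligned} (rotated source), \code{angle}
#'   (counter-clockwise rotation in radians) and \code{distance} (root summed
#'   squared landmark difference after rotation).
#' @export
align_pair <- function(source, target) {
  for (nm in list(source = source, target = target)) {
    if (max(abs(colMeans(nm))) > 1e-6) {
      stop("align_pair: configurations must be centered")
    }
    if (abs(sqrt(sum(nm^2)) - 1) > 1e-6) {
      stop("align_pair: configurations must have unit centroid size")
    }
  }
  a <- sum(source * target)
  b <- sum(source[, 1L] * target[, 2L] - source[, 2L] * target[, 1L])
  theta <- atan2(b, a)
  aligned <- rotate2d(source, theta)
  list(aligned = aligned, angle = theta,
       distance = sqrt(sum((aligned - target)^2)))
}

#' Generalized Procrustes analysis
#'
#' Removes translation, scale and rotation from a set of landmark
#' configurations: all configurations are centered and scaled to unit
#' centroid size, then iteratively rotated to the running consensus (the
#' re-centered, re-scaled mean shape) until the root-mean-squared consensus
#' movement falls below \code{tol}. Only proper rotations are used. With
#' \code{tangent_projection} the aligned shapes are orthogonally projected
#' onto the tangent space at the consensus. When the dataset carries the
#' five standard petal roles, the solution is finally rotated so the midline
#' vector (ventral landmark to the midpoint of the two dorsal landmarks)
#' points along +y, which fixes the display orientation and downstream sign
#' conventions.
#'
#' @param d a \code{landmark_dataset} or a \code{k x 2 x n} array.
#' @param tol convergence tolerance on RMS consensus movement (default 1e-8).
#' @param max_iter maximum iterations (default 100).
#' @param tangent_projection project aligned shapes onto the tangent space at
#'   the consensus (default \code{TRUE}).
#' @param standardize_orientation rotate the solution into the canonical
#'   midline-up frame when the standard roles are present (default
#'   \code{TRUE}).
#' @return Object of class \code{"gpa_fit"}: list with \code{aligned}
#'   (\code{k x 2 x n}), \code{consensus}, \code{centroid_sizes} (original
#'   units), \code{iterations}, \code{converged}, \code{tangent_projected},
#'   plus the ids and roles of the input.
#' @export
gpa <- function(d, tol = 1e-8, max_iter = 100L, tangent_projection = TRUE,
                standardize_orientation = TRUE) {
  if (inherits(d, "landmark_dataset")) {
    coords <- d$coords; roles <- d$roles
    specimen_id <- d$specimen_id; species_id <- d$species_id
  } else {
    coords <- d; roles <- dimnames(d)[[1]]
    specimen_id <- dimnames(d)[[3]]; species_id <- NULL
  }
  k <- dim(coords)[1]; n <- dim(coords)[3]
  if (n < 2L) stop("gpa: need at least 2 configurations")
  cs <- numeric(n)
  aligned <- coords
  for (i in seq_len(n)) {
    x <- center_config(coords[, , i])
    cs[i] <- sqrt(sum(x^2))
    if (cs[i] == 0) stop("gpa: degenerate configuration (zero centroid size): ",
                         specimen_id[i])
    aligned[, , i] <- x / cs[i]
  }
  consensus <- aligned[, , 1L]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- align_pair(aligned[, , i], consensus)$aligned
    }
    new_consensus <- center_config(apply(aligned, c(1L, 2L), mean))
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("gpa: did not converge in ", max_iter, " iterations")
  }
  for (i in seq_len(n)) {
    aligned[, , i] <- align_pair(aligned[, , i], consensus)$aligned
  }
  if (tangent_projection) {
    cvec <- flatten_config(consensus)
    for (i in seq_len(n)) {
      v <- flatten_config(aligned[, , i])
      aligned[, , i] <- unflatten_config(v + (1 - sum(v * cvec)) * cvec, k)
    }
  }
  if (standardize_orientation && !is.null(roles) &&
      all(standard_roles() %in% roles)) {
    m <- (consensus[match("D_left", roles), ] +
            consensus[match("D_right", roles), ]) / 2 -
      consensus[match("V", roles), ]
    theta <- pi / 2 - atan2(m[2L], m[1L])
    consensus <- rotate2d(consensus, theta)
    for (i in seq_len(n)) aligned[, , i] <- rotate2d(aligned[, , i], theta)
  }
  dimnames(aligned) <- dimnames(coords)
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = cs, iterations = iter,
                 converged = converged,
                 tangent_projected = tangent_projection,
                 roles = roles, specimen_id = specimen_id,
                 species_id = species_id),
            class = "gpa_fit")
}

#' Total Procrustes variance of an aligned set
#'
#' Sum over specimens of squared deviations from the consensus, divided by
#' \eqn{n - 1} (the trace of the shape covariance matrix).
#'
#' @param g a \code{gpa_fit}.
#' @return Nonnegative scalar.
#' @export
procrustes_variance <- function(g) {
  n <- dim(g$aligned)[3]
  sum(vapply(seq_len(n),
             function(i) sum((g$aligned[, , i] - g$consensus)^2),
             numeric(1))) / (n - 1)
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit:", dim(x$aligned)[3], "configurations,",
      dim(x$aligned)[1], "landmarks\n")
  cat(sprintf("  iterations: %d (%s); tangent projection: %s\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              if (x$tangent_projected) "on" else "off"))
  cat(sprintf("  total Procrustes variance: %.6g\n", procrustes_variance(x)))
  invisible(x)
}
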