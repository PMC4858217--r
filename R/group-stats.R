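petal_test <- function(statistic, p_value, method, n_per_group,
                       extras = list()) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n_per_group = n_per_group,
                 extras = extras),
            class = "petal_test")
}

#' @export
print.petal_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p = %.4g  (n = %s)\n",
              x$statistic, x$p_value, paste(x$n_per_group, collapse = ", ")))
  if (length(x$extras)) {
    cat("  ", paste(sprintf("%s = %.6g", names(x$extras),
                            unlist(x$extras)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Wilcoxon rank sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank sum test with midranks for ties.
#' Small tie-free samples are tested against the exact rank-sum
#' distribution; otherwise the normal approximation with tie and continuity
#' corrections is used (the study's clade samples, 214 vs 100 flowers, fall
#' in the latter regime). Two samples with all values identical give p = 1.
#'
#' @param a,b numeric samples.
#' @return A \code{petal_test} with the rank-sum statistic W.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (length(unique(c(a, b))) == 1L) {
    return(petal_test(length(a) * length(b) / 2, 1,
                      "Wilcoxon rank sum test (degenerate: all values equal)",
                      c(length(a), length(b))))
  }
  ht <- stats::wilcox.test(a, b, alternative = "two.sided", correct = TRUE)
  petal_test(ht$statistic, ht$p.value, ht$method,
             c(length(a), length(b)))
}

#' Bartlett's test of homogeneity of variances
#'
#' Standard Bartlett chi-squared test across two or more groups. A group
#' with zero variance makes the statistic undefined and raises an error.
#'
#' @param groups list of numeric samples, each of size at least 2.
#' @return A \code{petal_test}.
#' @export
bartlett <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("bartlett: a group has zero variance; statistic undefined")
  }
  ht <- stats::bartlett.test(groups)
  petal_test(ht$statistic, ht$p.value, ht$method, lengths(groups),
             extras = list(df = unname(ht$parameter)))
}

#' Levene's test of homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group center. The default
#' center is the group mean (Levene's original test); \code{center =
#' "median"} gives the Brown-Forsythe variant.
#'
#' @param groups list of numeric samples, each of size at least 2.
#' @param center \code{"mean"} or \code{"median"}.
#' @return A \code{petal_test} with the F statistic.
#' @export
levene <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  cfun <- if (center == "mean") mean else stats::median
  z <- unlist(lapply(groups, function(g) abs(g - cfun(g))))
  lab <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::anova(stats::lm(z ~ lab))
  petal_test(fit$`F value`[1L], fit$`Pr(>F)`[1L],
             sprintf("Levene's test (%s-centered)%s", center,
                     if (center == "median") " [Brown-Forsythe]" else ""),
             lengths(groups),
             extras = list(df1 = fit$Df[1L], df2 = fit$Df[2L]))
}

#' One-way analysis of variance
#'
#' F test of equality of group means, with the coefficient of determination
#' and its group-count adjustment (shared with [adjusted_r2()]).
#'
#' @param values numeric response vector.
#' @param grouping group labels of the same length (>= 2 groups).
#' @return A \code{petal_test} with extras \code{r2} and \code{adj_r2}.
#' @export
one_way_anova <- function(values, grouping) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop("one_way_anova: need at least 2 groups")
  fit <- stats::lm(values ~ grouping)
  a <- stats::anova(fit)
  petal_test(a$`F value`[1L], a$`Pr(>F)`[1L], "One-way ANOVA",
             as.integer(table(grouping)),
             extras = list(r2 = summary(fit)$r.squared,
                           adj_r2 = summary(fit)$adj.r.squared,
                           df1 = a$Df[1L], df2 = a$Df[2L]))
}

#' Simple linear regression
#'
#' Ordinary least squares of y on x with a two-sided t test on the slope;
#' used for the allometry checks (species mean corolla length against
#' centroid size and PC scores).
#'
#' @param x,y numeric vectors of equal length, n >= 3; x must vary.
#' @return A \code{petal_test} with extras \code{slope}, \code{intercept}
#'   and \code{r2}; the statistic is the slope t value.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stop("linear_regression: x is constant")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  petal_test(co["x", "t value"], co["x", "Pr(>|t|)"],
             "Linear regression (OLS, t test on slope)", length(x),
             extras = list(slope = co["x", "Estimate"],
                           intercept = co["(Intercept)", "Estimate"],
                           r2 = summary(fit)$r.squared))
}
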