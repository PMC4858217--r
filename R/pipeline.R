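#' Fit the full floral-symmetry shape model
#'
#' One call from landmark dataset to fitted model: joint Procrustes
#' superimposition with object-symmetry decomposition, PCA of the symmetric
#' shape components with sign-oriented axes, k-means morphotype clustering
#' of the leading scores, species-level summaries and the comparison of
#' subjective labels against morphotypes.
#'
#' @param d a \code{landmark_dataset}.
#' @param pairing a \code{pairing_scheme}; default [pentamerous_pairing()].
#' @param tol,max_iter,tangent_projection GPA options (see [gpa()]).
#' @param n_retained leading axes used in reports/clustering (default 2).
#' @param k,seed,restarts clustering options (see [cluster_morphotypes()]).
#' @return Object of class \code{"floral_symmetry_fit"}: list with
#'   \code{decomposition}, \code{pca}, \code{clusters}, \code{summaries},
#'   \code{comparison}, \code{asymmetry}, \code{anova} and the input
#'   \code{species} table.
#' @export
fit_floral_symmetry <- function(d, pairing = pentamerous_pairing(),
                                tol = 1e-8, max_iter = 100L,
                                tangent_projection = TRUE,
                                n_retained = 2L,
                                k = 3L, seed = 42L, restarts = 100L) {
  stopifnot(inherits(d, "landmark_dataset"))
  s <- decompose_symmetry(d, pairing, tol = tol, max_iter = max_iter,
                          tangent_projection = tangent_projection)
  m <- shape_pca(s, n_retained = n_retained)
  cl <- cluster_morphotypes(m, k = k, seed = seed, restarts = restarts)
  if (k == 3L) cl <- name_clusters(cl)
  summaries <- if (!is.null(cl$code_names)) species_summaries(m, cl) else NULL
  comparison <- if (!is.null(summaries)) {
    compare_groupings(summaries, d$species, m = m, cl = cl)
  } else NULL
  anova_tab <- if (length(unique(d$species_id)) >= 2L) {
    procrustes_anova(s)
  } else NULL
  structure(list(decomposition = s, pca = m, clusters = cl,
                 summaries = summaries, comparison = comparison,
                 asymmetry = asymmetry_summary(s), anova = anova_tab,
                 species = d$species),
            class = "floral_symmetry_fit")
}

#' @export
print.floral_symmetry_fit <- function(x, ...) {
  print(x$pca)
  print(x$decomposition)
  if (!is.null(x$clusters)) print(x$clusters)
  invisible(x)
}

#' @export
summary.floral_symmetry_fit <- function(object, ...) {
  list(variance = summary(object$pca),
       asymmetry = object$asymmetry,
       anova = object$anova,
       species = object$summaries,
       comparison = object$comparison)
}

#' @export
plot.floral_symmetry_fit <- function(x, ...) {
  groups <- if (!is.null(x$clusters$code_names)) {
    x$clusters$code_names[as.character(x$clusters$assignments)]
  } else NULL
  plot(x$pca, groups = groups, ...)
}

pipeline_log <- function(log, stage, msg) {
  c(log, sprintf("[%s] %s", stage, msg))
}

#' Run the end-to-end analysis and write report tables
#'
#' Orchestrates the whole pipeline from a configuration (an R list or a YAML
#' file): load landmarks from a TPS file or delimited table plus a species
#' metadata table, or simulate a dataset; validate; superimpose and
#' decompose symmetry; fit and orient the symmetric-shape PCA; cluster
#' morphotypes; summarize species; compare groupings; run the Procrustes
#' ANOVA and (when two clades are present) the clade comparisons. All report
#' tables are written as tab-delimited text with fixed column order, plus a
#' run log recording the seed, convergence and warnings; a run is
#' deterministic given its configuration.
#'
#' Configuration fields: exactly one of \code{input} (list with
#' \code{coordinates}, optional \code{species}, optional \code{format} =
#' \code{"table"} or \code{"tps"}, optional \code{roles}) or \code{simulate}
#' (arguments of [simulation_config()]); optional \code{gpa} (\code{tol},
#' \code{max_iter}, \code{tangent_projection}), \code{pca}
#' (\code{n_retained}), \code{cluster} (\code{k}, \code{seed},
#' \code{restarts}) and \code{output_dir}.
#'
#' @param config list or path to a YAML file.
#' @param output_dir overrides \code{config$output_dir}; \code{NULL} writes
#'   nothing.
#' @return Invisibly, a list with the fitted objects (\code{fit}), the
#'   dataset, the clade comparison table, the ground truth (when simulated)
#'   and the log lines.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(output_dir)) output_dir <- config$output_dir
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("run_pipeline: config must contain exactly one of 'input' or 'simulate'")
  }
  log <- character()
  truth <- NULL
  if (has_sim) {
    cfg <- do.call(simulation_config, config$simulate)
    sim <- simulate_flowers(cfg)
    d <- sim$dataset; truth <- sim$truth
    log <- pipeline_log(log, "simulate",
                        sprintf("seed %d: %d species, %d images",
                                cfg$seed, nrow(truth$species),
                                n_specimens(d)))
  } else {
    inp <- config$input
    fmt <- if (is.null(inp$format)) "table" else inp$format
    species <- if (!is.null(inp$species)) read_species_table(inp$species)
               else NULL
    d <- switch(fmt,
                table = read_landmark_table(inp$coordinates,
                                            roles = unlist(inp$roles),
                                            species = species),
                tps = read_tps(inp$coordinates, roles = unlist(inp$roles)),
                stop("run_pipeline [load]: unknown input format: ", fmt))
    if (fmt == "tps" && !is.null(species)) d$species <- species
    log <- pipeline_log(log, "load",
                        sprintf("%d configurations, %d species",
                                n_specimens(d),
                                length(unique(d$species_id))))
  }
  v <- validate_dataset(d)
  if (length(v)) {
    stop("run_pipeline [validate]: invalid dataset:\n  ",
         paste(v, collapse = "\n  "))
  }
  log <- pipeline_log(log, "validate", "ok")
  gpa_opts <- config$gpa
  pca_opts <- config$pca
  cl_opts <- config$cluster
  fit <- fit_floral_symmetry(
    d,
    tol = if (is.null(gpa_opts$tol)) 1e-8 else gpa_opts$tol,
    max_iter = if (is.null(gpa_opts$max_iter)) 100L else gpa_opts$max_iter,
    tangent_projection = if (is.null(gpa_opts$tangent_projection)) TRUE
                         else gpa_opts$tangent_projection,
    n_retained = if (is.null(pca_opts$n_retained)) 2L else pca_opts$n_retained,
    k = if (is.null(cl_opts$k)) 3L else cl_opts$k,
    seed = if (is.null(cl_opts$seed)) 42L else cl_opts$seed,
    restarts = if (is.null(cl_opts$restarts)) 100L else cl_opts$restarts)
  log <- pipeline_log(log, "decompose",
                      sprintf("joint GPA %s in %d iterations",
                              if (fit$decomposition$converged) "converged"
                              else "DID NOT CONVERGE",
                              fit$decomposition$iterations))
  vf <- 100 * fit$pca$variance_fraction
  log <- pipeline_log(log, "pca",
                      sprintf("PC1 %.2f%%, PC2 %.2f%%", vf[1L], vf[2L]))
  log <- pipeline_log(log, "cluster",
                      sprintf("k = %d, seed %d, within-SS %.5g",
                              fit$clusters$k, fit$clusters$seed,
                              fit$clusters$within_ss))
  # clade comparison: individuals of the two major clades, outgroups excluded
  clade_by_sp <- stats::setNames(d$species$clade, d$species$species_id)
  clade_ind <- unname(clade_by_sp[d$species_id])
  in_clades <- clade_ind %in% c("goodenia_sl", "scaevola_sl")
  clade_tab <- NULL
  if (length(unique(clade_ind[in_clades])) == 2L) {
    sc <- fit$pca$scores[in_clades, 1:2, drop = FALSE]
    cl_f <- clade_ind[in_clades]
    g1 <- cl_f == "goodenia_sl"
    row_for <- function(axis) {
      a <- sc[g1, axis]; b <- sc[!g1, axis]
      w <- wilcoxon_rank_sum(a, b)
      l <- levene(list(a, b))
      bt <- bartlett(list(a, b))
      data.frame(axis = paste0("PC", axis),
                 goodenia_mean = mean(a), goodenia_sd = stats::sd(a),
                 scaevola_mean = mean(b), scaevola_sd = stats::sd(b),
                 wilcoxon_p = w$p_value, levene_p = l$p_value,
                 bartlett_p = bt$p_value, stringsAsFactors = FALSE)
    }
    clade_tab <- rbind(row_for(1L), row_for(2L))
    log <- pipeline_log(log, "compare",
                        sprintf("clades: %d vs %d individuals",
                                sum(g1), sum(!g1)))
  } else {
    log <- pipeline_log(log, "compare",
                        "fewer than two major clades; clade comparison skipped")
  }
  # reconstructed mean shapes per morphotype
  mean_shapes <- NULL
  if (!is.null(fit$summaries)) {
    groups <- unique(fit$summaries$majority)
    mean_shapes <- do.call(rbind, lapply(groups, function(gname) {
      idx <- fit$summaries$majority == gname
      w <- fit$summaries$n_images[idx]
      sc <- c(stats::weighted.mean(fit$summaries$pc1_mean[idx], w),
              stats::weighted.mean(fit$summaries$pc2_mean[idx], w))
      shp <- reconstruct(sc, fit$pca)
      data.frame(group = gname, role = rownames(shp),
                 x = shp[, 1L], y = shp[, 2L],
                 pc1 = sc[1L], pc2 = sc[2L], stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, name) {
      utils::write.table(x, file.path(output_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(fit$summaries, "species_summary.tsv")
    wt(summary(fit$pca), "variance_explained.tsv")
    asym <- fit$asymmetry
    wt(data.frame(symmetric_mean = asym$symmetric_mean,
                  symmetric_sd = asym$symmetric_sd,
                  asymmetric_mean = asym$asymmetric_mean,
                  asymmetric_sd = asym$asymmetric_sd,
                  ratio_pct = asym$ratio_pct),
       "asymmetry_summary.tsv")
    if (!is.null(fit$anova)) wt(as.data.frame(fit$anova),
                                "procrustes_anova.tsv")
    if (!is.null(clade_tab)) wt(clade_tab, "clade_comparison.tsv")
    if (!is.null(fit$comparison)) {
      conf <- as.data.frame(fit$comparison$confusion)
      wt(conf, "grouping_confusion.tsv")
      if (!is.null(fit$comparison$adjusted_r2)) {
        r2 <- data.frame(axis = rownames(fit$comparison$adjusted_r2),
                         fit$comparison$adjusted_r2)
        wt(r2, "grouping_r2.tsv")
      }
    }
    if (!is.null(mean_shapes)) wt(mean_shapes, "mean_shapes.tsv")
    writeLines(c(sprintf("petalmorph %s",
                         as.character(utils::packageVersion("petalmorph"))),
                 log), file.path(output_dir, "run_log.txt"))
  }
  invisible(list(fit = fit, dataset = d, clade_comparison = clade_tab,
                 mean_shapes = mean_shapes, truth = truth, log = log))
}
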