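#' Pipeline configuration
#'
#' Collects every stage's settings: simulation parameters (or paths to an
#' on-disk cohort), embedding settings, statistical families and levels,
#' and null-model sizes. A single base seed expands deterministically into
#' per-stage seeds so stages can be rerun in isolation.
#'
#' @param params `sim_params` for the simulated cohort, or NULL when
#'   `cohort_dir` points to an on-disk cohort.
#' @param cohort_dir Optional directory with `manifest.tsv`, `regions.tsv`,
#'   matrices and `expression.tsv` (as written by [simulate_cohort()]).
#' @param kernel,sparsity,alpha,t,n_components Embedding settings.
#' @param k Number of gradients analyzed (default 3).
#' @param alpha_level Significance level for all families.
#' @param n_perm Spin/shuffle permutations for the PLS stage.
#' @param n_boot Bootstrap resamples for gene Z scores.
#' @param pls_components PLS components fitted (default 2).
#' @param seed Base seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(params = sim_params(), cohort_dir = NULL,
                            kernel = "cosine", sparsity = 0, alpha = 0.5,
                            t = 0L, n_components = 10L, k = 3L,
                            alpha_level = 0.05, n_perm = 1000L,
                            n_boot = 2000L, pls_components = 2L, seed = 1L) {
  cfg <- list(params = params, cohort_dir = cohort_dir, kernel = kernel,
              sparsity = sparsity, alpha = alpha, t = as.integer(t),
              n_components = as.integer(n_components), k = as.integer(k),
              alpha_level = alpha_level, n_perm = as.integer(n_perm),
              n_boot = as.integer(n_boot),
              pls_components = as.integer(pls_components),
              seed = as.integer(seed))
  if (is.null(cfg$cohort_dir) && !inherits(cfg$params, "sim_params")) {
    stop("either simulation params or a cohort directory is required", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `params:` block maps onto [sim_params()].
#'
#' @param path YAML file path.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sp <- if (!is.null(raw$params)) do.call(sim_params, raw$params) else sim_params()
  raw$params <- NULL
  if (!is.null(raw$cohort_dir) && !dir.exists(raw$cohort_dir)) {
    stop("cohort_dir does not exist: ", raw$cohort_dir, call. = FALSE)
  }
  do.call(pipeline_config, c(list(params = sp), raw))
}

load_cohort <- function(dir) {
  rt <- read_region_table(file.path(dir, "regions.tsv"))
  mf <- read_manifest(file.path(dir, "manifest.tsv"))
  nc <- sum(rt$is_cortical)
  connectomes <- lapply(file.path(dir, mf$connectome_path), read_matrix,
                        expected_shape = c(nc, nc))
  subcortical <- lapply(file.path(dir, mf$subcortical_path), read_matrix)
  names(connectomes) <- names(subcortical) <- mf$subject_id
  expr <- read_matrix(file.path(dir, "expression.tsv"))
  list(region_table = rt, manifest = mf, connectomes = connectomes,
       subcortical = subcortical, expression = expr)
}

stage_seed <- function(cfg, offset) cfg$seed * 13L + offset

#' Run the full gradient analysis pipeline
#'
#' Stages: (1) simulate or load the cohort; (2) build the template and
#' Procrustes-align every subject's gradients; (3) network- and
#' region-level multivariate and univariate group comparisons with age/sex
#' covariates; (4) subcortical-weighted gradient degrees and their
#' comparison; (5) PLS of left-hemisphere expression against the
#' left-hemisphere region-level multivariate statistic map, with spin
#' permutation, bootstrap gene Z scores and signed gene-set selection.
#' All tables are written under `out_dir` with a JSON manifest recording
#' parameters, seeds and md5 hashes of every artifact, so a rerun with the
#' same config is verifiably identical.
#'
#' @param config `pipeline_config`.
#' @param out_dir Output directory (created).
#' @return Invisible list with all in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(config$cohort_dir)) {
    load_cohort(config$cohort_dir)
  } else {
    simulate_cohort(config$params, seed = stage_seed(config, 1L))
  }
  rt <- cohort$region_table
  mf <- cohort$manifest
  ctx <- rt[rt$is_cortical, , drop = FALSE]

  vols <- ctx$volume
  conn <- lapply(cohort$connectomes, volume_scale, volumes = vols)
  template <- build_template(conn, rt, kernel = config$kernel,
                             sparsity = config$sparsity,
                             n_components = config$n_components,
                             alpha = config$alpha, t = config$t)
  aligned <- align_cohort(conn, template, kernel = config$kernel,
                          sparsity = config$sparsity, alpha = config$alpha,
                          t = config$t)
  garr <- gradient_array(aligned, k = config$k)

  X <- design_matrix(mf)
  # network level
  nets <- intersect(cortical_networks, unique(ctx$network))
  net_scores <- vapply(aligned, function(g)
    network_average(g$coordinates[, seq_len(config$k), drop = FALSE], rt),
    matrix(0, length(nets), config$k))
  net_arr <- aperm(net_scores, c(3L, 1L, 2L))
  dimnames(net_arr)[[2L]] <- nets
  net_multi <- compare_multivariate(net_arr, X, family = "7 networks",
                                    alpha = config$alpha_level)
  net_uni <- lapply(seq_len(config$k), function(g)
    compare_univariate(net_arr[, , g], X, family = sprintf("7 networks, g%d", g),
                       alpha = config$alpha_level))
  names(net_uni) <- paste0("g", seq_len(config$k))

  # region level
  reg_multi <- compare_multivariate(garr, X,
                                    units = as.character(ctx$region_id),
                                    family = "cortical regions",
                                    alpha = config$alpha_level)
  reg_posthoc <- lapply(seq_len(config$k), function(g)
    compare_univariate(garr[, , g], X, units = as.character(ctx$region_id),
                       family = sprintf("post hoc, g%d", g),
                       correction = "bonferroni", n_tests = config$k,
                       alpha = config$alpha_level))
  reg_uni <- lapply(seq_len(config$k), function(g)
    compare_univariate(garr[, , g], X, units = as.character(ctx$region_id),
                       family = sprintf("cortical regions, g%d", g),
                       alpha = config$alpha_level))
  names(reg_posthoc) <- names(reg_uni) <- paste0("g", seq_len(config$k))

  # subcortical, volume-scaled with the same sum rule as cortical edges
  # when subcortical volumes are present in the region table
  vol_sub <- rt$volume[!rt$is_cortical]
  subc_scaled <- lapply(cohort$subcortical, function(s) {
    if (length(vol_sub) == nrow(s)) {
      s / outer(vol_sub, vols, `+`)
    } else {
      s / outer(rep(1, nrow(s)), vols)
    }
  })
  degrees <- cohort_subcortical_degrees(aligned, subc_scaled, k = config$k)
  subc <- compare_subcortical(degrees, X, alpha = config$alpha_level)

  # transcriptomic arm: left hemisphere
  left <- ctx$hemisphere == "L"
  y <- as.numeric(scale(reg_multi$statistic[left]))
  expr_l <- cohort$expression[left, , drop = FALSE]
  spin_perms <- build_spin_permutations(rt, n_perm = config$n_perm,
                                        seed = stage_seed(config, 3L),
                                        hemisphere = "left")
  pls_fit <- fit_pls(expr_l, y, n_components = config$pls_components)
  pls_perm <- permutation_test_varexp(expr_l, y, config$pls_components,
                                      n_perm = config$n_perm, null = "spin",
                                      geometry = spin_perms,
                                      seed = stage_seed(config, 4L))
  pls_spatial <- spatial_correlation_of_scores(pls_fit, y = y,
                                               geometry = spin_perms,
                                               n_perm = config$n_perm,
                                               seed = stage_seed(config, 5L))
  boot_z <- bootstrap_weights(expr_l, y, component = pls_fit$selected_component,
                              n_components = config$pls_components,
                              n_boot = config$n_boot,
                              seed = stage_seed(config, 6L))
  gene_sets <- select_genes(boot_z, alpha = config$alpha_level)

  # write artifacts
  paths <- character(0)
  wr <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    paths[[name]] <<- p
    p
  }
  wr(template$coordinates, "template_gradients.tsv", write_matrix)
  utils::write.table(
    data.frame(component = seq_along(template$explained_variance),
               eigenvalue = template$eigenvalues,
               explained_variance = template$explained_variance),
    file.path(out_dir, "template_varexp.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  paths[["template_varexp.tsv"]] <- file.path(out_dir, "template_varexp.tsv")
  wr(net_multi, "network_multivariate.tsv", write_stat_map)
  for (g in names(net_uni)) wr(net_uni[[g]], sprintf("network_univariate_%s.tsv", g), write_stat_map)
  wr(reg_multi, "region_multivariate.tsv", write_stat_map)
  for (g in names(reg_posthoc)) wr(reg_posthoc[[g]], sprintf("region_posthoc_%s.tsv", g), write_stat_map)
  for (g in names(reg_uni)) wr(reg_uni[[g]], sprintf("region_univariate_%s.tsv", g), write_stat_map)
  wr(subc$multivariate, "subcortical_multivariate.tsv", write_stat_map)
  for (g in names(subc$univariate)) wr(subc$univariate[[g]], sprintf("subcortical_univariate_%s.tsv", g), write_stat_map)
  utils::write.table(gene_sets$table, file.path(out_dir, "pls_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths[["pls_genes.tsv"]] <- file.path(out_dir, "pls_genes.tsv")

  manifest <- list(
    config = list(kernel = config$kernel, sparsity = config$sparsity,
                  alpha = config$alpha, t = config$t,
                  n_components = config$n_components, k = config$k,
                  n_perm = config$n_perm, n_boot = config$n_boot,
                  seed = config$seed),
    stage_seeds = list(simulate = stage_seed(config, 1L),
                       spin = stage_seed(config, 3L),
                       pls_perm = stage_seed(config, 4L),
                       pls_spatial = stage_seed(config, 5L),
                       bootstrap = stage_seed(config, 6L)),
    summary = list(
      template_varexp_top3 = sum(template$explained_variance[seq_len(config$k)]),
      significant_networks = net_multi$unit[net_multi$significant],
      n_significant_regions = sum(reg_multi$significant),
      significant_subcortical = subc$multivariate$unit[subc$multivariate$significant],
      pls_varexp = pls_fit$varexp,
      pls_selected_component = pls_fit$selected_component,
      pls_p_joint = pls_perm$p_joint,
      pls_p_per_component = pls_perm$p_per_component,
      pls_score_map_r = pls_spatial$r,
      pls_score_map_p = pls_spatial$p,
      n_plus_genes = length(gene_sets$plus),
      n_minus_genes = length(gene_sets$minus),
      z_threshold = gene_sets$z_threshold,
      spin_duplication_rate = attr(spin_perms, "duplication_rate")),
    artifacts = as.list(tools::md5sum(unlist(paths))))
  names(manifest$artifacts) <- names(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, template = template, aligned = aligned,
                 network = list(multivariate = net_multi, univariate = net_uni),
                 region = list(multivariate = reg_multi, posthoc = reg_posthoc,
                               univariate = reg_uni),
                 subcortical = subc, degrees = degrees,
                 pls = list(fit = pls_fit, permutation = pls_perm,
                            spatial = pls_spatial, boot_z = boot_z,
                            gene_sets = gene_sets),
                 manifest = manifest))
}
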