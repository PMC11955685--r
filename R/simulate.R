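#' Simulation parameters for synthetic cohorts
#'
#' Bundles the knobs of the synthetic-cohort generator. The defaults define
#' the reference simulation used throughout the test suite: 100 regions in
#' 7 networks, 25 subjects per group, modular distance-dependent log-normal
#' connectivity, a patient-group perturbation confined to the somatomotor
#' network, 16 subcortical structures and a 500-gene expression matrix with
#' 20 genes tracking the effect topology.
#'
#' @param n_regions Number of cortical regions (even; half per hemisphere).
#' @param n_networks Number of functional networks (at most 7, labelled
#'   Vis, Smn, Dan, Van, Lim, Fpn, Dmn).
#' @param n_subjects_per_group Subjects in each of control and patient groups.
#' @param edge_length_scale Distance-decay constant (radians of great-circle
#'   arc) of expected edge weight.
#' @param within_network_boost Multiplicative factor (> 1) applied to edges
#'   joining two regions of the same network.
#' @param noise_sd Log-scale standard deviation of the multiplicative
#'   log-normal edge noise.
#' @param effect_networks Character vector of network labels whose incident
#'   edges are perturbed in the patient group.
#' @param effect_size Multiplicative perturbation: selected patient-group
#'   edges are scaled by `1 + effect_size`.
#' @param effect_scope `"within"` (default) scales only edges joining two
#'   effect-network regions; `"incident"` scales every edge touching one.
#' @param n_subcortical Number of subcortical structures (8 bilateral).
#' @param subcortical_effect_structures Indices (1-based) of subcortical
#'   structures perturbed in patients.
#' @param subcortical_effect_size Multiplicative perturbation of those
#'   structures' cortical connectivity.
#' @param n_genes Number of genes in the expression matrix.
#' @param n_signal_genes Number of genes constructed to track the target map.
#' @param expression_autocorr_scale Length scale (radians) of the
#'   squared-exponential spatial covariance of gene maps.
#' @param signal_noise_sd Amplitude of the smooth field added to signal
#'   genes relative to the unit-variance target map.
#' @param age_mean,age_sd Normal age distribution, truncated to 45-80 years.
#' @param seed Base seed recorded with the parameters.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_regions = 100L,
                       n_networks = 7L,
                       n_subjects_per_group = 25L,
                       edge_length_scale = 0.75,
                       within_network_boost = 2,
                       noise_sd = 0.4,
                       effect_networks = "Smn",
                       effect_size = 0.4,
                       effect_scope = "within",
                       n_subcortical = 16L,
                       subcortical_effect_structures = integer(0),
                       subcortical_effect_size = 0,
                       n_genes = 500L,
                       n_signal_genes = 20L,
                       expression_autocorr_scale = 0.3,
                       signal_noise_sd = 1,
                       age_mean = 62,
                       age_sd = 8,
                       seed = 1L) {
  p <- list(n_regions = as.integer(n_regions),
            n_networks = as.integer(n_networks),
            n_subjects_per_group = as.integer(n_subjects_per_group),
            edge_length_scale = edge_length_scale,
            within_network_boost = within_network_boost,
            noise_sd = noise_sd,
            effect_networks = effect_networks,
            effect_size = effect_size,
            effect_scope = match.arg(effect_scope, c("within", "incident")),
            n_subcortical = as.integer(n_subcortical),
            subcortical_effect_structures = as.integer(subcortical_effect_structures),
            subcortical_effect_size = subcortical_effect_size,
            n_genes = as.integer(n_genes),
            n_signal_genes = as.integer(n_signal_genes),
            expression_autocorr_scale = expression_autocorr_scale,
            signal_noise_sd = signal_noise_sd,
            age_mean = age_mean, age_sd = age_sd,
            seed = as.integer(seed))
  if (p$n_regions < 2L * p$n_networks) {
    stop("n_regions must be at least 2 * n_networks", call. = FALSE)
  }
  if (p$n_regions %% 2L != 0L) stop("n_regions must be even", call. = FALSE)
  if (p$n_networks > length(cortical_networks)) {
    stop("at most ", length(cortical_networks), " networks are supported", call. = FALSE)
  }
  if (p$n_signal_genes > p$n_genes) {
    stop("n_signal_genes must not exceed n_genes", call. = FALSE)
  }
  if (p$within_network_boost < 1) stop("within_network_boost must be >= 1", call. = FALSE)
  if (!all(p$effect_networks %in% cortical_networks[seq_len(p$n_networks)])) {
    stop("effect_networks must be defined network labels", call. = FALSE)
  }
  if (p$n_subcortical %% 2L != 0L) stop("n_subcortical must be even (bilateral)", call. = FALSE)
  class(p) <- "sim_params"
  p
}

subcortical_structures <- c("thalamus", "caudate", "putamen", "pallidum",
                            "hippocampus", "amygdala", "accumbens", "ventral-DC")

# shared deep anchor geometry across a cohort: bilateral pairs mirrored in x
subcortical_geometry <- function(n_subcortical, seed) {
  n_half <- n_subcortical %/% 2L
  set.seed(seed + 104729L)
  av <- matrix(stats::rnorm(3L * n_half), ncol = 3L)
  av <- av / sqrt(rowSums(av^2)) * stats::runif(n_half, 0.2, 0.5)
  av[, 1L] <- -abs(av[, 1L])
  anchors <- rbind(av, av * matrix(c(-1, 1, 1), n_half, 3L, byrow = TRUE))
  structs <- rep(subcortical_structures, length.out = n_half)
  list(anchors = anchors,
       names = c(paste0("L_", structs), paste0("R_", structs)),
       structures = structs,
       volumes = exp(stats::rnorm(n_subcortical, 0, 0.3)))
}

#' Great-circle distance matrix between unit vectors
#'
#' @param a Matrix of unit row vectors.
#' @param b Optional second matrix (defaults to `a`).
#' @return Matrix of arc lengths in radians.
#' @export
great_circle <- function(a, b = a) {
  cosang <- tcrossprod(a, b)
  acos(pmin(pmax(cosang, -1), 1))
}

#' Place synthetic parcels on the sphere
#'
#' Samples left-hemisphere centroids uniformly on the unit sphere (each
#' hemisphere has its own registration sphere, as surface-based parcel
#' centroids do) and mirrors them in x to the right hemisphere, producing a
#' bilaterally symmetric geometry suitable for spin-permutation nulls
#' with hemispherically mirrored rotations. Networks are
#' assigned as spatially contiguous caps of comparable size (k-means
#' clustering of the centroids), mirrored across hemispheres, so network
#' labels are spatially autocorrelated. Volumes are log-normal with unit
#' median.
#'
#' @param n_regions Even number of cortical regions.
#' @param n_networks Number of networks (<= 7).
#' @param seed Integer seed.
#' @return A validated region table (see [validate_region_table()]).
#' @export
place_parcels <- function(n_regions, n_networks = 7L, seed = 1L) {
  if (n_regions < 2L * n_networks) stop("n_regions must be at least 2 * n_networks", call. = FALSE)
  if (n_regions %% 2L != 0L) stop("n_regions must be even", call. = FALSE)
  set.seed(seed)
  n_left <- n_regions %/% 2L
  # quasi-uniform parcel centroids: Lloyd relaxation (k-means) of a dense
  # uniform sample, normalized back to the sphere — parcel centroids of a
  # real tessellation are well separated, not iid uniform
  cloud <- matrix(stats::rnorm(3L * 200L * n_left), ncol = 3L)
  cloud <- cloud / sqrt(rowSums(cloud^2))
  km <- stats::kmeans(cloud, centers = n_left, iter.max = 50L, nstart = 1L)
  v <- km$centers / sqrt(rowSums(km$centers^2))
  dimnames(v) <- NULL
  # contiguous network caps of comparable size: k-means of the centroids
  for (attempt in 1:20) {
    kn <- stats::kmeans(v, centers = n_networks, iter.max = 50L, nstart = 5L)
    if (min(tabulate(kn$cluster, n_networks)) >= 2L) break
  }
  nets <- cortical_networks[kn$cluster]
  vols <- exp(stats::rnorm(n_regions, 0, 0.3))
  left <- data.frame(
    region_id = 0:(n_left - 1L),
    name = sprintf("L_%s_%d", nets, seq_len(n_left)),
    hemisphere = "L", network = nets, volume = vols[seq_len(n_left)],
    x = v[, 1L], y = v[, 2L], z = v[, 3L], is_cortical = TRUE,
    stringsAsFactors = FALSE)
  right <- left
  right$region_id <- n_left:(n_regions - 1L)
  right$name <- sprintf("R_%s_%d", nets, seq_len(n_left))
  right$hemisphere <- "R"
  right$volume <- vols[n_left + seq_len(n_left)]
  right$x <- -left$x
  rt <- rbind(left, right)
  rownames(rt) <- NULL
  validate_region_table(rt)
}

#' Generate one synthetic structural connectome
#'
#' Expected weight between regions i and j is
#' `exp(-d(i,j) / edge_length_scale)` times `within_network_boost` when the
#' two regions share a network, with d the great-circle distance; each edge
#' is then multiplied by independent log-normal noise. For the patient
#' group, edges incident to any region of an effect network are multiplied
#' by `1 + effect_size`, shifting those regions' connectivity profiles and
#' hence their gradient positions.
#'
#' @param region_table Region table from [place_parcels()].
#' @param params `sim_params` object.
#' @param group `"control"` or `"patient"`.
#' @param seed Integer seed.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
generate_connectome <- function(region_table, params, group = "control", seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  group <- match.arg(group, c("control", "patient"))
  ctx <- region_table[region_table$is_cortical, , drop = FALSE]
  n <- nrow(ctx)
  cen <- as.matrix(ctx[, c("x", "y", "z")])
  d <- great_circle(cen)
  mu <- exp(-d / params$edge_length_scale)
  same_net <- outer(ctx$network, ctx$network, `==`)
  mu[same_net] <- mu[same_net] * params$within_network_boost
  if (group == "patient" && params$effect_size != 0 && length(params$effect_networks)) {
    # "within": only edges joining two effect-network regions are scaled —
    # changes the network's internal cohesion and shifts its own gradient
    # position while leaving the rest of the connectome first-order intact.
    # "incident": every edge touching an effect region is scaled; under
    # profile-normalizing kernels (cosine) the uniform row factor cancels
    # for effect regions and the perturbation acts diffusely instead.
    hit <- ctx$network %in% params$effect_networks
    sel <- if (params$effect_scope == "within") outer(hit, hit, `&`) else outer(hit, hit, `|`)
    mu[sel] <- mu[sel] * (1 + params$effect_size)
  }
  set.seed(seed)
  noise <- matrix(0, n, n)
  noise[upper.tri(noise)] <- exp(stats::rnorm(n * (n - 1L) / 2L, 0, params$noise_sd))
  noise <- noise + t(noise)
  w <- mu * noise
  diag(w) <- 0
  dimnames(w) <- NULL
  w
}

#' Generate synthetic subcortical-to-cortical connectivity
#'
#' Each subcortical structure sits at a random deep anchor point (inside the
#' sphere, mirrored across hemispheres for bilateral pairs); its cortical
#' connectivity profile decays with Euclidean distance from the anchor to
#' each cortical centroid, times log-normal noise. Structures listed in
#' `params$subcortical_effect_structures` are scaled by
#' `1 + subcortical_effect_size` in the patient group.
#'
#' @param region_table Region table.
#' @param n_subcortical Number of structures (even; defaults from params).
#' @param params `sim_params` object.
#' @param group `"control"` or `"patient"`.
#' @param seed Integer seed. Anchors are derived from `params$seed` so all
#'   subjects share the same subcortical geometry.
#' @return Matrix `n_subcortical x n_cortical`, rows named `L_/R_<structure>`.
#' @export
generate_subcortical <- function(region_table, n_subcortical = params$n_subcortical,
                                 params, group = "control", seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  group <- match.arg(group, c("control", "patient"))
  ctx <- region_table[region_table$is_cortical, , drop = FALSE]
  cen <- as.matrix(ctx[, c("x", "y", "z")])
  geom <- subcortical_geometry(n_subcortical, params$seed)
  anchors <- geom$anchors
  rn <- geom$names
  dd2 <- outer(rowSums(anchors^2), rep(1, nrow(cen))) -
    2 * tcrossprod(anchors, cen) + outer(rep(1, nrow(anchors)), rowSums(cen^2))
  dd <- sqrt(pmax(dd2, 0))
  mu <- exp(-dd / params$edge_length_scale)
  if (group == "patient" && params$subcortical_effect_size != 0 &&
      length(params$subcortical_effect_structures)) {
    mu[params$subcortical_effect_structures, ] <-
      mu[params$subcortical_effect_structures, , drop = FALSE] *
      (1 + params$subcortical_effect_size)
  }
  set.seed(seed)
  noise <- matrix(exp(stats::rnorm(length(mu), 0, params$noise_sd)), nrow(mu), ncol(mu))
  out <- mu * noise
  dimnames(out) <- list(rn, NULL)
  out
}

grf_chol <- function(cen, autocorr_scale) {
  d <- great_circle(cen)
  k <- exp(-d^2 / (2 * autocorr_scale^2))
  chol(k + diag(1e-8, nrow(k)))
}

#' Generate a spatially autocorrelated map
#'
#' One realization of a zero-mean, unit-variance Gaussian random field on
#' the region centroids with a squared-exponential covariance in
#' great-circle distance.
#'
#' @param region_table Region table (cortical rows are used).
#' @param autocorr_scale Length scale in radians.
#' @param seed Integer seed.
#' @return Numeric vector over cortical regions, standardized.
#' @export
generate_autocorrelated_map <- function(region_table, autocorr_scale = 0.3, seed = 1L) {
  ctx <- region_table[region_table$is_cortical, , drop = FALSE]
  cen <- as.matrix(ctx[, c("x", "y", "z")])
  ch <- grf_chol(cen, autocorr_scale)
  set.seed(seed)
  as.numeric(scale(crossprod(ch, stats::rnorm(nrow(cen)))))
}

#' Generate a synthetic regions-by-genes expression matrix
#'
#' Every gene map is a smooth Gaussian random field on the centroids plus
#' independent white measurement noise (probe/donor noise survives parcel
#' averaging in real microarray data); signal genes additionally contain
#' the standardized target map, with the field-plus-noise part scaled by
#' `signal_noise_sd`. All columns are standardized, as a processed
#' microarray matrix would be.
#'
#' @param region_table Region table whose cortical rows carry the maps.
#' @param target_map Numeric vector over the cortical regions.
#' @param n_genes,n_signal_genes Gene counts.
#' @param autocorr_scale Spatial length scale of the smooth field component.
#' @param signal_noise_sd Amplitude of the field-plus-noise component in
#'   signal genes, relative to the unit-variance target.
#' @param measurement_noise_sd White-noise amplitude relative to the
#'   unit-variance smooth field.
#' @param seed Integer seed.
#' @return List with `values` (regions x genes, column-standardized,
#'   colnames gene ids) and `signal_genes` (integer column indices).
#' @export
generate_expression <- function(region_table, target_map, n_genes = 500L,
                                n_signal_genes = 20L, autocorr_scale = 0.3,
                                signal_noise_sd = 1,
                                measurement_noise_sd = 1, seed = 1L) {
  ctx <- region_table[region_table$is_cortical, , drop = FALSE]
  n <- nrow(ctx)
  if (length(target_map) != n) {
    stop("target_map length must match the cortical region count", call. = FALSE)
  }
  if (n_signal_genes > n_genes) stop("n_signal_genes must not exceed n_genes", call. = FALSE)
  cen <- as.matrix(ctx[, c("x", "y", "z")])
  ch <- grf_chol(cen, autocorr_scale)
  set.seed(seed)
  fields <- crossprod(ch, matrix(stats::rnorm(n * n_genes), n, n_genes))
  fields <- fields + measurement_noise_sd * matrix(stats::rnorm(n * n_genes), n, n_genes)
  fields <- fields / sqrt(1 + measurement_noise_sd^2)
  signal_idx <- sort(sample.int(n_genes, n_signal_genes))
  target_z <- as.numeric(scale(target_map))
  x <- fields
  if (n_signal_genes > 0L) {
    x[, signal_idx] <- target_z + signal_noise_sd * fields[, signal_idx, drop = FALSE]
  }
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  colnames(x) <- sprintf("gene%04d", seq_len(n_genes))
  list(values = x, signal_genes = signal_idx)
}

#' Simulate a complete synthetic cohort
#'
#' Generates the region table, per-subject connectomes and subcortical
#' connectivity for both groups, cohort covariates (age ~ Normal(62, 8)
#' truncated to 45-80 years, sex Bernoulli(0.5)), an expression matrix whose
#' signal genes track the injected effect topology, and a ground-truth
#' record of everything injected. Optionally writes the cohort to disk as
#' TSV matrices plus a manifest and ground-truth JSON.
#'
#' @param params `sim_params` object.
#' @param out_dir Optional directory; when given, all artifacts are written
#'   there and paths recorded in the manifest.
#' @param seed Overrides `params$seed` when non-NULL.
#' @return List with `region_table`, `manifest`, `connectomes` (named list),
#'   `subcortical` (named list), `expression`, `target_map`, `ground_truth`.
#' @export
simulate_cohort <- function(params = sim_params(), out_dir = NULL, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) params$seed <- as.integer(seed)
  base <- params$seed
  rt <- place_parcels(params$n_regions, params$n_networks, seed = base)
  geom <- subcortical_geometry(params$n_subcortical, base)
  rt <- rbind(rt, data.frame(
    region_id = params$n_regions + seq_len(params$n_subcortical) - 1L,
    name = geom$names,
    hemisphere = rep(c("L", "R"), each = params$n_subcortical %/% 2L),
    network = rep(geom$structures, 2L),
    volume = geom$volumes,
    x = geom$anchors[, 1L], y = geom$anchors[, 2L], z = geom$anchors[, 3L],
    is_cortical = FALSE, stringsAsFactors = FALSE))
  rt <- validate_region_table(rt)
  n_per <- params$n_subjects_per_group
  groups <- rep(c("control", "patient"), each = n_per)
  ids <- sprintf("sub-%s%03d", ifelse(groups == "control", "c", "p"),
                 c(seq_len(n_per), seq_len(n_per)))
  set.seed(base + 1L)
  age <- stats::rnorm(2L * n_per, params$age_mean, params$age_sd)
  age <- pmin(pmax(age, 45), 80)
  sex <- ifelse(stats::runif(2L * n_per) < 0.5, "female", "male")
  manifest <- data.frame(subject_id = ids, group = groups, age = age, sex = sex,
                         stringsAsFactors = FALSE)

  connectomes <- vector("list", 2L * n_per)
  subcort <- vector("list", 2L * n_per)
  for (i in seq_along(ids)) {
    connectomes[[i]] <- generate_connectome(rt, params, groups[[i]],
                                            seed = base + 1000L + i)
    subcort[[i]] <- generate_subcortical(rt, params$n_subcortical, params,
                                         groups[[i]], seed = base + 5000L + i)
  }
  names(connectomes) <- names(subcort) <- ids

  # target map for expression: smoothed indicator of the effect networks
  ctx <- rt[rt$is_cortical, , drop = FALSE]
  raw_target <- as.numeric(ctx$network %in% params$effect_networks)
  if (stats::sd(raw_target) == 0) raw_target <- raw_target + seq_along(raw_target) * 1e-6
  target <- as.numeric(scale(raw_target))
  expr <- generate_expression(rt, target, params$n_genes, params$n_signal_genes,
                              params$expression_autocorr_scale,
                              params$signal_noise_sd, seed = base + 9000L)

  ground_truth <- list(effect_networks = params$effect_networks,
                       effect_size = params$effect_size,
                       subcortical_effect_structures = params$subcortical_effect_structures,
                       subcortical_effect_size = params$subcortical_effect_size,
                       signal_genes = colnames(expr$values)[expr$signal_genes],
                       seed = base)

  out <- list(region_table = rt, manifest = manifest, connectomes = connectomes,
              subcortical = subcort, expression = expr$values,
              signal_genes = expr$signal_genes, target_map = target,
              ground_truth = ground_truth, params = params)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_region_table(rt, file.path(out_dir, "regions.tsv"))
    cpaths <- file.path(out_dir, paste0(ids, "_connectome.tsv"))
    spaths <- file.path(out_dir, paste0(ids, "_subcortical.tsv"))
    for (i in seq_along(ids)) {
      write_matrix(connectomes[[i]], cpaths[[i]])
      write_matrix(subcort[[i]], spaths[[i]])
    }
    write_matrix(expr$values, file.path(out_dir, "expression.tsv"))
    manifest_disk <- manifest
    manifest_disk$connectome_path <- basename(cpaths)
    manifest_disk$subcortical_path <- basename(spaths)
    utils::write.table(manifest_disk, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$out_dir <- out_dir
  }
  out
}
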