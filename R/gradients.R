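#' Connectivity-profile affinity matrix
#'
#' Pairwise similarity of regional connectivity profiles (rows of the
#' connectome; the zero diagonal contributes nothing to the products).
#' Supported kernels: cosine similarity, Spearman rank correlation, and
#' normalized angle `1 - acos(cosine)/pi`. Negative similarities are
#' clipped to zero (diffusion operators require non-negative weights), the
#' diagonal is set to 1 and the result symmetrized.
#'
#' @param weights Connectome matrix (validated with [validate_connectome()]).
#' @param kernel One of `"cosine"`, `"spearman"`, `"normalized_angle"`.
#' @param sparsity Sparsity level applied with [sparsify()] before the
#'   kernel; 0 (the default) uses the unthresholded connectome.
#' @return List of class `affinity_matrix` with `values` and `kernel`.
#' @export
compute_affinity <- function(weights,
                             kernel = c("cosine", "spearman", "normalized_angle"),
                             sparsity = 0) {
  kernel <- match.arg(kernel)
  weights <- validate_connectome(weights)
  if (sparsity > 0) weights <- sparsify(weights, sparsity)
  zero_rows <- which(rowSums(abs(weights)) == 0)
  if (length(zero_rows)) {
    stop("disconnected region(s) with all-zero connectivity profile: ",
         paste(zero_rows, collapse = ", "), call. = FALSE)
  }
  if (kernel == "spearman") {
    a <- stats::cor(t(weights), method = "spearman")
  } else {
    nrm <- sqrt(rowSums(weights^2))
    cosine <- tcrossprod(weights) / outer(nrm, nrm)
    cosine <- pmin(pmax(cosine, -1), 1)
    a <- if (kernel == "cosine") cosine else 1 - acos(cosine) / pi
  }
  a[a < 0] <- 0
  a <- (a + t(a)) / 2
  diag(a) <- 1
  structure(list(values = a, kernel = kernel, sparsity = sparsity),
            class = "affinity_matrix")
}

affinity_values <- function(x) {
  if (inherits(x, "affinity_matrix")) x$values else x
}

graph_components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  k <- 0L
  adj <- w > 0
  diag(adj) <- FALSE
  for (s in seq_len(n)) {
    if (comp[[s]] != 0L) next
    k <- k + 1L
    frontier <- s
    comp[[s]] <- k
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- k
      frontier <- nb
    }
  }
  comp
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Applies the anisotropic normalization `W' = D^-alpha W D^-alpha` (D the
#' degree diagonal of W), forms the row-stochastic transition operator
#' `P = D'^-1 W'`, and takes its leading nontrivial eigenvectors via the
#' symmetric conjugate `D'^(1/2) P D'^(-1/2)`. The trivial constant
#' eigenvector (eigenvalue 1) is discarded. Components are scaled by
#' `lambda^t` for diffusion time t >= 1 and by the multi-scale weight
#' `lambda / (1 - lambda)` for t = 0, and returned in descending eigenvalue
#' order — descending explained variance.
#'
#' Explained variance defaults to `lambda^2 / sum(lambda^2)` over the full
#' nontrivial spectrum; `ev_power = 1` uses first-power eigenvalues (with
#' negative eigenvalues clamped to zero in the denominator).
#'
#' @param affinity `affinity_matrix` or plain symmetric non-negative matrix.
#' @param n_components Number of gradients to return (< number of regions).
#' @param alpha Anisotropy parameter in `[0, 1]`; 0.5 preserves global
#'   relationships (approximates the Fokker-Planck operator).
#' @param t Diffusion time (non-negative integer; 0 selects the multi-scale
#'   weighting).
#' @param ev_power 2 (default) or 1; exponent in the explained-variance
#'   formula.
#' @return Object of class `gradient_set`: `coordinates` (regions x
#'   n_components, columns g1, g2, ...), `eigenvalues`, `explained_variance`,
#'   and `params`.
#' @export
diffusion_map_embed <- function(affinity, n_components = 10L, alpha = 0.5,
                                t = 0L, ev_power = 2) {
  w <- affinity_values(affinity)
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  n <- nrow(w)
  if (n_components >= n) stop("n_components must be smaller than the region count", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer", call. = FALSE)
  if (any(w < 0)) stop("affinity must be non-negative", call. = FALSE)
  comp <- graph_components(w)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("affinity graph is disconnected (", max(comp), " components of sizes ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  }

  d <- rowSums(w)
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  s <- w1 / outer(sqrt(d1), sqrt(d1))
  s <- (s + t(s)) / 2
  eig <- eigen(s, symmetric = TRUE)
  lam <- eig$values
  vec <- eig$vectors
  # eigen() returns non-increasing eigenvalues; enforce a deterministic
  # orientation-independent order on exact ties
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  vec <- vec[, ord, drop = FALSE]
  # map symmetric eigenvectors to random-walk eigenvectors; dividing by the
  # stationary eigenvector equals D'^(-1/2) scaling up to a constant
  psi <- vec / vec[, 1L]
  lam_nt <- lam[-1L]
  psi_nt <- psi[, -1L, drop = FALSE]
  keep <- seq_len(n_components)
  scale_fac <- if (t == 0L) lam_nt[keep] / (1 - lam_nt[keep]) else lam_nt[keep]^t
  coords <- sweep(psi_nt[, keep, drop = FALSE], 2L, scale_fac, `*`)
  colnames(coords) <- paste0("g", keep)
  ev_base <- if (ev_power == 2) lam_nt^2 else pmax(lam_nt, 0)
  explained <- ev_base[keep] / sum(ev_base)
  structure(list(coordinates = coords,
                 eigenvalues = lam_nt[keep],
                 explained_variance = explained,
                 eigenvalues_full = lam_nt,
                 params = list(alpha = alpha, t = t, ev_power = ev_power)),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient_set: %d regions x %d components (alpha=%.2g, t=%d)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$params$alpha, x$params$t))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Group-level gradient template
#'
#' Averages the cohort's connectomes element-wise, embeds the mean
#' connectome, and fixes the sign convention: each of the first three
#' template gradients is flipped, if needed, so that its correlation with a
#' fixed spatial reference axis (the centroid x, y, z coordinate for g1, g2,
#' g3) is non-negative; later gradients are flipped so their largest-
#' magnitude element is positive. Individual subjects inherit orientation
#' through Procrustes alignment to this template.
#'
#' @param connectomes List of connectome matrices (equal size).
#' @param region_table Region table supplying the reference axes.
#' @param kernel,sparsity Passed to [compute_affinity()].
#' @param n_components,alpha,t,ev_power Passed to [diffusion_map_embed()].
#' @return A `gradient_set` for the mean connectome.
#' @export
build_template <- function(connectomes, region_table,
                           kernel = "cosine", sparsity = 0,
                           n_components = 10L, alpha = 0.5, t = 0L,
                           ev_power = 2) {
  stopifnot(length(connectomes) >= 1L)
  mean_w <- Reduce(`+`, connectomes) / length(connectomes)
  aff <- compute_affinity(mean_w, kernel = kernel, sparsity = sparsity)
  g <- diffusion_map_embed(aff, n_components = n_components, alpha = alpha,
                           t = t, ev_power = ev_power)
  ctx <- region_table[region_table$is_cortical, , drop = FALSE]
  axes <- as.matrix(ctx[, c("x", "y", "z")])
  for (j in seq_len(ncol(g$coordinates))) {
    flip <- if (j <= 3L) {
      stats::cor(g$coordinates[, j], axes[, j]) < 0
    } else {
      g$coordinates[which.max(abs(g$coordinates[, j])), j] < 0
    }
    if (isTRUE(flip)) g$coordinates[, j] <- -g$coordinates[, j]
  }
  g
}

#' Orthogonal Procrustes alignment of gradients to a template
#'
#' Finds the orthogonal matrix S (rotation/reflection; no scaling, no
#' translation) minimizing `||G S - M||_F^2` between a subject's gradients G
#' and the template M, from the SVD of `t(G) %*% M`, and applies it.
#'
#' @param source `gradient_set` (or plain coordinate matrix) to align.
#' @param template `gradient_set` (or matrix) with matching dimensions.
#' @return List with `aligned` (same class as `source`, rotated
#'   coordinates) and `rotation` (k x k orthogonal matrix).
#' @export
procrustes_align <- function(source, template) {
  g <- if (inherits(source, "gradient_set")) source$coordinates else as.matrix(source)
  m <- if (inherits(template, "gradient_set")) template$coordinates else as.matrix(template)
  if (!all(dim(g) == dim(m))) {
    stop(sprintf("dimension mismatch: source is %d x %d, template %d x %d",
                 nrow(g), ncol(g), nrow(m), ncol(m)), call. = FALSE)
  }
  sv <- svd(crossprod(g, m))
  rot <- sv$u %*% t(sv$v)
  aligned_coords <- g %*% rot
  colnames(aligned_coords) <- colnames(m)
  aligned <- source
  if (inherits(source, "gradient_set")) {
    aligned$coordinates <- aligned_coords
  } else {
    aligned <- aligned_coords
  }
  list(aligned = aligned, rotation = rot)
}

#' Embed and align every subject of a cohort
#'
#' Convenience wrapper: embeds each subject's connectome and aligns it to
#' the template with [procrustes_align()].
#'
#' @param connectomes Named list of connectome matrices.
#' @param template `gradient_set` template.
#' @param kernel,sparsity,alpha,t,ev_power Embedding settings (must match
#'   those used for the template).
#' @return Named list of aligned `gradient_set` objects.
#' @export
align_cohort <- function(connectomes, template, kernel = "cosine", sparsity = 0,
                         alpha = 0.5, t = 0L, ev_power = 2) {
  k <- ncol(template$coordinates)
  lapply(connectomes, function(w) {
    g <- diffusion_map_embed(compute_affinity(w, kernel = kernel, sparsity = sparsity),
                             n_components = k, alpha = alpha, t = t,
                             ev_power = ev_power)
    procrustes_align(g, template)$aligned
  })
}

#' Stack cohort gradient scores into a subjects x regions x k array
#'
#' @param aligned Named list of aligned `gradient_set` objects.
#' @param k Number of gradients to keep (default 3).
#' @return Numeric array `n_subjects x n_regions x k`.
#' @export
gradient_array <- function(aligned, k = 3L) {
  n <- length(aligned)
  nr <- nrow(aligned[[1L]]$coordinates)
  arr <- array(NA_real_, dim = c(n, nr, k),
               dimnames = list(names(aligned), NULL, paste0("g", seq_len(k))))
  for (i in seq_len(n)) arr[i, , ] <- aligned[[i]]$coordinates[, seq_len(k)]
  arr
}
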