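#' Partial least squares regression of a spatial map on gene expression
#'
#' Single-response PLS by sequential covariance-maximizing extraction with
#' deflation (NIPALS-equivalent): at each step the gene weight vector is
#' `w = X'y / ||X'y||`, the region scores are `t = X w`, and X and y are
#' deflated by the score regression. The first-component weight vector is
#' therefore proportional to `X'y` for standardized X — the closed-form
#' cross-check used in the tests. Explained variance per component is the
#' incremental R-squared of the original response on the scores.
#'
#' @param X Regions x genes expression matrix (columns standardized).
#' @param y Response vector over regions (internally centered).
#' @param n_components Number of components (default 2).
#' @return Object of class `pls_result`: `weights` (genes x components),
#'   `scores` (regions x components), `varexp`, `loadings`, `y_loadings`,
#'   `selected_component` (argmax of varexp).
#' @export
fit_pls <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("constant response; PLS undefined", call. = FALSE)
  if (n_components > min(dim(X))) stop("too many components", call. = FALSE)
  y0 <- y - mean(y)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y0
  n_genes <- ncol(X)
  W <- matrix(NA_real_, n_genes, n_components)
  P <- matrix(NA_real_, n_genes, n_components)
  Tm <- matrix(NA_real_, nrow(X), n_components)
  qv <- numeric(n_components)
  for (comp in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate deflated covariance at component ", comp, call. = FALSE)
    w <- w / nw
    tt <- as.numeric(Xc %*% w)
    t2 <- sum(tt^2)
    p_load <- crossprod(Xc, tt) / t2
    q_load <- sum(yc * tt) / t2
    Xc <- Xc - tcrossprod(tt, p_load)
    yc <- yc - tt * q_load
    W[, comp] <- w
    P[, comp] <- p_load
    Tm[, comp] <- tt
    qv[comp] <- q_load
  }
  # incremental R^2 of the original centered response on each score
  # (scores are mutually orthogonal in single-response NIPALS)
  ssy <- sum(y0^2)
  varexp <- vapply(seq_len(n_components), function(comp) {
    tt <- Tm[, comp]
    (sum(tt * y0)^2 / sum(tt^2)) / ssy
  }, numeric(1L))
  rownames(W) <- colnames(X)
  colnames(W) <- colnames(Tm) <- paste0("pls", seq_len(n_components))
  structure(list(weights = W, scores = Tm, varexp = varexp,
                 loadings = P, y_loadings = qv,
                 selected_component = which.max(varexp)),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("pls_result: %d genes, %d regions, %d components\n",
              nrow(x$weights), nrow(x$scores), ncol(x$scores)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$varexp), collapse = " "),
      sprintf("(component %d selected)\n", x$selected_component))
  invisible(x)
}

#' Permutation test of PLS explained variance
#'
#' Null distribution of the variance explained by the PLS components,
#' obtained by refitting on permuted responses. The default null spins the
#' response over the sphere (preserving spatial autocorrelation); plain
#' shuffling is available for comparison. Reports the joint test on the
#' cumulative variance of all components and per-component tests, both
#' with the +1 correction.
#'
#' @param X Expression matrix.
#' @param y Response vector.
#' @param n_components Components to fit.
#' @param n_perm Number of permutations.
#' @param null `"spin"` (default) or `"shuffle"`.
#' @param geometry Region table / centroids / permutation matrix for the
#'   spin null (see [spin_correlation_test()]).
#' @param seed Integer seed.
#' @param hemisphere For region-table geometry (default `"left"`, matching
#'   a left-hemisphere transcriptomic analysis).
#' @return List with `p_joint`, `p_per_component`, `observed`,
#'   `observed_per_component`, `null_cumulative`.
#' @export
permutation_test_varexp <- function(X, y, n_components = 2L, n_perm = 1000L,
                                    null = c("spin", "shuffle"),
                                    geometry = NULL, seed = 1L,
                                    hemisphere = "left") {
  null <- match.arg(null)
  fit <- fit_pls(X, y, n_components)
  obs_per <- fit$varexp
  obs_cum <- sum(obs_per)
  n <- length(y)
  if (null == "spin") {
    if (is.null(geometry)) stop("spin null requires geometry", call. = FALSE)
    if (is.matrix(geometry) && is.integer(geometry[1L])) {
      perms <- geometry
    } else if (is.data.frame(geometry)) {
      perms <- build_spin_permutations(geometry, n_perm, seed, hemisphere)
    } else {
      cen <- as.matrix(geometry)
      set.seed(seed)
      perms <- t(vapply(seq_len(n_perm), function(b) {
        nearest_index(cen %*% t(random_rotation()), cen)
      }, integer(n)))
    }
  } else {
    set.seed(seed)
    perms <- t(vapply(seq_len(n_perm), function(b) sample.int(n), integer(n)))
  }
  null_per <- matrix(NA_real_, nrow(perms), n_components)
  for (b in seq_len(nrow(perms))) {
    yb <- y[perms[b, ]]
    if (stats::sd(yb) == 0) next
    null_per[b, ] <- fit_pls(X, yb, n_components)$varexp
  }
  ok <- stats::complete.cases(null_per)
  null_per <- null_per[ok, , drop = FALSE]
  null_cum <- rowSums(null_per)
  p_joint <- (1 + sum(null_cum >= obs_cum)) / (1 + nrow(null_per))
  p_per <- vapply(seq_len(n_components), function(comp) {
    (1 + sum(null_per[, comp] >= obs_per[comp])) / (1 + nrow(null_per))
  }, numeric(1L))
  list(p_joint = p_joint, p_per_component = p_per,
       observed = obs_cum, observed_per_component = obs_per,
       null_cumulative = null_cum)
}

#' Spin test of the correlation between PLS scores and the response map
#'
#' @param fit `pls_result`.
#' @param component Component index (default the selected component).
#' @param y Response vector over the same regions.
#' @param geometry Geometry for [spin_correlation_test()].
#' @param n_perm Number of spins.
#' @param seed Integer seed.
#' @param hemisphere Hemisphere mode for region-table geometry.
#' @return List with `r` and `p` from [spin_correlation_test()].
#' @export
spatial_correlation_of_scores <- function(fit, component = fit$selected_component,
                                          y, geometry, n_perm = 1000L, seed = 1L,
                                          hemisphere = "left") {
  spin_correlation_test(fit$scores[, component], y, geometry,
                        n_perm = n_perm, seed = seed, hemisphere = hemisphere)
}

#' Bootstrap Z scores of PLS gene weights
#'
#' Resamples regions with replacement, refits the PLS, re-signs each
#' bootstrap weight vector so that it correlates positively with the
#' original component (sign alignment is mandatory: component sign flips
#' would otherwise inflate the bootstrap SD and destroy Z calibration), and
#' returns `Z = original weight / bootstrap SD` per gene. Degenerate
#' resamples (a single distinct region) are redrawn and counted.
#'
#' @param X Expression matrix (regions x genes).
#' @param y Response vector.
#' @param component Component whose weights are bootstrapped (default from
#'   the fit on the full data).
#' @param n_components Components fitted in each resample (defaults to
#'   `component`).
#' @param n_boot Number of resamples (default 2000).
#' @param seed Integer seed.
#' @return Named numeric vector of Z scores with attributes `weights`
#'   (original weights) and `n_redrawn`.
#' @export
bootstrap_weights <- function(X, y, component = NULL, n_components = NULL,
                              n_boot = 2000L, seed = 1L) {
  full <- fit_pls(X, y, if (is.null(n_components)) max(2L, component %||% 2L)
                  else n_components)
  if (is.null(component)) component <- full$selected_component
  w0 <- full$weights[, component]
  n <- nrow(X)
  boots <- matrix(NA_real_, length(w0), n_boot)
  set.seed(seed)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(idx)) > 1L && stats::sd(y[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    wb <- fit_pls(X[idx, , drop = FALSE], y[idx], component)$weights[, component]
    if (sum(wb * w0) < 0) wb <- -wb
    boots[, b] <- wb
  }
  sds <- apply(boots, 1L, stats::sd)
  z <- w0 / sds
  z[sds == 0] <- 0
  names(z) <- names(w0)
  attr(z, "weights") <- w0
  attr(z, "n_redrawn") <- n_redrawn
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select significant genes from bootstrap Z scores
#'
#' Two-sided normal p-values per gene, Benjamini-Hochberg correction across
#' genes, and a split of the significant genes by weight sign into positive
#' and negative sets. The realized |Z| threshold at the FDR boundary is
#' reported.
#'
#' @param boot_z Named Z-score vector from [bootstrap_weights()].
#' @param alpha FDR level (default 0.05).
#' @return List with `plus` and `minus` gene-name vectors, `z_threshold`
#'   (minimum |Z| among selected genes, NA when none), and the per-gene
#'   table `table` (gene, z, p, q, set).
#' @export
select_genes <- function(boot_z, alpha = 0.05) {
  z <- as.numeric(boot_z)
  genes <- names(boot_z)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_along(z))
  p <- 2 * stats::pnorm(-abs(z))
  q <- fdr_bh(p)
  sig <- q < alpha
  set <- ifelse(!sig, "ns", ifelse(z > 0, "plus", "minus"))
  tab <- data.frame(gene = genes, z = z, p = p, q = q, set = set,
                    stringsAsFactors = FALSE)
  list(plus = genes[sig & z > 0],
       minus = genes[sig & z < 0],
       z_threshold = if (any(sig)) min(abs(z[sig])) else NA_real_,
       table = tab)
}
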