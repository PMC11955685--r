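#' Subcortical-weighted gradient
#'
#' Element-wise product of a cortical gradient with one subcortical
#' structure's cortical connectivity profile.
#'
#' @param gradient Numeric vector over cortical regions.
#' @param subcortical_row Connectivity profile of equal length.
#' @return Weighted cortical vector.
#' @export
weighted_gradient <- function(gradient, subcortical_row) {
  if (length(gradient) != length(subcortical_row)) {
    stop("gradient and subcortical row must have equal length", call. = FALSE)
  }
  gradient * subcortical_row
}

#' Degree of a weighted gradient
#'
#' The nodal degree of a subcortical structure along one gradient: the
#' arithmetic mean of its weighted gradient.
#'
#' @param weighted Weighted cortical vector.
#' @return Scalar mean.
#' @export
degree <- function(weighted) {
  mean(weighted)
}

#' Per-subject subcortical degree matrix
#'
#' Computes degree values for every subcortical structure along each of the
#' first k aligned gradients: `degrees[s, g] = mean(subcortical[s, ] *
#' gradient_g)`. Subcortical rows are volume-scaled with the subcortical
#' volumes when provided, mirroring the cortical edge normalization.
#'
#' @param gradients `gradient_set` (subject's aligned gradients) or matrix.
#' @param subcortical n_subcortical x n_cortical connectivity matrix.
#' @param k Number of gradients (default 3).
#' @return n_subcortical x k matrix of degrees.
#' @export
subcortical_degrees <- function(gradients, subcortical, k = 3L) {
  g <- if (inherits(gradients, "gradient_set")) gradients$coordinates else as.matrix(gradients)
  stopifnot(ncol(subcortical) == nrow(g), k <= ncol(g))
  out <- subcortical %*% g[, seq_len(k), drop = FALSE] / ncol(subcortical)
  colnames(out) <- paste0("g", seq_len(k))
  out
}

#' Cohort array of subcortical degrees
#'
#' @param aligned Named list of aligned `gradient_set` objects.
#' @param subcortical Named list of subcortical connectivity matrices in
#'   the same subject order.
#' @param k Number of gradients.
#' @return Array `n_subjects x n_subcortical x k`.
#' @export
cohort_subcortical_degrees <- function(aligned, subcortical, k = 3L) {
  stopifnot(length(aligned) == length(subcortical))
  first <- subcortical_degrees(aligned[[1L]], subcortical[[1L]], k)
  arr <- array(NA_real_,
               dim = c(length(aligned), nrow(first), k),
               dimnames = list(names(aligned), rownames(first), colnames(first)))
  arr[1L, , ] <- first
  for (i in seq_along(aligned)[-1L]) {
    arr[i, , ] <- subcortical_degrees(aligned[[i]], subcortical[[i]], k)
  }
  arr
}

#' Group comparison of subcortical degrees
#'
#' Multivariate (Hotelling's T-squared across the k gradients jointly) and
#' per-gradient univariate comparisons of subcortical degree values, each
#' FDR-corrected across the subcortical structures.
#'
#' @param degrees Array `n_subjects x n_subcortical x k` from
#'   [cohort_subcortical_degrees()].
#' @param X Design matrix.
#' @param alpha Significance level.
#' @return List: `multivariate` stat map, `univariate` list of per-gradient
#'   stat maps.
#' @export
compare_subcortical <- function(degrees, X, alpha = 0.05) {
  units <- dimnames(degrees)[[2L]]
  multi <- compare_multivariate(degrees, X, units = units,
                                family = "subcortical structures", alpha = alpha)
  k <- dim(degrees)[[3L]]
  uni <- lapply(seq_len(k), function(g) {
    compare_univariate(degrees[, , g], X, units = units,
                       family = paste0("subcortical structures, g", g),
                       alpha = alpha)
  })
  names(uni) <- paste0("g", seq_len(k))
  list(multivariate = multi, univariate = uni)
}
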