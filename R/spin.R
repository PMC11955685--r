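#' Uniform random 3-D rotation
#'
#' Draws a rotation uniformly from SO(3) by QR-orthogonalizing a standard
#' Gaussian matrix, sign-correcting with the signs of the diagonal of R,
#' and flipping one column if the determinant is -1.
#'
#' @return 3 x 3 orthogonal matrix with determinant +1. Uses the current
#'   RNG state; seed with [set.seed()] upstream.
#' @export
random_rotation <- function() {
  z <- matrix(stats::rnorm(9L), 3L, 3L)
  qrz <- qr(z)
  q <- qr.Q(qrz)
  q <- q %*% diag(sign(diag(qr.R(qrz))))
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

nearest_index <- function(rotated, originals) {
  # argmax of dot product = nearest on the sphere; ties -> lowest index
  sim <- tcrossprod(rotated, originals)
  max.col(sim, ties.method = "first")
}

#' Spin a parcellated map by a rotation
#'
#' Each region's value is replaced by the value of the region whose
#' original centroid is nearest (great-circle) to that region's rotated
#' centroid. Nearest-neighbour ties go to the lowest region index.
#'
#' @param map Numeric vector over regions.
#' @param centroids Matrix of unit row vectors, one per region.
#' @param rotation 3 x 3 rotation matrix.
#' @return List with `values` (permuted map) and `index` (source region of
#'   each output value).
#' @export
spin_map <- function(map, centroids, rotation) {
  stopifnot(length(map) == nrow(centroids))
  rotated <- centroids %*% t(rotation)
  idx <- nearest_index(rotated, centroids)
  list(values = map[idx], index = idx)
}

#' Precompute spin permutations for a parcellation
#'
#' Builds an `n_perm x n_regions` index matrix of spin permutations.
#' For whole-cortex maps (`hemisphere = "both"`), one rotation is applied to
#' the left-hemisphere centroids and its x-mirrored image to the right, and
#' nearest-centroid lookup is restricted within hemisphere, preserving
#' hemispheric correspondence. For `hemisphere = "left"` only left cortical
#' regions are rotated (the transcriptomic arm). The realized duplication
#' rate (fraction of non-bijective assignments) is stored as an attribute.
#'
#' @param region_table Region table (cortical rows used).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param hemisphere `"both"` or `"left"`.
#' @return Integer matrix `n_perm x n_regions_used` with attributes
#'   `duplication_rate` and `regions` (row indices of the cortical subset
#'   used).
#' @export
build_spin_permutations <- function(region_table, n_perm = 1000L, seed = 1L,
                                    hemisphere = c("both", "left")) {
  hemisphere <- match.arg(hemisphere)
  ctx <- region_table[region_table$is_cortical, , drop = FALSE]
  use <- if (hemisphere == "left") which(ctx$hemisphere == "L") else seq_len(nrow(ctx))
  cen <- as.matrix(ctx[use, c("x", "y", "z")])
  hemi <- ctx$hemisphere[use]
  left <- hemi == "L"
  mirror <- diag(c(-1, 1, 1))
  perms <- matrix(NA_integer_, n_perm, length(use))
  set.seed(seed)
  dup <- 0
  for (b in seq_len(n_perm)) {
    r <- random_rotation()
    idx <- integer(length(use))
    if (hemisphere == "left" || !any(!left)) {
      rotated <- cen %*% t(r)
      idx <- nearest_index(rotated, cen)
    } else {
      rl <- cen[left, , drop = FALSE] %*% t(r)
      idx_l <- which(left)[nearest_index(rl, cen[left, , drop = FALSE])]
      rm_ <- mirror %*% r %*% mirror
      rr <- cen[!left, , drop = FALSE] %*% t(rm_)
      idx_r <- which(!left)[nearest_index(rr, cen[!left, , drop = FALSE])]
      idx[left] <- idx_l
      idx[!left] <- idx_r
    }
    dup <- dup + 1 - length(unique(idx)) / length(idx)
    perms[b, ] <- idx
  }
  attr(perms, "duplication_rate") <- dup / n_perm
  attr(perms, "regions") <- use
  attr(perms, "seed") <- seed
  perms
}

#' Spin-permutation test of a spatial correlation
#'
#' Pearson correlation between two region-level maps with a two-tailed
#' spatial-autocorrelation-preserving null: map_a is spun `n_perm` times
#' while map_b stays fixed, and
#' `p = (1 + #(|r_null| >= |r_obs|)) / (1 + n_perm)`. Only map_a is spun;
#' this asymmetry is intentional and documented.
#'
#' @param map_a,map_b Numeric vectors over the same regions.
#' @param geometry Region table, or a centroid matrix (unit row vectors),
#'   or a precomputed permutation matrix from [build_spin_permutations()].
#' @param n_perm Number of spins (ignored when permutations are supplied).
#' @param seed Integer seed.
#' @param hemisphere Passed to [build_spin_permutations()] for region
#'   tables.
#' @return List with `r`, `p`, `n_perm`, `null` (the null correlations).
#' @export
spin_correlation_test <- function(map_a, map_b, geometry, n_perm = 1000L,
                                  seed = 1L, hemisphere = "both") {
  stopifnot(length(map_a) == length(map_b))
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("correlation undefined for a constant map", call. = FALSE)
  }
  if (is.matrix(geometry) && is.integer(geometry[1L])) {
    perms <- geometry
  } else if (is.data.frame(geometry)) {
    perms <- build_spin_permutations(geometry, n_perm, seed, hemisphere)
  } else {
    # raw centroid matrix: single-sphere rotations
    cen <- as.matrix(geometry)
    stopifnot(nrow(cen) == length(map_a))
    set.seed(seed)
    perms <- t(vapply(seq_len(n_perm), function(b) {
      nearest_index(cen %*% t(random_rotation()), cen)
    }, integer(nrow(cen))))
  }
  if (ncol(perms) != length(map_a)) {
    stop("permutation matrix does not match map length", call. = FALSE)
  }
  r_obs <- stats::cor(map_a, map_b)
  spun <- matrix(map_a[t(perms)], ncol = nrow(perms))  # regions x n_perm
  r_null <- as.numeric(suppressWarnings(stats::cor(spun, map_b)))
  r_null[is.na(r_null)] <- 0  # a spin that lands constant carries no evidence
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + nrow(perms))
  list(r = r_obs, p = p, n_perm = nrow(perms), null = r_null)
}
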