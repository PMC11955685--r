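test_that("affinity kernels match hand-computed similarities", {
  # two identical rows -> similarity 1; orthogonal rows -> 0 after clipping
  w <- matrix(0, 4, 4)
  w[1, 3] <- w[3, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 4] <- w[4, 1] <- 1
  w[2, 4] <- w[4, 2] <- 1
  w[3, 4] <- w[4, 3] <- 0.5
  a <- compute_affinity(w, "cosine")
  expect_equal(a$values[1, 2], 1)           # rows 1 and 2 identical
  expect_equal(diag(a$values), rep(1, 4))
  expect_true(all(a$values >= 0 & a$values <= 1))
  expect_equal(a$values, t(a$values))

  # hand case: profiles (1,1,0) and (1,0,1) -> cosine 1/2
  w2 <- rbind(c(0, 0, 1, 1, 0),
              c(0, 0, 1, 0, 1),
              c(1, 1, 0, 1, 1),
              c(1, 0, 1, 0, 1),
              c(0, 1, 1, 1, 0))
  a2 <- compute_affinity(w2, "cosine")
  expect_equal(a2$values[1, 2], 0.5)
  # normalized angle of the same pair: 1 - acos(0.5)/pi = 2/3
  a3 <- compute_affinity(w2, "normalized_angle")
  expect_equal(a3$values[1, 2], 2 / 3)

  # spearman kernel is rank-based: monotone row transforms are invisible
  w3 <- random_connectome(8, 3)
  a4 <- compute_affinity(w3, "spearman")
  a5 <- compute_affinity(w3^3, "spearman")
  expect_equal(a4$values, a5$values, tolerance = 1e-12)

  wz <- random_connectome(5, 1); wz[2, ] <- 0; wz[, 2] <- 0
  expect_error(compute_affinity(wz), "disconnected region")
})

test_that("diffusion embedding matches a dense eigendecomposition oracle", {
  for (s in 1:5) {
    a <- random_affinity(30, s)
    g <- diffusion_map_embed(a, n_components = 5, alpha = 0.5, t = 0)

    # independent dense oracle on the symmetrized operator
    d <- rowSums(a)
    w1 <- a / outer(d^0.5, d^0.5)
    d1 <- rowSums(w1)
    sym <- w1 / outer(sqrt(d1), sqrt(d1))
    eig <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
    lam <- eig$values[-1][1:5]
    expect_equal(g$eigenvalues, lam, tolerance = 1e-8)

    psi <- eig$vectors / eig$vectors[, 1]
    for (j in 1:5) {
      expected <- psi[, j + 1] * lam[j] / (1 - lam[j])
      got <- g$coordinates[, j]
      expect_true(min(max(abs(got - expected)), max(abs(got + expected))) < 1e-8)
    }
  }
})

test_that("two weakly bridged cliques separate in sign on gradient 1", {
  n <- 10
  a <- matrix(1e-4, n, n)
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 1
  g <- diffusion_map_embed(a, 3)
  g1 <- g$coordinates[, 1]
  expect_true(all(sign(g1[1:5]) == sign(g1[1])))
  expect_true(all(sign(g1[6:10]) == -sign(g1[1])))
})

test_that("embedding is equivariant under region permutation", {
  a <- random_affinity(20, 7)
  perm <- sample(20)
  g <- diffusion_map_embed(a, 4)
  gp <- diffusion_map_embed(a[perm, perm], 4)
  for (j in 1:4) {
    x <- g$coordinates[perm, j]; y <- gp$coordinates[, j]
    expect_true(min(max(abs(x - y)), max(abs(x + y))) < 1e-8)
  }
  expect_equal(g$eigenvalues, gp$eigenvalues, tolerance = 1e-10)
})

test_that("embedding is invariant to uniform rescaling of the affinity", {
  a <- random_affinity(15, 9)
  g1 <- diffusion_map_embed(a, 4)
  g2 <- diffusion_map_embed(2.5 * a, 4)
  for (j in 1:4) {
    x <- g1$coordinates[, j]; y <- g2$coordinates[, j]
    expect_true(min(max(abs(x - y)), max(abs(x + y))) < 1e-8)
  }
})

test_that("doubling connectome weights leaves cosine gradients unchanged", {
  w <- random_connectome(20, 11)
  g1 <- diffusion_map_embed(compute_affinity(w), 4)
  g2 <- diffusion_map_embed(compute_affinity(2 * w), 4)
  expect_equal(g1$coordinates, g2$coordinates, tolerance = 1e-10)
})

test_that("disconnected affinity graphs are rejected with component count", {
  a <- diag(1, 6)
  a[1:3, 1:3] <- 1
  a[4:6, 4:6] <- 1
  expect_error(diffusion_map_embed(a, 2), "disconnected")
  expect_error(diffusion_map_embed(random_affinity(10, 1), 10), "n_components")
})

test_that("explained variance is a proper fraction ordered with eigenvalues", {
  a <- random_affinity(25, 13)
  g <- diffusion_map_embed(a, 10)
  expect_true(all(g$explained_variance >= 0 & g$explained_variance <= 1))
  expect_lte(sum(g$explained_variance), 1 + 1e-12)
  expect_true(all(diff(g$eigenvalues) <= 1e-12))
  # t >= 1 scaling uses lambda^t
  g2 <- diffusion_map_embed(a, 3, t = 2L)
  psi <- g$coordinates[, 1] * (1 - g$eigenvalues[1]) / g$eigenvalues[1]
  expect_equal(g2$coordinates[, 1], psi * g$eigenvalues[1]^2, tolerance = 1e-8)
})

test_that("template equals the individual embedding for degenerate cohorts", {
  co <- small_cohort()
  w <- co$connectomes[[1]]
  rt <- co$region_table
  tpl1 <- build_template(list(w), rt, n_components = 4)
  tpl3 <- build_template(list(w, w, w), rt, n_components = 4)
  expect_equal(tpl1$coordinates, tpl3$coordinates, tolerance = 1e-10)

  solo <- diffusion_map_embed(compute_affinity(w), 4)
  for (j in 1:4) {
    x <- tpl1$coordinates[, j]; y <- solo$coordinates[, j]
    expect_true(min(max(abs(x - y)), max(abs(x + y))) < 1e-8)
  }
})

test_that("template sign convention is deterministic and axis-anchored", {
  co <- small_cohort()
  rt <- co$region_table
  tpl <- build_template(co$connectomes, rt, n_components = 4)
  ctx <- rt[rt$is_cortical, ]
  for (j in 1:3) {
    expect_gte(cor(tpl$coordinates[, j], ctx[[c("x", "y", "z")[j]]]), 0)
  }
})

test_that("Procrustes aligns exactly: identity, recovery, and optimality", {
  co <- small_cohort()
  tpl <- build_template(co$connectomes, co$region_table, n_components = 5)

  self <- procrustes_align(tpl, tpl)
  expect_equal(self$rotation, diag(5), tolerance = 1e-8)

  # construct-and-recover with random orthogonal matrices
  for (s in 1:5) {
    r <- random_orthogonal(5, s)
    g <- tpl
    g$coordinates <- tpl$coordinates %*% t(r)
    rec <- procrustes_align(g, tpl)
    expect_equal(rec$rotation, r, tolerance = 1e-8)
    expect_lt(norm(rec$aligned$coordinates - tpl$coordinates, "F"), 1e-10)
  }

  # optimality: aligned residual never exceeds unaligned residual
  g2 <- diffusion_map_embed(compute_affinity(co$connectomes[[2]]), 5)
  al <- procrustes_align(g2, tpl)
  expect_lte(norm(al$aligned$coordinates - tpl$coordinates, "F"),
             norm(g2$coordinates - tpl$coordinates, "F"))
  expect_equal(crossprod(al$rotation), diag(5), tolerance = 1e-8)

  expect_error(procrustes_align(matrix(0, 3, 2), matrix(0, 4, 2)), "mismatch")
})

test_that("alignment raises between-subject gradient agreement", {
  co <- small_cohort()
  tpl <- build_template(co$connectomes, co$region_table, n_components = 5)
  raw <- lapply(co$connectomes[1:6], function(w)
    diffusion_map_embed(compute_affinity(w), 5))
  al <- align_cohort(co$connectomes[1:6], tpl)
  mean_abs_cor <- function(gs) {
    pairs <- combn(length(gs), 2)
    mean(apply(pairs, 2, function(ij)
      abs(cor(gs[[ij[1]]]$coordinates[, 2], gs[[ij[2]]]$coordinates[, 2]))))
  }
  # compare signed agreement: alignment fixes sign and axis mixing
  signed_cor <- function(gs) {
    pairs <- combn(length(gs), 2)
    mean(apply(pairs, 2, function(ij)
      cor(gs[[ij[1]]]$coordinates[, 2], gs[[ij[2]]]$coordinates[, 2])))
  }
  expect_gt(signed_cor(al), signed_cor(raw))
  expect_gt(signed_cor(al), 0.5)
})
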