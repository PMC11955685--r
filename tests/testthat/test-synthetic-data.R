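test_that("parcel placement is deterministic, on-sphere, and network-complete", {
  rt <- place_parcels(60, 7, seed = 5)
  rt2 <- place_parcels(60, 7, seed = 5)
  expect_identical(rt, rt2)
  expect_false(identical(rt, place_parcels(60, 7, seed = 6)))

  norms <- sqrt(rt$x^2 + rt$y^2 + rt$z^2)
  expect_true(all(abs(norms - 1) < 1e-8))
  expect_true(all(table(rt$network) >= 2))
  expect_equal(sum(rt$hemisphere == "L"), 30)
  # mirrored geometry
  expect_equal(rt$x[rt$hemisphere == "R"], -rt$x[rt$hemisphere == "L"])
  expect_error(place_parcels(10, 7), "at least")
})

test_that("generated connectomes satisfy the connectome invariants", {
  co <- small_cohort()
  for (w in co$connectomes[c(1, 9)]) {
    expect_silent(validate_connectome(w, co$region_table))
  }
  p <- co$params
  w1 <- generate_connectome(co$region_table, p, "control", seed = 3)
  w2 <- generate_connectome(co$region_table, p, "control", seed = 3)
  expect_identical(w1, w2)
})

test_that("null effect leaves expected weights identical across groups", {
  p <- sim_params(n_regions = 40, n_networks = 4, effect_size = 0, seed = 2)
  rt <- place_parcels(40, 4, seed = 2)
  wc <- generate_connectome(rt, p, "control", seed = 11)
  wp <- generate_connectome(rt, p, "patient", seed = 11)
  expect_identical(wc, wp)
})

test_that("limiting case: no boost, flat decay, no noise gives unit weights", {
  p <- sim_params(n_regions = 20, n_networks = 3, within_network_boost = 1,
                  edge_length_scale = 1e9, noise_sd = 1e-12, seed = 4)
  rt <- place_parcels(20, 3, seed = 4)
  w <- generate_connectome(rt, p, "control", seed = 1)
  off <- w[upper.tri(w)]
  expect_true(all(abs(off - 1) < 1e-4))
  expect_equal(unname(diag(w)), rep(0, 20))
})

test_that("within-network weights exceed between-network weights on average", {
  diffs <- vapply(1:50, function(s) {
    rt <- place_parcels(30, 3, seed = s)
    p <- sim_params(n_regions = 30, n_networks = 3, within_network_boost = 2,
                    seed = s)
    w <- generate_connectome(rt, p, "control", seed = s + 1000)
    same <- outer(rt$network, rt$network, `==`)
    diag(same) <- NA
    mean(w[same & upper.tri(w)]) - mean(w[!same & upper.tri(w)])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("patient effect scales only the designated edges", {
  p <- sim_params(n_regions = 40, n_networks = 4, effect_networks = "Smn",
                  effect_size = 0.4, seed = 9)
  rt <- place_parcels(40, 4, seed = 9)
  wc <- generate_connectome(rt, p, "control", seed = 5)
  wp <- generate_connectome(rt, p, "patient", seed = 5)
  hit <- rt$network == "Smn"
  within <- outer(hit, hit, `&`); diag(within) <- FALSE
  other <- !outer(hit, hit, `&`); diag(other) <- FALSE
  expect_equal(wp[within], wc[within] * 1.4, tolerance = 1e-12)
  expect_equal(wp[other], wc[other], tolerance = 1e-12)

  p2 <- sim_params(n_regions = 40, n_networks = 4, effect_networks = "Smn",
                   effect_size = 0.4, effect_scope = "incident", seed = 9)
  wp2 <- generate_connectome(rt, p2, "patient", seed = 5)
  inc <- outer(hit, hit, `|`); diag(inc) <- FALSE
  expect_equal(wp2[inc], wc[inc] * 1.4, tolerance = 1e-12)
})

test_that("subcortical profiles decay with distance and respect the group effect", {
  co <- small_cohort()
  p <- co$params
  s1 <- generate_subcortical(co$region_table, p$n_subcortical, p, "control", seed = 8)
  s2 <- generate_subcortical(co$region_table, p$n_subcortical, p, "control", seed = 8)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0))
  expect_equal(ncol(s1), sum(co$region_table$is_cortical))

  pe <- sim_params(n_regions = 40, n_networks = 4, n_subcortical = 8,
                   subcortical_effect_structures = 3L,
                   subcortical_effect_size = 0.5, seed = p$seed)
  sp <- generate_subcortical(co$region_table, 8, pe, "patient", seed = 8)
  sc <- generate_subcortical(co$region_table, 8, pe, "control", seed = 8)
  expect_equal(sp[3, ], sc[3, ] * 1.5, tolerance = 1e-12)
  expect_equal(sp[-3, ], sc[-3, ], tolerance = 1e-12)
})

test_that("expression signal genes track the target map better than noise genes", {
  gaps <- vapply(1:20, function(s) {
    rt <- place_parcels(40, 4, seed = s)
    target <- generate_autocorrelated_map(rt, 0.3, seed = 900 + s)
    ex <- generate_expression(rt, target, n_genes = 60, n_signal_genes = 10,
                              seed = 700 + s)
    r <- abs(as.numeric(cor(ex$values, target)))
    mean(r[ex$signal_genes]) - mean(r[-ex$signal_genes])
  }, numeric(1))
  expect_gt(mean(gaps), 0.2)
  expect_true(all(gaps > 0))
})

test_that("expression columns are standardized and reproducible", {
  rt <- place_parcels(40, 4, seed = 3)
  target <- generate_autocorrelated_map(rt, 0.3, seed = 5)
  ex <- generate_expression(rt, target, n_genes = 30, n_signal_genes = 5, seed = 6)
  expect_equal(colMeans(ex$values), setNames(rep(0, 30), colnames(ex$values)),
               tolerance = 1e-12)
  expect_equal(apply(ex$values, 2, sd), setNames(rep(1, 30), colnames(ex$values)),
               tolerance = 1e-12)
  ex2 <- generate_expression(rt, target, n_genes = 30, n_signal_genes = 5, seed = 6)
  expect_identical(ex$values, ex2$values)

  # with no signal genes, correlation with the target is centred on zero
  ex0 <- generate_expression(rt, target, n_genes = 200, n_signal_genes = 0, seed = 8)
  r <- as.numeric(cor(ex0$values, target))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("tiny autocorrelation scale approaches white noise", {
  rt <- place_parcels(60, 4, seed = 12)
  cen <- as.matrix(rt[, c("x", "y", "z")])
  d <- great_circle(cen)
  lag1 <- function(m) {
    nn <- apply(d + diag(Inf, nrow(d)), 1, which.min)
    cor(m, m[nn])
  }
  smooth_map <- generate_autocorrelated_map(rt, 0.5, seed = 31)
  rough_map <- generate_autocorrelated_map(rt, 0.01, seed = 31)
  expect_gt(lag1(smooth_map), 0.4)
  expect_lt(abs(lag1(rough_map)), 0.25)
})

test_that("a simulated cohort writes a loadable on-disk layout", {
  dir <- withr::local_tempdir()
  p <- sim_params(n_regions = 20, n_networks = 3, n_subjects_per_group = 3,
                  n_genes = 15, n_signal_genes = 3, n_subcortical = 4, seed = 77)
  co <- simulate_cohort(p, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  loaded <- conngrad:::load_cohort(dir)
  expect_equal(loaded$connectomes[[1]], unname(co$connectomes[[1]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(loaded$manifest$subject_id, co$manifest$subject_id)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$effect_networks, "Smn")
})
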