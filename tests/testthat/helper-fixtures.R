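# Shared fixtures, built in code. The small cohort is memoized per session
# because several test files exercise the same embedding/alignment path.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    p <- sim_params(n_regions = 40L, n_networks = 4L, n_subjects_per_group = 8L,
                    n_genes = 60L, n_signal_genes = 6L, n_subcortical = 8L,
                    seed = 421L)
    .fixture_env$cohort <- simulate_cohort(p)
  }
  .fixture_env$cohort
}

# deterministic tiny region table on exact coordinates, no RNG
tiny_region_table <- function() {
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  data.frame(region_id = 0:5, name = paste0("r", 0:5),
             hemisphere = rep(c("L", "R"), 3),
             network = rep(c("Vis", "Smn", "Dmn"), each = 2),
             volume = 1, x = ax[, 1], y = ax[, 2], z = ax[, 3],
             is_cortical = TRUE, stringsAsFactors = FALSE)
}

# random symmetric non-negative connectome with zero diagonal
random_connectome <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  w <- w + t(w)
  w
}

# random connected affinity-like matrix: symmetric, non-negative, unit diag
random_affinity <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n, 0.01, 1), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

random_orthogonal <- function(k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(k * k), k)))
}
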