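make_design <- function(n1, n2, seed = 1, covariates = TRUE) {
  set.seed(seed)
  mf <- data.frame(subject_id = sprintf("s%02d", seq_len(n1 + n2)),
                   group = rep(c("control", "patient"), c(n1, n2)),
                   age = runif(n1 + n2, 50, 75),
                   sex = sample(c("female", "male"), n1 + n2, TRUE))
  list(mf = mf, X = design_matrix(mf, covariates = covariates))
}

test_that("design matrix encodes group and covariates with full rank", {
  d <- make_design(5, 6)
  expect_identical(colnames(d$X), c("intercept", "group", "age", "sex"))
  expect_equal(d$X[, "group"], as.numeric(d$mf$group == "patient"))
  expect_equal(sort(unique(d$X[, "sex"])), c(0, 1))
  mf_const <- d$mf; mf_const$sex <- "male"
  expect_error(design_matrix(mf_const), "rank")
})

test_that("Hotelling reduces to the classical two-sample T2 without covariates", {
  for (s in 1:20) {
    set.seed(s)
    n1 <- 12; n2 <- 15; k <- 3
    Y <- rbind(matrix(rnorm(n1 * k), n1), matrix(rnorm(n2 * k, mean = 0.3), n2))
    X <- cbind(intercept = 1, group = rep(c(0, 1), c(n1, n2)))
    got <- hotelling_test(Y, X)

    # textbook formula oracle
    d <- colMeans(Y[X[, 2] == 1, ]) - colMeans(Y[X[, 2] == 0, ])
    s1 <- cov(Y[X[, 2] == 0, ]); s2 <- cov(Y[X[, 2] == 1, ])
    sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    t2 <- (n1 * n2 / (n1 + n2)) * as.numeric(t(d) %*% solve(sp) %*% d)
    expect_equal(got$T2, t2, tolerance = 1e-8)

    f <- t2 * (n1 + n2 - k - 1) / (k * (n1 + n2 - 2))
    expect_equal(got$F, f, tolerance = 1e-8)
    expect_equal(got$p, pf(f, k, n1 + n2 - k - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("Hotelling with k = 1 equals the squared univariate t", {
  d <- make_design(10, 12, seed = 3)
  set.seed(4)
  y <- rnorm(22) + 0.5 * d$X[, "group"] + 0.02 * d$X[, "age"]
  h <- hotelling_test(matrix(y, ncol = 1), d$X)
  u <- univariate_test(y, d$X)
  expect_equal(h$F, u$t^2, tolerance = 1e-10)
  expect_equal(h$p, u$p, tolerance = 1e-10)
})

test_that("Hotelling degenerate inputs behave as specified", {
  d <- make_design(8, 8, seed = 5)
  set.seed(6)
  base <- matrix(rnorm(16 * 2), 16)
  h <- hotelling_test(base, d$X)
  expect_gt(h$p, 0)

  # force identical group means: zero contrast, T2 = 0, p = 1
  g <- d$X[, "group"]
  Yn <- base
  Yn[g == 1, ] <- sweep(Yn[g == 1, ], 2,
                        colMeans(base[g == 1, ]) - colMeans(base[g == 0, ]))
  h0 <- hotelling_test(Yn, d$X[, c("intercept", "group")])
  expect_lt(h0$T2, 1e-12)
  expect_equal(h0$p, 1, tolerance = 1e-8)

  expect_error(hotelling_test(matrix(rnorm(12), 4, 3), d$X[1:4, ]), "few subjects")
})

test_that("Hotelling agrees with anova.mlm on data with covariates", {
  d <- make_design(15, 15, seed = 8)
  set.seed(9)
  Y <- matrix(rnorm(30 * 3), 30) + outer(d$X[, "group"], c(0.5, 0, -0.3))
  got <- hotelling_test(Y, d$X)
  # group last: the sequential test then adjusts for both covariates
  fit <- stats::lm(Y ~ age + sex + group,
                   data = data.frame(group = d$X[, "group"], age = d$X[, "age"],
                                     sex = d$X[, "sex"]))
  aov_tab <- stats::anova(fit, test = "Hotelling-Lawley")
  hl <- aov_tab["group", "Hotelling-Lawley"]
  # Hotelling-Lawley trace for a 1-df contrast is T2 / (n - rank)
  expect_equal(got$T2, hl * (30 - 4), tolerance = 1e-8)
  expect_equal(got$p, aov_tab["group", "Pr(>F)"], tolerance = 1e-8)
})

test_that("univariate test matches normal equations and flips sign with labels", {
  # 6-subject fixture solved by hand via normal equations
  X <- cbind(intercept = 1, group = c(0, 0, 0, 1, 1, 1))
  y <- c(1, 2, 3, 4, 6, 8)
  got <- univariate_test(y, X)
  # group means 2 and 6, pooled var = (2 + 8)/4 = 2.5, se = sqrt(2.5*2/3)
  expect_equal(got$estimate, 4, tolerance = 1e-10)
  expect_equal(got$t, 4 / sqrt(2.5 * 2 / 3), tolerance = 1e-10)
  lmfit <- summary(lm(y ~ X[, "group"]))$coefficients
  expect_equal(got$t, lmfit[2, "t value"], tolerance = 1e-10)
  expect_equal(got$p, lmfit[2, "Pr(>|t|)"], tolerance = 1e-10)

  Xs <- cbind(intercept = 1, group = 1 - X[, "group"])
  expect_equal(univariate_test(y, Xs)$t, -got$t, tolerance = 1e-12)
  expect_error(univariate_test(rep(2, 6), X), "zero variance")
})

test_that("FDR adjustment reproduces the step-up procedure", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.03, 0.8, 0.04)
  q <- fdr_bh(p)
  expect_true(all(q >= p))
  shuf <- c(3, 1, 5, 2, 4)
  expect_equal(fdr_bh(p[shuf]), q[shuf])
})

test_that("post-hoc Bonferroni threshold sits exactly at alpha over three", {
  expect_true(posthoc_bonferroni(0.0165))
  expect_false(posthoc_bonferroni(0.0167))
  expect_true(posthoc_bonferroni(0))
})

test_that("network averaging is the plain mean over member regions", {
  rt <- tiny_region_table()
  g <- matrix(c(1, 3, 2, 2, 5, -1), ncol = 1)
  avg <- network_average(g, rt)
  expect_equal(unname(avg["Vis", 1]), 2)   # regions 0,1 scores (1,3)
  expect_equal(unname(avg["Smn", 1]), 2)
  expect_equal(unname(avg["Dmn", 1]), 2)

  gc <- matrix(7, 6, 2)
  expect_true(all(network_average(gc, rt) == 7))

  # single-region network
  rt1 <- rt; rt1$network <- c("Vis", "Smn", "Smn", "Smn", "Smn", "Smn")
  expect_equal(unname(network_average(g, rt1)["Vis", 1]), 1)
})

test_that("stat maps carry coherent q-values and significance flags", {
  d <- make_design(10, 10, seed = 21)
  set.seed(22)
  scores <- array(rnorm(20 * 6 * 3), c(20, 6, 3))
  scores[, 2, ] <- scores[, 2, ] + outer(d$X[, "group"], c(2, 2, 2))
  sm <- compare_multivariate(scores, d$X, units = letters[1:6], family = "test")
  expect_true(all(sm$q >= sm$p))
  expect_identical(sm$significant, sm$q < 0.05)
  expect_equal(sm$unit[which.max(sm$statistic)], "b")
  expect_identical(attr(sm, "family"), "test")

  smu <- compare_univariate(scores[, , 1], d$X, units = letters[1:6],
                            correction = "bonferroni", n_tests = 3)
  expect_identical(smu$significant, smu$p < 0.05 / 3)
})

test_that("term-map decoding ranks by correlation and drops constant maps", {
  stat <- c(2, 0.5, -1, 3, 1)
  sig <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  thr <- ifelse(sig, stat, 0)
  tm <- rbind(self = thr,
              anti = -thr,
              mix = c(1, 1, 0, 2, 0),
              flat = rep(3, 5))
  expect_warning(out <- decode_term_maps(stat, sig, tm, top_n = 3), "constant")
  expect_equal(out$term[1], "self")
  expect_equal(out$correlation[1], 1)
  expect_equal(nrow(out), 3)
  expect_equal(out$correlation[out$term == "mix"],
               cor(thr, c(1, 1, 0, 2, 0)))
  expect_false("flat" %in% out$term)
  expect_error(decode_term_maps(stat, rep(FALSE, 5), tm), "constant")
})

test_that("permutation p-values agree with the F reference on Gaussian data", {
  d <- make_design(12, 12, seed = 41)
  set.seed(42)
  Y <- matrix(rnorm(24 * 3), 24) + outer(d$X[, "group"], c(0.8, 0, 0.4))
  h <- hotelling_test(Y, d$X, n_perm = 400, seed = 9)
  expect_gte(h$p_perm, 1 / 401)
  expect_lt(abs(h$p_perm - h$p), 0.08)
})
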