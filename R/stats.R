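#' Build the group-comparison design matrix
#'
#' Columns: intercept, group indicator (patient = 1), age, sex indicator
#' (female = 0, male = 1). Age and sex are the paper-style nuisance
#' covariates; they can be dropped for covariate-free comparisons.
#'
#' @param manifest Cohort manifest data frame (see [read_manifest()]).
#' @param covariates Include age and sex columns (default TRUE).
#' @return Numeric matrix with named columns, checked for full column rank.
#' @export
design_matrix <- function(manifest, covariates = TRUE) {
  validate_manifest(manifest)
  x <- cbind(intercept = 1,
             group = as.numeric(manifest$group == "patient"))
  if (covariates) {
    x <- cbind(x, age = manifest$age,
               sex = as.numeric(manifest$sex == "male"))
  }
  if (qr(x)$rank < ncol(x)) {
    stop("design matrix is rank deficient (constant covariate?)", call. = FALSE)
  }
  x
}

#' Hotelling's T-squared test of a group effect in a multivariate GLM
#'
#' Fits `Y = X B + E` by least squares and tests the contrast on the group
#' column: `T2 = d' V^-1 d` with `d = c B` and
#' `V = (c (X'X)^-1 c') * Sigma`, `Sigma = E'E / (n - rank(X))`. The F
#' transform `F = T2 (n - p - k + 1) / (k (n - p))` is referred to an
#' `F(k, n - p - k + 1)` distribution — exact under Gaussian errors. With
#' two groups and no covariates this reduces to the classical two-sample
#' Hotelling T-squared; with k = 1 it reduces to the squared t statistic.
#'
#' @param Y Numeric matrix, subjects x k responses.
#' @param X Design matrix from [design_matrix()].
#' @param contrast Column name or index of the tested coefficient
#'   (default `"group"`).
#' @param n_perm When > 0, additionally compute a permutation p-value
#'   (`p_perm`) by refitting under `n_perm` random permutations of the
#'   response rows, with the +1 correction — a robustness check when the
#'   Gaussian F reference is in doubt.
#' @param seed Seed for the permutation draw.
#' @return List with `T2`, `F`, `df`, `p` (and `p_perm` when requested).
#' @export
hotelling_test <- function(Y, X, contrast = "group", n_perm = 0L, seed = 1L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  p <- ncol(X)
  if (nrow(X) != n) stop("Y and X must have the same number of rows", call. = FALSE)
  if (n <= p + k) {
    stop("too few subjects for a ", k, "-variate test with ", p,
         " design columns; need n > rank(X) + k", call. = FALSE)
  }
  ci <- if (is.character(contrast)) match(contrast, colnames(X)) else contrast
  if (is.na(ci)) stop("contrast column not found in design", call. = FALSE)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- xtx_inv %*% crossprod(X, Y)
  E <- Y - X %*% B
  sigma <- crossprod(E) / (n - p)
  d <- B[ci, , drop = FALSE]
  if (max(abs(d)) < 1e-12 * (1 + max(abs(Y)))) {
    # exactly null contrast (e.g. responses identical across subjects)
    return(list(T2 = 0, F = 0, df = c(k, n - p - k + 1), p = 1))
  }
  v <- xtx_inv[ci, ci] * sigma
  vi <- tryCatch(chol2inv(chol(v)), error = function(e) {
    stop("singular error covariance; use more subjects or fewer responses",
         call. = FALSE)
  })
  t2 <- as.numeric(d %*% vi %*% t(d))
  fstat <- t2 * (n - p - k + 1) / (k * (n - p))
  pval <- stats::pf(fstat, k, n - p - k + 1, lower.tail = FALSE)
  out <- list(T2 = t2, F = fstat, df = c(k, n - p - k + 1), p = pval)
  if (n_perm > 0L) {
    set.seed(seed)
    t2_null <- vapply(seq_len(n_perm), function(b) {
      Yb <- Y[sample.int(n), , drop = FALSE]
      Bb <- xtx_inv %*% crossprod(X, Yb)
      Eb <- Yb - X %*% Bb
      vb <- xtx_inv[ci, ci] * crossprod(Eb) / (n - p)
      db <- Bb[ci, , drop = FALSE]
      as.numeric(db %*% chol2inv(chol(vb)) %*% t(db))
    }, numeric(1L))
    out$p_perm <- (1 + sum(t2_null >= t2)) / (1 + n_perm)
  }
  out
}

#' Univariate group test via ordinary least squares
#'
#' @param y Response vector (subjects).
#' @param X Design matrix.
#' @param contrast Tested coefficient (default `"group"`).
#' @return List with `t`, `df`, `p`, `estimate`.
#' @export
univariate_test <- function(y, X, contrast = "group") {
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("y and X must have matching length", call. = FALSE)
  if (stats::sd(y) == 0) stop("response has zero variance; t undefined", call. = FALSE)
  ci <- if (is.character(contrast)) match(contrast, colnames(X)) else contrast
  xtx_inv <- chol2inv(chol(crossprod(X)))
  b <- as.numeric(xtx_inv %*% crossprod(X, y))
  e <- y - as.numeric(X %*% b)
  s2 <- sum(e^2) / (n - p)
  se <- sqrt(s2 * xtx_inv[ci, ci])
  tstat <- b[ci] / se
  list(t = tstat, df = n - p,
       p = 2 * stats::pt(abs(tstat), n - p, lower.tail = FALSE),
       estimate = b[ci])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()]).
#'
#' @param p Vector of p-values.
#' @return Vector of q-values, same order as the input.
#' @export
fdr_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Post-hoc Bonferroni flags across gradients
#'
#' @param p Vector of per-gradient p-values.
#' @param n_gradients Correction family size (default 3).
#' @param alpha Nominal level (default 0.05).
#' @return Logical vector: `p < alpha / n_gradients`.
#' @export
posthoc_bonferroni <- function(p, n_gradients = 3L, alpha = 0.05) {
  p < alpha / n_gradients
}

#' Average gradient scores within functional networks
#'
#' @param coordinates `gradient_set` or regions x k matrix of gradient
#'   scores over cortical regions.
#' @param region_table Region table; cortical rows define the networks.
#' @return networks x k matrix of network-mean scores, rows named by
#'   network label in canonical order.
#' @export
network_average <- function(coordinates, region_table) {
  g <- if (inherits(coordinates, "gradient_set")) coordinates$coordinates else as.matrix(coordinates)
  ctx <- region_table[region_table$is_cortical, , drop = FALSE]
  if (nrow(g) != nrow(ctx)) stop("gradient rows must match cortical regions", call. = FALSE)
  nets <- intersect(cortical_networks, unique(ctx$network))
  out <- do.call(rbind, lapply(nets, function(nw) {
    colMeans(g[ctx$network == nw, , drop = FALSE])
  }))
  rownames(out) <- nets
  out
}

stat_map <- function(unit, statistic, p, family, alpha = 0.05,
                     correction = c("fdr", "bonferroni"), n_tests = length(p)) {
  correction <- match.arg(correction)
  if (correction == "fdr") {
    q <- fdr_bh(p)
    sig <- q < alpha
  } else {
    q <- pmin(p * n_tests, 1)
    sig <- posthoc_bonferroni(p, n_tests, alpha)
  }
  out <- data.frame(unit = unit, statistic = statistic, p = p, q = q,
                    significant = sig, stringsAsFactors = FALSE)
  attr(out, "family") <- family
  attr(out, "correction") <- correction
  out
}

#' Multivariate group comparison across units
#'
#' Runs [hotelling_test()] once per unit (region, network, or subcortical
#' structure) on the subjects x units x k score array and corrects the
#' family with Benjamini-Hochberg FDR.
#'
#' @param scores Array `n_subjects x n_units x k`.
#' @param X Design matrix.
#' @param units Unit labels.
#' @param family Label recorded as the correction family.
#' @param alpha Significance level (default 0.05).
#' @return `stat_map` data frame (unit, statistic = T2, p, q, significant)
#'   with the family stored as an attribute.
#' @export
compare_multivariate <- function(scores, X, units = NULL,
                                 family = "units", alpha = 0.05) {
  stopifnot(length(dim(scores)) == 3L)
  nu <- dim(scores)[[2L]]
  if (is.null(units)) units <- dimnames(scores)[[2L]]
  if (is.null(units)) units <- as.character(seq_len(nu) - 1L)
  res <- vapply(seq_len(nu), function(u) {
    h <- hotelling_test(scores[, u, , drop = TRUE], X)
    c(h$T2, h$p)
  }, numeric(2L))
  stat_map(units, res[1L, ], res[2L, ], family = family, alpha = alpha)
}

#' Univariate group comparison across units for one gradient
#'
#' @param scores Matrix `n_subjects x n_units` of one gradient's scores.
#' @param X Design matrix.
#' @param units Unit labels.
#' @param family Correction-family label.
#' @param correction `"fdr"` (default) or `"bonferroni"` (post-hoc maps).
#' @param n_tests Family size for Bonferroni (default 3 gradients).
#' @param alpha Significance level.
#' @return `stat_map` data frame with Student's t statistics.
#' @export
compare_univariate <- function(scores, X, units = NULL, family = "units",
                               correction = "fdr", n_tests = 3L, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (is.null(units)) units <- colnames(scores)
  if (is.null(units)) units <- as.character(seq_len(ncol(scores)) - 1L)
  res <- vapply(seq_len(ncol(scores)), function(u) {
    y <- scores[, u]
    if (stats::sd(y) == 0) return(c(0, 1))  # constant unit: no group effect
    h <- univariate_test(y, X)
    c(h$t, h$p)
  }, numeric(2L))
  stat_map(units, res[1L, ], res[2L, ], family = family, alpha = alpha,
           correction = correction, n_tests = n_tests)
}

#' Correlate a thresholded statistic map with term maps
#'
#' Functional decoding against user-supplied meta-analytic term maps:
#' non-significant regions are zeroed, each term map is Pearson-correlated
#' with the thresholded map, and the top terms are returned in descending
#' correlation order. Constant term maps (undefined correlation) are
#' excluded with a warning.
#'
#' @param statistic Region-level statistic vector.
#' @param significant Logical vector; regions failing it are set to 0.
#' @param term_maps Matrix terms x regions with row names as term labels.
#' @param top_n Number of terms to keep (default 15).
#' @return Data frame (term, correlation), sorted descending.
#' @export
decode_term_maps <- function(statistic, significant, term_maps, top_n = 15L) {
  stopifnot(length(statistic) == length(significant),
            ncol(term_maps) == length(statistic))
  thr <- ifelse(significant, statistic, 0)
  if (stats::sd(thr) == 0) {
    stop("thresholded map is constant; no significant regions to decode", call. = FALSE)
  }
  keep <- apply(term_maps, 1L, function(m) stats::sd(m) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant term map(s) excluded from decoding")
  }
  tm <- term_maps[keep, , drop = FALSE]
  r <- as.numeric(stats::cor(thr, t(tm)))
  ord <- order(r, decreasing = TRUE)
  out <- data.frame(term = rownames(tm)[ord], correlation = r[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, top_n)
}
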