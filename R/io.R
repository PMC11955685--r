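#' Read a delimited numeric matrix
#'
#' Reads a tab- or comma-delimited numeric table, optionally headed by a row
#' of region (or gene) names. Any non-numeric, missing or non-finite cell is
#' an error naming its row and column, so malformed connectomes fail loudly
#' rather than propagating NaNs into the embedding.
#'
#' @param path File path to a delimited text matrix.
#' @param expected_shape Optional integer pair `c(nrow, ncol)`; a mismatch is
#'   an error.
#' @return A numeric matrix. Column names are taken from the header row when
#'   one is present.
#' @export
read_matrix <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty matrix file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)

  first <- suppressWarnings(as.numeric(rows[[1L]]))
  has_header <- anyNA(first)
  header <- NULL
  if (has_header) {
    header <- trimws(rows[[1L]])
    rows <- rows[-1L]
    if (length(rows) == 0L) stop("matrix file has a header but no data: ", path, call. = FALSE)
  }

  ncol_ <- length(rows[[1L]])
  out <- matrix(NA_real_, nrow = length(rows), ncol = ncol_)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol_) {
      stop(sprintf("ragged matrix in %s: row %d has %d fields, expected %d",
                   path, i, length(rows[[i]]), ncol_), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column %d of %s",
                   trimws(rows[[i]][j]), i, j, path), call. = FALSE)
    }
    out[i, ] <- vals
  }
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d of %s",
                 bad[[1L]], bad[[2L]], path), call. = FALSE)
  }
  if (!is.null(header)) colnames(out) <- header
  if (!is.null(expected_shape)) {
    if (nrow(out) != expected_shape[[1L]] || ncol(out) != expected_shape[[2L]]) {
      stop(sprintf("matrix in %s has shape %d x %d, expected %d x %d",
                   path, nrow(out), ncol(out),
                   expected_shape[[1L]], expected_shape[[2L]]), call. = FALSE)
    }
  }
  out
}

#' Write a numeric matrix as tab-delimited text
#'
#' Values are written with 17 significant digits so that a
#' write/read round trip is lossless well below 1e-12.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param col_names Write a header row of column names when present.
#' @export
write_matrix <- function(m, path, col_names = !is.null(colnames(m))) {
  stopifnot(is.matrix(m), is.numeric(m))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (isTRUE(col_names) && !is.null(colnames(m))) {
    writeLines(paste(colnames(m), collapse = "\t"), con)
  }
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Scale connectivity by regional volumes
#'
#' Divides each edge weight by the combined volume of its two endpoint
#' regions, removing the bias of larger parcels accumulating more
#' streamlines. The combination rule is the sum of the two volumes by
#' default (`rule = "sum"`); division by the product is available.
#'
#' @param weights Square numeric matrix.
#' @param volumes Positive numeric vector, one volume per region.
#' @param rule `"sum"` (default) or `"product"`.
#' @return Matrix of the same shape with entry `(i, j)` equal to
#'   `weights[i, j] / (volumes[i] + volumes[j])` (or the product rule).
#' @export
volume_scale <- function(weights, volumes, rule = c("sum", "product")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (length(volumes) != nrow(weights)) {
    stop("length(volumes) must equal the matrix dimension", call. = FALSE)
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("all volumes must be positive and finite", call. = FALSE)
  }
  denom <- if (rule == "sum") outer(volumes, volumes, `+`) else outer(volumes, volumes)
  weights / denom
}

#' Threshold a connectome by sparsity level
#'
#' Sets the given fraction of smallest off-diagonal entries (counted over
#' unordered region pairs) to zero, preserving symmetry. Ties at the
#' threshold are resolved by keeping the pairs with lower (row, column)
#' indices, so output is deterministic.
#'
#' @param weights Symmetric non-negative matrix.
#' @param sparsity Fraction in `[0, 1)` of pairs to zero out; 0 is a no-op.
#' @return Sparsified matrix; the number of surviving pairs is
#'   `round((1 - sparsity) * n_pairs)`.
#' @export
sparsify <- function(weights, sparsity) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      is.na(sparsity) || sparsity < 0 || sparsity >= 1) {
    stop("sparsity must be a single value in [0, 1)", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("weights must be symmetric", call. = FALSE)
  }
  if (sparsity == 0) return(weights)
  n <- nrow(weights)
  ut <- which(upper.tri(weights))
  vals <- weights[ut]
  n_pairs <- length(ut)
  n_keep <- round((1 - sparsity) * n_pairs)
  n_zero <- n_pairs - n_keep
  if (n_zero == 0L) return(weights)
  # ascending value; within ties, higher-index pairs are dropped first so
  # the survivors are the lower (row, col) pairs
  ord <- order(vals, -seq_along(vals))
  drop_idx <- ut[ord[seq_len(n_zero)]]
  out <- weights
  out[drop_idx] <- 0
  rc <- arrayInd(drop_idx, dim(weights))
  out[cbind(rc[, 2L], rc[, 1L])] <- 0
  out
}

cortical_networks <- c("Vis", "Smn", "Dan", "Van", "Lim", "Fpn", "Dmn")

#' Validate a region metadata table
#'
#' Checks the invariants of the parcellation table: contiguous 0-based
#' region ids, unit-norm centroids for cortical rows, positive volumes and
#' L/R hemisphere labels.
#'
#' @param rt Data frame with columns `region_id`, `name`, `hemisphere`,
#'   `network`, `volume`, `x`, `y`, `z`, `is_cortical`.
#' @return The validated table, invisibly usable downstream.
#' @export
validate_region_table <- function(rt) {
  needed <- c("region_id", "name", "hemisphere", "network", "volume",
              "x", "y", "z", "is_cortical")
  missing_cols <- setdiff(needed, names(rt))
  if (length(missing_cols)) {
    stop("region table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(rt)
  rt$region_id <- as.integer(rt$region_id)
  if (anyDuplicated(rt$region_id) || !identical(sort(rt$region_id), 0:(n - 1L))) {
    stop("region_id must be unique and contiguous from 0", call. = FALSE)
  }
  if (!all(rt$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  }
  if (any(!is.finite(rt$volume)) || any(rt$volume <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  cn <- sqrt(rt$x^2 + rt$y^2 + rt$z^2)
  if (any(abs(cn[rt$is_cortical] - 1) > 1e-8)) {
    stop("cortical centroids must lie on the unit sphere", call. = FALSE)
  }
  rt
}

#' @rdname validate_region_table
#' @param path TSV path.
#' @export
read_region_table <- function(path) {
  rt <- utils::read.delim(path, stringsAsFactors = FALSE)
  rt$region_id <- as.integer(rt$region_id)
  rt$is_cortical <- as.logical(rt$is_cortical)
  validate_region_table(rt)
}

#' @rdname validate_region_table
#' @param rt Region table.
#' @export
write_region_table <- function(rt, path) {
  utils::write.table(validate_region_table(rt), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' The manifest lists one subject per row with columns `subject_id`,
#' `group` (control/patient), `age`, `sex` (female/male) and, when the
#' cohort lives on disk, `connectome_path` and `subcortical_path`.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_manifest(mf)
}

#' @rdname read_manifest
#' @param mf Manifest data frame.
#' @export
validate_manifest <- function(mf) {
  needed <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(needed, names(mf))
  if (length(missing_cols)) {
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(mf$subject_id)) stop("subject_id must be unique", call. = FALSE)
  if (!all(mf$group %in% c("control", "patient"))) {
    stop("group must be 'control' or 'patient'", call. = FALSE)
  }
  if (any(table(factor(mf$group, c("control", "patient"))) < 2L)) {
    stop("both groups must have at least two subjects", call. = FALSE)
  }
  if (!all(mf$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (any(!is.finite(mf$age)) || any(mf$age <= 0)) {
    stop("age must be positive", call. = FALSE)
  }
  mf
}

#' Validate a connectome matrix against its region table
#'
#' @param weights Square matrix over cortical regions.
#' @param region_table Region table whose cortical rows define order/size.
#' @return The weights matrix.
#' @export
validate_connectome <- function(weights, region_table = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (any(!is.finite(weights))) stop("connectome contains non-finite values", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("connectome must be symmetric to 1e-10", call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("connectome diagonal must be zero", call. = FALSE)
  if (any(weights < 0)) stop("connectome must be non-negative", call. = FALSE)
  if (!is.null(region_table)) {
    nc <- sum(region_table$is_cortical)
    if (nrow(weights) != nc) {
      stop(sprintf("connectome has %d regions, region table has %d cortical rows",
                   nrow(weights), nc), call. = FALSE)
    }
  }
  weights
}

#' Write a statistic map as a TSV result table
#'
#' @param sm Data frame with columns `unit`, `statistic`, `p`, `q`,
#'   `significant`.
#' @param path Output TSV path.
#' @export
write_stat_map <- function(sm, path) {
  stopifnot(all(c("unit", "statistic", "p", "q", "significant") %in% names(sm)))
  utils::write.table(sm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
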