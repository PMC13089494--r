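# Internal helpers shared across modules.

#' Validate a cells x genes count matrix
#'
#' Checks the count-matrix contract: non-negative entries and unique cell and
#' gene identifiers in the dimnames. Returns the matrix invisibly so the check
#' can be chained.
#'
#' @param m A matrix or [Matrix::Matrix] with cells as rows and genes as
#'   columns; `rownames` are cell ids, `colnames` gene ids.
#' @return `m`, invisibly.
#' @export
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    rlang::abort("count matrix must carry cell ids (rownames) and gene ids (colnames)")
  }
  if (anyDuplicated(rownames(m)) > 0) rlang::abort("duplicate cell ids")
  if (anyDuplicated(colnames(m)) > 0) rlang::abort("duplicate gene ids")
  if (min_value(m) < 0) rlang::abort("count matrix has negative entries")
  invisible(m)
}

min_value <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    x <- methods::slot(methods::as(m, "CsparseMatrix"), "x")
    if (length(x) == 0) 0 else min(0, min(x))
  } else {
    if (length(m) == 0) 0 else min(m)
  }
}

# Row sums / detected-gene counts that work for both dense and sparse input.
cell_totals <- function(m) as.numeric(Matrix::rowSums(m))
cell_n_detected <- function(m) as.numeric(Matrix::rowSums(m > 0))
gene_n_detected <- function(m) as.numeric(Matrix::colSums(m > 0))

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Exact k-nearest-neighbour search
#'
#' Chunked exact Euclidean kNN between two point sets, computed with dense
#' matrix algebra. Suited to the desk-scale problem sizes the package targets
#' (up to a few tens of thousands of points in tens of dimensions).
#'
#' @param query Numeric matrix, points x dims.
#' @param ref Numeric matrix, points x dims (same dims).
#' @param k Number of neighbours to return (`k <= nrow(ref)`).
#' @param chunk Rows of `query` processed per block.
#' @return List with `idx` (query x k reference row indices, nearest first)
#'   and `dist` (matching Euclidean distances).
#' @export
knn_search <- function(query, ref, k, chunk = 512L) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  if (ncol(query) != ncol(ref)) rlang::abort("query/ref dimension mismatch")
  if (k > nrow(ref)) rlang::abort("k exceeds the number of reference points")
  nq <- nrow(query)
  rn2 <- rowSums(ref^2)
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  starts <- seq(1L, nq, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    nr <- ncol(d2)
    for (i in seq_len(nrow(d2))) {
      row <- d2[i, ]
      if (k < nr) {
        # partial selection before the O(k log k) ordering
        thr <- sort.int(row, partial = k)[k]
        cand <- which(row <= thr)
        ord <- cand[order(row[cand])][seq_len(k)]
      } else {
        ord <- order(row)
      }
      idx[s + i - 1L, ] <- ord
      dst[s + i - 1L, ] <- sqrt(row[ord])
    }
  }
  list(idx = idx, dist = dst)
}

# Draw labels from a named probability vector.
sample_labels <- function(n, probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-6)
  sample(names(probs), size = n, replace = TRUE, prob = probs)
}

# Truncated normal by rejection with an interval fallback.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0
  while (length(bad) > 0 && tries < 50) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1
  }
  if (length(bad) > 0) out[bad] <- stats::runif(length(bad), lower, upper)
  out
}

# Dirichlet draws (rows on the simplex).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}
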