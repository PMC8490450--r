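#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Row-wise Welch two-sample t-test
#'
#' Vectorized Welch (unequal-variance) t-statistics, two-sided p-values and
#' log2 fold changes for every row of a matrix, comparing two column groups.
#' Matches `stats::t.test(var.equal = FALSE)` row by row.
#'
#' @param m numeric matrix (features x samples).
#' @param idx_a,idx_b column indices (or names) of the two groups; each must
#'   select at least two columns.
#' @return data.frame with `mean_a`, `mean_b`, `log2_fold_change`
#'   (`mean_a - mean_b`), `t_statistic`, `df`, `p_value`, one row per row
#'   of `m`.
#' @keywords internal
row_welch <- function(m, idx_a, idx_b) {
  a <- m[, idx_a, drop = FALSE]
  b <- m[, idx_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 samples (got ", na, " and ", nb, ")")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  data.frame(row.names = rownames(m),
             mean_a = ma, mean_b = mb, log2_fold_change = ma - mb,
             t_statistic = tstat, df = df, p_value = p)
}

#' Cosine similarity between nonnegative vectors
#'
#' `dot(u, v) / (||u|| ||v||)`. For nonnegative inputs the result lies in
#' \[0, 1\].
#'
#' @param u,v numeric vectors of equal length; neither may be all zero.
#' @return scalar cosine similarity.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0)) # 1/sqrt(2)
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

# Pairwise cosine similarity between columns of two matrices (rows aligned).
cosine_matrix <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  crossprod(An, Bn)
}

# Stop unless x is a numeric matrix with unique, non-missing dimnames.
check_named_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column names")
  if (anyDuplicated(rownames(x))) stop("duplicate row identifiers in ", what)
  if (anyDuplicated(colnames(x))) stop("duplicate column identifiers in ", what)
  if (!all(is.finite(x))) stop("non-finite values in ", what)
  invisible(x)
}

# Gamma-based Dirichlet draw (one vector).
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}
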