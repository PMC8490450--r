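# Class-level copy-number landscape comparison: per-feature class means,
# pairwise Welch tests, segment-wise Fisher tests under BH control, and
# expression-copy-number association.

cn_classes <- function(cn, classes) align_labels(classes, colnames(cn$values))

# Order features by genomic coordinate when coordinates exist.
feature_order <- function(features) {
  if (all(c("chrom", "start") %in% colnames(features))) {
    chrom_num <- suppressWarnings(as.integer(sub("^chr", "", features$chrom)))
    order(ifelse(is.na(chrom_num), .Machine$integer.max, chrom_num),
          features$chrom, features$start)
  } else seq_len(nrow(features))
}

#' Per-class mean copy number and pairwise difference tracks
#'
#' Means of the continuous values per feature within each class, plus the
#' difference track for every ordered class pair, output ordered by genomic
#' coordinate for plotting. Difference tracks are antisymmetric under
#' swapping the pair.
#'
#' @param cn `cn_table`.
#' @param classes class labels (named by sample or positional).
#' @return list with `means` (features + one column per class) and
#'   `differences` (features + one column per class pair `a_minus_b`).
#' @export
class_mean_cn <- function(cn, classes) {
  classes <- cn_classes(cn, classes)
  cls <- sort(unique(classes))
  if (any(!cls %in% classes)) stop("empty class")
  means <- vapply(cls, function(cl)
    rowMeans(cn$values[, classes == cl, drop = FALSE]), numeric(nrow(cn$values)))
  pairs <- utils::combn(cls, 2L, simplify = FALSE)
  diffs <- vapply(pairs, function(p) means[, p[1L]] - means[, p[2L]],
                  numeric(nrow(means)))
  colnames(diffs) <- vapply(pairs, function(p)
    paste0(p[1L], "_minus_", p[2L]), character(1))
  ord <- feature_order(cn$features)
  list(means = cbind(cn$features, means)[ord, , drop = FALSE],
       differences = cbind(cn$features, diffs)[ord, , drop = FALSE])
}

#' Per-feature Welch t-test between two classes (continuous copy number)
#'
#' @param cn `cn_table`.
#' @param classes class labels.
#' @param class_a,class_b the two classes to compare (>= 2 samples each).
#' @param alpha significance flag threshold (default 0.05).
#' @return data.frame per feature: coordinates, class means, `t_statistic`,
#'   `p_value`, `significant`.
#' @export
pairwise_cn_ttest <- function(cn, classes, class_a, class_b, alpha = 0.05) {
  classes <- cn_classes(cn, classes)
  ia <- which(classes == class_a); ib <- which(classes == class_b)
  res <- row_welch(cn$values, ia, ib)
  out <- cbind(cn$features,
               data.frame(mean_a = res$mean_a, mean_b = res$mean_b,
                          t_statistic = res$t_statistic, p_value = res$p_value,
                          significant = res$p_value < alpha))
  rownames(out) <- NULL
  out[feature_order(cn$features), , drop = FALSE]
}

#' Segment-wise class-specific alteration test (Fisher exact + BH)
#'
#' For every segment/feature, counts samples altered in each class
#' (direction `loss`: call <= -1; `gain`: call >= 1; `any`: call != 0),
#' runs the two-sided Fisher exact test on the 2x2 (class x altered) table,
#' and controls the FDR with Benjamini-Hochberg over all tested segments of
#' the comparison. Significant means `fdr < fdr_cutoff`.
#'
#' @param cn `cn_table` with discretized calls.
#' @param classes class labels.
#' @param class_a,class_b the two classes to compare.
#' @param direction `"loss"`, `"gain"` or `"any"`.
#' @param fdr_cutoff BH cutoff (default 0.05).
#' @return data.frame of class `segment_test` per feature: coordinates,
#'   altered counts, class sizes, `odds_ratio`, `p_value`, `fdr`,
#'   `significant`, `direction`; attribute `n_significant`.
#' @export
segment_fisher <- function(cn, classes, class_a, class_b,
                           direction = c("loss", "gain", "any"),
                           fdr_cutoff = 0.05) {
  direction <- match.arg(direction)
  if (is.null(cn$calls)) stop("discretized calls are required for segment tests")
  classes <- cn_classes(cn, classes)
  ia <- which(classes == class_a); ib <- which(classes == class_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty class")
  altered <- switch(direction,
                    loss = cn$calls <= -1L,
                    gain = cn$calls >= 1L,
                    any = cn$calls != 0L)
  ka <- rowSums(altered[, ia, drop = FALSE])
  kb <- rowSums(altered[, ib, drop = FALSE])
  na <- length(ia); nb <- length(ib)
  stats_ <- t(mapply(function(a, b) {
    ft <- stats::fisher.test(matrix(c(a, na - a, b, nb - b), 2L))
    c(ft$p.value, unname(ft$estimate))
  }, ka, kb))
  fdr <- stats::p.adjust(stats_[, 1L], method = "BH")
  out <- cbind(cn$features,
               data.frame(class_a_altered = ka, class_b_altered = kb,
                          n_class_a = na, n_class_b = nb,
                          odds_ratio = stats_[, 2L], p_value = stats_[, 1L],
                          fdr = fdr, significant = fdr < fdr_cutoff,
                          direction = direction))
  rownames(out) <- NULL
  out <- out[feature_order(cn$features), , drop = FALSE]
  attr(out, "n_significant") <- sum(out$significant)
  class(out) <- c("segment_test", "data.frame")
  out
}

#' Expression-copy-number correlation for one gene
#'
#' Correlates a gene's expression with its copy-number value (calls when
#' present, else continuous), per class and over all samples, with the
#' correlation-test p-value. A class with constant copy number yields `NA`
#' with a warning.
#'
#' @param expr expression matrix containing the gene.
#' @param cn `cn_table` containing the gene as a feature.
#' @param gene gene/feature identifier.
#' @param classes class labels (named by sample or positional over the
#'   shared samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param use_calls correlate against discretized calls when available.
#' @return data.frame per class (plus `overall`): `r`, `p_value`, `n`.
#' @export
expr_cn_correlation <- function(expr, cn, gene, classes,
                                method = c("pearson", "spearman"),
                                use_calls = TRUE) {
  method <- match.arg(method)
  if (!gene %in% rownames(expr)) stop("gene absent from expression: ", gene)
  if (!gene %in% rownames(cn$values)) stop("gene absent from copy number: ", gene)
  samples <- intersect(colnames(expr), colnames(cn$values))
  if (length(samples) < 3L) stop("fewer than 3 shared samples")
  classes <- align_labels(classes, samples)
  cnval <- if (use_calls && !is.null(cn$calls)) cn$calls[gene, samples]
           else cn$values[gene, samples]
  e <- expr[gene, samples]
  one <- function(idx, label) {
    if (length(unique(cnval[idx])) < 2L || length(unique(e[idx])) < 2L) {
      warning("constant expression or copy number in ", label, "; correlation undefined")
      return(data.frame(class = label, r = NA_real_, p_value = NA_real_,
                        n = length(idx)))
    }
    ct <- suppressWarnings(stats::cor.test(e[idx], cnval[idx], method = method))
    data.frame(class = label, r = unname(ct$estimate), p_value = ct$p.value,
               n = length(idx))
  }
  cls <- sort(unique(classes))
  out <- do.call(rbind, c(lapply(cls, function(cl) one(which(classes == cl), cl)),
                          list(one(seq_along(samples), "overall"))))
  rownames(out) <- NULL
  out
}

#' Per-class fraction of samples altered for one gene
#'
#' @param cn `cn_table` with calls.
#' @param gene feature identifier.
#' @param classes class labels.
#' @param direction `"loss"` (call <= -1), `"gain"` (call >= 1) or `"any"`.
#' @return named numeric vector, fraction altered per class.
#' @export
gene_alteration_frequency <- function(cn, gene, classes,
                                      direction = c("loss", "gain", "any")) {
  direction <- match.arg(direction)
  if (is.null(cn$calls)) stop("discretized calls are required")
  if (!gene %in% rownames(cn$calls)) stop("gene absent from copy number: ", gene)
  classes <- cn_classes(cn, classes)
  calls <- cn$calls[gene, ]
  altered <- switch(direction, loss = calls <= -1L, gain = calls >= 1L,
                    any = calls != 0L)
  vapply(split(altered, classes), mean, numeric(1))
}
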