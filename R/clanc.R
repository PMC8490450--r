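# ClaNC-style nearest-centroid classifier: class-specific gene selection on
# a labeled training cohort, correlation-based prediction on new cohorts.

#' Train a nearest-centroid classifier with class-specific gene selection
#'
#' For every gene and class a class-versus-rest moderated t-like score is
#' computed: `(class mean - overall mean) / (pooled within-class SD + s0)`,
#' where `s0` is the median pooled SD over genes (stabilizes zero-variance
#' genes). Genes are selected greedily by absolute score, highest first
#' (ties broken by gene id, then class name), each gene assigned to at most
#' one class, until every class holds `total_genes / n_classes` genes
#' (remainder spread over the first classes in name order). Centroids are
#' the training-class means of the centered expression over the selected
#' union.
#'
#' @param expr median-centered training expression (genes x samples).
#' @param labels class labels (named by sample or positional); >= 2 classes
#'   with >= 2 samples each.
#' @param total_genes total classifier size (default 150).
#' @return list of class `clanc`: `genes` (data.frame gene/class/score),
#'   `centroids` (selected genes x classes), `classes`, `total_genes`.
#' @export
train_clanc <- function(expr, labels, total_genes = 150L) {
  labels <- align_labels(labels, colnames(expr))
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("need at least 2 classes")
  sizes <- table(labels)[cls]
  if (any(sizes < 2L)) stop("every class needs at least 2 samples")
  n <- ncol(expr); K <- length(cls)
  overall <- rowMeans(expr)
  class_means <- vapply(cls, function(cl)
    rowMeans(expr[, labels == cl, drop = FALSE]), numeric(nrow(expr)))
  ss_within <- rowSums(vapply(cls, function(cl) {
    x <- expr[, labels == cl, drop = FALSE]
    rowSums((x - class_means[, cl])^2)
  }, numeric(nrow(expr))))
  pooled_sd <- sqrt(ss_within / (n - K))
  s0 <- stats::median(pooled_sd)
  scores <- (class_means - overall) / (pooled_sd + s0)
  quota <- rep(total_genes %/% K, K) +
    c(rep(1L, total_genes %% K), rep(0L, K - total_genes %% K))
  names(quota) <- cls
  cand <- data.frame(gene = rep(rownames(expr), K),
                     class = rep(cls, each = nrow(expr)),
                     score = as.vector(scores), stringsAsFactors = FALSE)
  cand <- cand[order(-abs(cand$score), cand$gene, cand$class), ]
  taken_gene <- character(0)
  filled <- stats::setNames(integer(K), cls)
  sel <- vector("list", sum(quota)); nsel <- 0L
  for (i in seq_len(nrow(cand))) {
    if (nsel == sum(quota)) break
    g <- cand$gene[i]; cl <- cand$class[i]
    if (filled[cl] >= quota[cl] || g %in% taken_gene) next
    nsel <- nsel + 1L
    sel[[nsel]] <- cand[i, ]
    taken_gene <- c(taken_gene, g)
    filled[cl] <- filled[cl] + 1L
  }
  sel <- do.call(rbind, sel[seq_len(nsel)])
  if (nsel < sum(quota))
    warning("only ", nsel, " of ", sum(quota),
            " requested genes could be selected")
  sel <- sel[order(sel$class, -abs(sel$score)), ]
  rownames(sel) <- NULL
  union_genes <- sel$gene
  centroids <- vapply(cls, function(cl)
    rowMeans(expr[union_genes, labels == cl, drop = FALSE]),
    numeric(length(union_genes)))
  rownames(centroids) <- union_genes
  structure(list(genes = sel, centroids = centroids, classes = cls,
                 total_genes = total_genes),
            class = "clanc")
}

#' Predict subtype labels with a trained centroid classifier
#'
#' Each sample of the new cohort (median-centered on its own cohort) is
#' Spearman-correlated to every class centroid over the genes shared with
#' the classifier; the label is the argmax. At least half of the classifier
#' genes must be present. Ties are broken by class name order, with a
#' message.
#'
#' @param object trained `clanc` classifier.
#' @param expr_new centered expression matrix of the new cohort.
#' @param ... unused.
#' @return data.frame: `sample_id`, `label`, one correlation column per
#'   class (`rho_<class>`).
#' @export
predict.clanc <- function(object, expr_new, ...) {
  shared <- intersect(rownames(object$centroids), rownames(expr_new))
  coverage <- length(shared) / nrow(object$centroids)
  if (coverage < 0.5)
    stop("only ", round(100 * coverage), "% of classifier genes present; >= 50% required")
  rho <- stats::cor(expr_new[shared, , drop = FALSE],
                    object$centroids[shared, , drop = FALSE],
                    method = "spearman")
  best <- apply(rho, 1L, which.max)
  ties <- apply(rho, 1L, function(r) sum(r == max(r)) > 1L)
  if (any(ties))
    message(sum(ties), " tie(s) broken by class name order")
  out <- data.frame(sample_id = colnames(expr_new),
                    label = object$classes[best],
                    rho, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out)[-(1:2)] <- paste0("rho_", object$classes)
  rownames(out) <- NULL
  out
}
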