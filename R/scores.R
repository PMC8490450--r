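# Derived expression statistics: differentiation scores, gene-set module
# scores, immune high/low grouping and per-gene differential expression.

#' Differentiation score from two reference correlations
#'
#' Difference of a sample's correlations to two reference tissues, e.g.
#' normal bile duct minus normal liver. Antisymmetric in its arguments.
#'
#' @param rho_ref1,rho_ref2 named per-sample correlation vectors; names are
#'   aligned when present.
#' @return named per-sample score in \[-2, 2\].
#' @export
differentiation_score <- function(rho_ref1, rho_ref2) {
  if (!is.null(names(rho_ref1)) && !is.null(names(rho_ref2))) {
    if (!setequal(names(rho_ref1), names(rho_ref2)))
      stop("the two correlation vectors cover different samples")
    rho_ref2 <- rho_ref2[names(rho_ref1)]
  } else if (length(rho_ref1) != length(rho_ref2))
    stop("correlation vectors differ in length")
  rho_ref1 - rho_ref2
}

#' Gene-set module score per sample
#'
#' Median (or mean) of median-centered expression over the genes of a set.
#' Genes absent from the matrix are dropped with a warning; an entirely
#' absent set is an error. Invariant to gene order within the set.
#'
#' @param expr centered expression matrix.
#' @param gene_set character vector of gene ids.
#' @param method `"median"` (default) or `"mean"`.
#' @return named per-sample score.
#' @export
module_score <- function(expr, gene_set, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!is_centered(expr))
    warning("module_score expects median-centered expression")
  present <- intersect(unique(gene_set), rownames(expr))
  if (length(present) == 0L) stop("no gene of the set is present in the matrix")
  if (length(present) < length(unique(gene_set)))
    warning("dropped ", length(unique(gene_set)) - length(present),
            " set gene(s) absent from the matrix")
  sub <- expr[present, , drop = FALSE]
  fn <- if (method == "median") stats::median else mean
  apply(sub, 2L, fn)
}

#' Immune high/low grouping from signature scores
#'
#' Scores every immune signature per sample with [module_score()], takes the
#' per-sample median across signatures as the overall immune score, and
#' splits at the cohort median: samples at or above it are `high` (inclusive
#' rule; a fully degenerate cohort is all `high`, with a message).
#'
#' @param expr centered expression matrix.
#' @param immune_sets named list of gene-id vectors (e.g. 24 immune cell
#'   signatures).
#' @param method passed to [module_score()].
#' @return list with `group` (named factor `high`/`low`), `overall` (named
#'   scores) and `set_scores` (signatures x samples matrix).
#' @export
immune_grouping <- function(expr, immune_sets, method = "median") {
  if (length(immune_sets) == 0L) stop("no immune signatures given")
  set_scores <- t(vapply(immune_sets, function(g)
    module_score(expr, g, method = method), numeric(ncol(expr))))
  overall <- apply(set_scores, 2L, stats::median)
  cut <- stats::median(overall)
  group <- factor(ifelse(overall >= cut, "high", "low"), levels = c("high", "low"))
  names(group) <- colnames(expr)
  if (all(group == "high"))
    message("degenerate immune scores: every sample is at the cohort median")
  list(group = group, overall = overall, set_scores = set_scores)
}

#' Class enrichment of a binary grouping (Fisher exact)
#'
#' For each class other than the referent, builds the 2x2 table
#' (class vs referent) x (high vs low) and reports the two-sided Fisher
#' exact p-value with the conditional odds-ratio estimate.
#'
#' @param groups named `high`/`low` grouping (e.g. from [immune_grouping()]).
#' @param classes named class labels over the same samples.
#' @param referent_class the comparison class (default `"HCC"`).
#' @return data.frame per class: counts, `odds_ratio`, `p_value`.
#' @export
class_enrichment <- function(groups, classes, referent_class = "HCC") {
  classes <- align_labels(classes, names(groups))
  if (!referent_class %in% classes) stop("referent class absent: ", referent_class)
  others <- setdiff(sort(unique(classes)), referent_class)
  if (length(others) == 0L) stop("no class to compare to the referent")
  ref_high <- sum(groups[classes == referent_class] == "high")
  ref_low <- sum(groups[classes == referent_class] == "low")
  rows <- lapply(others, function(cl) {
    n_high <- sum(groups[classes == cl] == "high")
    n_low <- sum(groups[classes == cl] == "low")
    if (n_high + n_low == 0L) stop("empty class: ", cl)
    tab <- matrix(c(n_high, n_low, ref_high, ref_low), 2L)
    ft <- stats::fisher.test(tab)
    data.frame(class = cl, high = n_high, low = n_low,
               referent_high = ref_high, referent_low = ref_low,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene differential expression (Welch t, BH adjustment)
#'
#' Welch two-sample t-test per gene between two sample groups, log2 fold
#' change as the difference of group means (expression already on the log2
#' scale), and Benjamini-Hochberg adjustment over all tested genes.
#'
#' @param expr expression matrix (genes x samples).
#' @param samples_a,samples_b column ids of the two groups (>= 2 each).
#' @return data.frame per gene: `mean_a`, `mean_b`, `log2_fold_change`,
#'   `t_statistic`, `p_value`, `fdr`, ordered as in `expr`.
#' @export
differential_expression <- function(expr, samples_a, samples_b) {
  missing <- setdiff(c(samples_a, samples_b), colnames(expr))
  if (length(missing)) stop("samples missing from the matrix: ",
                            paste(missing, collapse = ", "))
  res <- row_welch(expr, samples_a, samples_b)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$df <- NULL
  res
}
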