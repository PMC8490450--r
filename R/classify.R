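# Reference-anchored subtype classification.
#
# The core procedure: filter to highly/variably expressed genes, median-center
# each gene, correlate every sample to a CCA centroid (Spearman), call
# CCA-Like above the mean - 1 SD threshold of the CCA self-correlations, then
# call Blast-Like in the upper tertile of hepatoblast correlation among the
# remaining tumors. Tumor-adjacent normals pass through untouched.

#' Filter to highly expressed, variably expressed genes
#'
#' Keeps genes with expression above `min_expr` in at least
#' `min_expr_fraction` of samples, then ranks survivors by median absolute
#' deviation (MAD) and keeps the `top_n_variable` most variable.
#'
#' @param expr uncentered log2 expression matrix (genes x samples).
#' @param min_expr log2 expression floor.
#' @param min_expr_fraction fraction of samples that must exceed the floor.
#' @param top_n_variable how many genes to keep; if more than survive the
#'   expression filter, all survivors are kept with a warning.
#' @return character vector of gene ids, sorted by variability descending.
#' @export
filter_genes <- function(expr, min_expr = 1, min_expr_fraction = 0.7,
                         top_n_variable = 4035L) {
  if (is_centered(expr))
    stop("filter_genes expects uncentered expression (the floor is on the log2 scale)")
  frac <- rowMeans(expr > min_expr)
  surv <- expr[frac >= min_expr_fraction, , drop = FALSE]
  mads <- apply(surv, 1L, stats::mad)
  ord <- order(mads, decreasing = TRUE)
  if (top_n_variable > nrow(surv)) {
    warning("top_n_variable = ", top_n_variable, " exceeds the ", nrow(surv),
            " genes surviving the expression filter; keeping all")
    top_n_variable <- nrow(surv)
  }
  rownames(surv)[ord[seq_len(top_n_variable)]]
}

#' Median-center each gene
#'
#' Subtracts the per-gene median so every row has median 0. Idempotent.
#' @param expr expression matrix.
#' @return centered matrix with `is_centered = TRUE`.
#' @export
median_center <- function(expr) {
  centered <- expr - apply(expr, 1L, stats::median)
  expression_matrix(unclass(centered), is_centered = TRUE)
}

#' Spearman correlation of every sample to a reference centroid
#'
#' Computed on the genes shared between the matrix and the centroid
#' (at least 3 required); ties get average ranks.
#'
#' @param expr expression matrix (genes x samples).
#' @param centroid named numeric vector of per-gene reference expression.
#' @return named vector of per-sample rho in \[-1, 1\].
#' @export
spearman_to_centroid <- function(expr, centroid) {
  shared <- intersect(rownames(expr), names(centroid))
  if (length(shared) < 3L)
    stop("need at least 3 genes shared with the centroid (found ",
         length(shared), ")")
  r <- stats::cor(expr[shared, , drop = FALSE], centroid[shared],
                  method = "spearman")
  stats::setNames(as.vector(r), colnames(expr))
}

#' CCA-Like call from CCA-centroid correlations
#'
#' The threshold is `mean - sd` (sample SD, n-1 denominator) of the CCA
#' samples' own correlations to the CCA centroid. Every non-CCA tumor at or
#' above the threshold is labeled CCA-Like (inclusive boundary); CCA samples
#' keep their CCA label.
#'
#' @param rhos named per-sample correlations to the CCA centroid.
#' @param cca_sample_ids ids of the CCA samples (all must be present in
#'   `rhos`).
#' @param normal_ids optional ids of tumor-adjacent normals, labeled
#'   `Normal` and never reassigned.
#' @return list with `labels` (named; `CCA`, `CCA-Like`, `HCC` or `Normal`)
#'   and `threshold`.
#' @export
classify_cca_like <- function(rhos, cca_sample_ids, normal_ids = NULL) {
  if (!all(cca_sample_ids %in% names(rhos)))
    stop("some CCA sample ids are missing from the correlation vector")
  cca_rho <- rhos[cca_sample_ids]
  threshold <- mean(cca_rho) - stats::sd(cca_rho)
  labels <- ifelse(rhos >= threshold, "CCA-Like", "HCC")
  labels[cca_sample_ids] <- "CCA"
  labels[names(rhos) %in% normal_ids] <- "Normal"
  names(labels) <- names(rhos)
  list(labels = labels, threshold = threshold)
}

#' Blast-Like call from hepatoblast correlations (upper-tertile rule)
#'
#' The cutoff is the 66.67th percentile (linear-interpolation quantile) of
#' the hepatoblast correlation over all non-CCA tumor samples; CCA-Like
#' samples stay in the ranking population but are not relabeled. Tumors at or
#' above the cutoff (inclusive) and not CCA-Like become Blast-Like; the rest
#' become HCC.
#'
#' @param hepatoblast_rhos named per-sample correlations to the hepatoblast
#'   centroid (must cover the tumor samples).
#' @param labels named labels as produced by [classify_cca_like()].
#' @return list with updated `labels` and `tertile_cutoff`.
#' @export
classify_blast_like <- function(hepatoblast_rhos, labels) {
  pop <- names(labels)[!labels %in% c("CCA", "Normal")]
  if (!all(pop %in% names(hepatoblast_rhos)))
    stop("hepatoblast correlations missing for some tumor samples")
  if (length(pop) == 0L) return(list(labels = labels, tertile_cutoff = NA_real_))
  cutoff <- stats::quantile(hepatoblast_rhos[pop], 2 / 3, type = 7, names = FALSE)
  blast <- pop[hepatoblast_rhos[pop] >= cutoff & labels[pop] != "CCA-Like"]
  labels[pop[labels[pop] != "CCA-Like"]] <- "HCC"
  labels[blast] <- "Blast-Like"
  list(labels = labels, tertile_cutoff = cutoff)
}

#' Merge two cohorts by anchoring per-gene medians
#'
#' Cohort A is shifted, gene by gene, by the difference between the median
#' expression of the anchor samples in cohort B and in cohort A, so that
#' after merging the per-gene anchor medians agree. The anchors must be the
#' same biological class in both cohorts. Output is restricted to shared
#' genes.
#'
#' @param expr_a,expr_b expression matrices (genes x samples).
#' @param anchor_ids_a,anchor_ids_b anchor sample ids within each cohort.
#' @return merged matrix over shared genes, columns of A (shifted) then B.
#' @export
merge_cohorts <- function(expr_a, expr_b, anchor_ids_a, anchor_ids_b) {
  shared <- intersect(rownames(expr_a), rownames(expr_b))
  if (length(shared) < 3L) stop("fewer than 3 genes shared between cohorts")
  if (length(intersect(colnames(expr_a), colnames(expr_b))))
    stop("cohorts share sample identifiers")
  if (!all(anchor_ids_a %in% colnames(expr_a)) ||
      !all(anchor_ids_b %in% colnames(expr_b)))
    stop("anchor samples missing from their cohort")
  a <- expr_a[shared, , drop = FALSE]
  b <- expr_b[shared, , drop = FALSE]
  shift <- apply(b[, anchor_ids_b, drop = FALSE], 1L, stats::median) -
    apply(a[, anchor_ids_a, drop = FALSE], 1L, stats::median)
  expression_matrix(cbind(a + shift, b), is_centered = FALSE)
}

#' Assign CCA-Like / Blast-Like / HCC subtype labels
#'
#' The full classification: gene filter, median centering, Spearman
#' correlation of every sample to the cohort CCA centroid (per-gene median
#' of the CCA samples' centered expression), the mean - 1 SD CCA-Like rule,
#' Spearman correlation to the hepatoblast reference centroid, the
#' upper-tertile Blast-Like rule, and residual HCC labels. Normals pass
#' through labeled `Normal`.
#'
#' @param expr uncentered log2 expression matrix of the whole cohort.
#' @param cca_ids ids of the CCA samples.
#' @param centroids named list of reference centroids (named numeric
#'   vectors); `hepatoblast` is required, `hepatocyte` and `cholangiocyte`
#'   are correlated when present.
#' @param config `classification` block of [default_config()].
#' @param normal_ids optional tumor-adjacent normal ids.
#' @return data.frame of class `subtype_assignment`: `sample_id`, `label`,
#'   `rho_cca`, `rho_hepatoblast`, `rho_hepatocyte`, `rho_cholangiocyte`,
#'   `threshold_used`, `tertile_cutoff_used`.
#' @export
assign_subtypes <- function(expr, cca_ids, centroids,
                            config = default_config()$classification,
                            normal_ids = NULL) {
  if (!all(cca_ids %in% colnames(expr))) stop("CCA samples missing from the cohort")
  if (!"hepatoblast" %in% names(centroids))
    stop("a 'hepatoblast' reference centroid is required")
  genes <- filter_genes(expr, config$min_expr, config$min_expr_fraction,
                        config$top_n_variable)
  centered <- median_center(expr[genes, , drop = FALSE])
  cca_centroid <- apply(centered[, cca_ids, drop = FALSE], 1L, stats::median)
  rho_cca <- spearman_to_centroid(centered, cca_centroid)
  step1 <- classify_cca_like(rho_cca, cca_ids, normal_ids = normal_ids)
  rho_blast <- spearman_to_centroid(centered, centroids$hepatoblast)
  step2 <- classify_blast_like(rho_blast, step1$labels)
  aux <- function(name) {
    if (name %in% names(centroids))
      spearman_to_centroid(centered, centroids[[name]])
    else stats::setNames(rep(NA_real_, ncol(expr)), colnames(expr))
  }
  out <- data.frame(
    sample_id = colnames(expr),
    label = unname(step2$labels[colnames(expr)]),
    rho_cca = unname(rho_cca),
    rho_hepatoblast = unname(rho_blast),
    rho_hepatocyte = unname(aux("hepatocyte")[colnames(expr)]),
    rho_cholangiocyte = unname(aux("cholangiocyte")[colnames(expr)]),
    threshold_used = step1$threshold,
    tertile_cutoff_used = step2$tertile_cutoff,
    stringsAsFactors = FALSE)
  class(out) <- c("subtype_assignment", "data.frame")
  out
}
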