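# Trinucleotide mutation motifs and de novo mutational signatures.
#
# Single-base substitutions are collapsed to a pyrimidine central base
# (C or T): a substitution reported on the purine strand is reverse-
# complemented together with its flanking context, giving 6 substitution
# classes x 16 flank pairs = 96 canonical motifs.

.comp <- c(A = "T", C = "G", G = "C", T = "A")

revcomp3 <- function(x) {
  # reverse complement of 3-mers, vectorized
  chartr("ACGT", "TGCA",
         paste0(substr(x, 3L, 3L), substr(x, 2L, 2L), substr(x, 1L, 1L)))
}

#' The 96 canonical motif labels in fixed order
#'
#' Substitution-major order: `C>A, C>G, C>T, T>A, T>C, T>G`, and within each
#' substitution the 5' flank then the 3' flank in `A, C, G, T` order
#' (`A[C>A]A`, `A[C>A]C`, ...). Catalogs and motif matrices are always
#' aligned by these labels, never by row position.
#' @return character vector of length 96.
#' @export
motif_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases,
                      function(f1, f2) paste0(f1, "[", s, "]", f2))))),
    use.names = FALSE)
}

#' Canonical pyrimidine-centered motif label for a substitution
#'
#' If the reference base is a purine (A/G) the substitution and its 3-mer
#' context are reverse-complemented so the central base is C or T; the label
#' is formatted `"X[R>A]Y"`. Vectorized.
#'
#' @param ref,alt single reference/alternate bases (A/C/G/T).
#' @param context 3-mer centered on the mutated base; its middle base must
#'   equal `ref`.
#' @return character vector of motif labels; `NA` for records with ambiguous
#'   bases (N) or malformed context, which callers count as skipped.
#' @export
#' @examples
#' canonical_motif("C", "T", "ACG") # "A[C>T]G"
#' canonical_motif("G", "T", "AGC") # "G[C>A]T"
canonical_motif <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  n <- length(ref)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt & nchar(context) == 3L & substr(context, 2L, 2L) == ref &
    !grepl("[^ACGT]", context)
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  pur <- r %in% c("A", "G")
  r[pur] <- .comp[r[pur]]
  a[pur] <- .comp[a[pur]]
  ctx[pur] <- revcomp3(ctx[pur])
  out[ok] <- paste0(substr(ctx, 1L, 1L), "[", r, ">", a, "]", substr(ctx, 3L, 3L))
  out
}

#' Count 96-context motifs per sample
#'
#' Builds the samples x 96 motif count matrix from a variant table whose
#' records carry an inline 3-mer context (see [context_from_fasta()] to fill
#' contexts from a reference sequence). Records that are not single-base
#' substitutions with a usable context are skipped and reported. Samples with
#' zero usable SNVs are retained as all-zero rows.
#'
#' @param variants variant table (see [read_variants()]).
#' @param sample_ids optional vector of samples to force into the output
#'   (zero rows for samples without records).
#' @return integer matrix samples x 96 (columns in [motif_labels()] order)
#'   with attribute `skipped`: a per-reason count of dropped records.
#' @export
count_motifs <- function(variants, sample_ids = NULL) {
  labels <- motif_labels()
  motif <- canonical_motif(variants$ref, variants$alt, variants$context)
  skipped <- sum(is.na(motif))
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  keep <- !is.na(motif)
  counts <- table(factor(variants$sample_id[keep], levels = sample_ids),
                  factor(motif[keep], levels = labels))
  m <- matrix(as.integer(counts), nrow = length(sample_ids),
              dimnames = list(sample_ids, labels))
  if (skipped > 0L)
    message("skipped ", skipped, " record(s) without a canonical SNV motif")
  attr(m, "skipped") <- skipped
  m
}

#' Per-sample motif frequencies
#' @param counts samples x 96 count matrix.
#' @return matrix of per-sample frequencies (rows sum to 1; all-zero rows
#'   stay zero).
#' @export
motif_frequencies <- function(counts) {
  tot <- rowSums(counts)
  f <- counts / ifelse(tot > 0, tot, 1)
  attr(f, "skipped") <- NULL
  f
}

#' Fill variant contexts from a reference FASTA
#'
#' Looks up the 3-mer `pos - 1 .. pos + 1` (1-based) on the named chromosome
#' of a reference sequence set and writes it into the `context` column.
#' Requires the Biostrings package.
#'
#' @param variants variant table.
#' @param fasta path to an (uncompressed) FASTA whose sequence names match
#'   `variants$chrom`.
#' @return the variant table with contexts filled; records whose reference
#'   base disagrees with the FASTA get `NA` context and a warning.
#' @export
context_from_fasta <- function(variants, fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA context extraction")
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ctx <- rep(NA_character_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    if (!ch %in% names(seqs)) next
    len <- length(seqs[[ch]])
    ok <- variants$pos[i] > 1L & variants$pos[i] < len
    ctx[i[ok]] <- as.character(Biostrings::subseq(
      rep(seqs[ch], sum(ok)),
      start = variants$pos[i[ok]] - 1L, width = 3L))
  }
  mismatch <- !is.na(ctx) & substr(ctx, 2L, 2L) != variants$ref
  if (any(mismatch)) {
    warning(sum(mismatch), " record(s) disagree with the reference base; context set to NA")
    ctx[mismatch] <- NA_character_
  }
  variants$context <- ctx
  variants
}

#' Per-class median motif profile (Lego-plot table)
#'
#' For each class, the median across its samples of the per-sample motif
#' frequencies, one value per canonical motif.
#'
#' @param counts samples x 96 motif count matrix.
#' @param classes named (by sample) or positionally aligned class labels.
#' @return classes x 96 matrix of median frequencies.
#' @export
class_motif_profile <- function(counts, classes) {
  classes <- align_labels(classes, rownames(counts))
  freq <- motif_frequencies(counts)
  cls <- sort(unique(classes))
  if (any(table(classes)[cls] == 0L) || length(cls) == 0L) stop("empty class")
  out <- t(vapply(cls, function(cl)
    apply(freq[classes == cl, , drop = FALSE], 2L, stats::median),
    numeric(ncol(freq))))
  rownames(out) <- cls
  out
}

# Align a label vector to ids: use names when present, else positions.
align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels))) stop("labels missing for some samples")
    return(unname(labels[ids]))
  }
  if (length(labels) != length(ids)) stop("labels and samples differ in length")
  unname(labels)
}

#' Extract de novo mutational signatures by NMF
#'
#' Non-negative matrix factorization of the motifs x samples matrix
#' (per-sample frequencies by default, so hypermutated samples do not
#' dominate) under Frobenius loss with multiplicative updates. The best of
#' `n_restarts` random initializations by reconstruction error is kept;
#' signatures are column-normalized to sum 1 (exposures rescaled
#' compensatingly) and ordered by total exposure, descending. The
#' reconstruction-error trace of the winning restart is checked to be
#' non-increasing and returned.
#'
#' @param counts samples x 96 motif count matrix.
#' @param k number of signatures (`1 <= k <= min(96, usable samples)`).
#' @param n_restarts random restarts.
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol relative-improvement stopping tolerance.
#' @param input `"frequency"` (default) or `"count"`.
#' @return list of class `signature_model`: `signatures` (96 x k, columns
#'   sum to 1), `exposures` (k x samples; zero for zero-mutation samples),
#'   `k`, `n_restarts`, `seed`, `reconstruction_error`, `error_trace`.
#' @export
extract_signatures <- function(counts, k, n_restarts = 20L, seed = 1L,
                               max_iter = 2000L, tol = 1e-8,
                               input = c("frequency", "count")) {
  input <- match.arg(input)
  if (k < 1L) stop("k must be at least 1")
  usable <- rowSums(counts) > 0
  if (any(!usable))
    warning(sum(!usable), " zero-mutation sample(s) excluded from factorization")
  V <- t(if (input == "frequency") motif_frequencies(counts[usable, , drop = FALSE])
         else counts[usable, , drop = FALSE])
  if (k > min(nrow(V), ncol(V)))
    stop("k = ", k, " exceeds the achievable rank min(96, usable samples) = ",
         min(nrow(V), ncol(V)))
  set.seed(seed)
  eps <- 1e-10
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H <- matrix(stats::runif(k * ncol(V), 0.1, 1), k, ncol(V))
    trace <- numeric(0)
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * crossprod(W, V) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err <- sqrt(sum((V - W %*% H)^2))
      trace <- c(trace, err)
      if (is.finite(err_prev) && (err_prev - err) < tol * max(err_prev, eps)) break
      err_prev <- err
    }
    if (any(diff(trace) > 1e-9 * trace[-length(trace)]))
      stop("multiplicative updates increased the reconstruction error")
    if (is.null(best) || err < best$err)
      best <- list(W = W, H = H, err = err, trace = trace)
  }
  sc <- colSums(best$W)
  W <- sweep(best$W, 2L, sc, "/")
  H <- best$H * sc
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  sig_names <- paste0("S", seq_len(k))
  dimnames(W) <- list(rownames(V), sig_names)
  exposures <- matrix(0, k, nrow(counts),
                      dimnames = list(sig_names, rownames(counts)))
  exposures[, usable] <- H
  structure(list(signatures = W, exposures = exposures, k = k,
                 n_restarts = n_restarts, seed = seed,
                 reconstruction_error = best$err, error_trace = best$trace),
            class = "signature_model")
}

#' Cosine similarity of de novo signatures to a reference catalog
#'
#' Full k x K pairwise cosine table; catalog rows are aligned to the model's
#' motif labels (a label mismatch is an error).
#'
#' @param model `signature_model`.
#' @param catalog 96 x K catalog matrix with motif-label rownames.
#' @return k x K matrix of cosine similarities.
#' @export
match_catalog <- function(model, catalog) {
  if (!setequal(rownames(catalog), rownames(model$signatures)))
    stop("catalog motif labels do not match the model")
  catalog <- catalog[rownames(model$signatures), , drop = FALSE]
  cosine_matrix(model$signatures, catalog)
}

#' Per-class median cosine similarity of samples to catalog signatures
#'
#' Each usable sample's motif frequency vector is compared to every catalog
#' signature by cosine similarity; per class the median over samples is
#' reported. Zero-mutation samples are excluded with a warning.
#'
#' @param counts samples x 96 motif count matrix.
#' @param catalog 96 x K catalog matrix.
#' @param classes class labels (named by sample or positional).
#' @return classes x K matrix of median cosine similarities.
#' @export
sample_catalog_similarity <- function(counts, catalog, classes) {
  classes <- align_labels(classes, rownames(counts))
  usable <- rowSums(counts) > 0
  if (any(!usable))
    warning(sum(!usable), " zero-mutation sample(s) excluded from cosine similarity")
  catalog <- catalog[motif_labels(), , drop = FALSE]
  freq <- motif_frequencies(counts[usable, , drop = FALSE])
  cs <- cosine_matrix(t(freq), catalog)  # samples x K
  cls <- sort(unique(classes[usable]))
  out <- t(vapply(cls, function(cl)
    apply(cs[classes[usable] == cl, , drop = FALSE], 2L, stats::median),
    numeric(ncol(cs))))
  rownames(out) <- cls
  out
}

#' Per-class median normalized signature exposure
#'
#' Exposures are normalized per sample to sum 1 (zero-exposure samples are
#' excluded with a warning), then the class-wise median per signature is
#' taken.
#'
#' @param model `signature_model`.
#' @param classes class labels (named by sample or positional).
#' @return classes x k matrix of median normalized exposures.
#' @export
exposure_by_class <- function(model, classes) {
  E <- model$exposures
  classes <- align_labels(classes, colnames(E))
  tot <- colSums(E)
  usable <- tot > 0
  if (any(!usable))
    warning(sum(!usable), " zero-exposure sample(s) excluded")
  En <- sweep(E[, usable, drop = FALSE], 2L, tot[usable], "/")
  cls <- sort(unique(classes[usable]))
  out <- t(vapply(cls, function(cl)
    apply(En[, classes[usable] == cl, drop = FALSE], 1L, stats::median),
    numeric(nrow(En))))
  rownames(out) <- cls
  out
}

#' Compare catalog-signature similarity between two sample groups
#'
#' Per-sample cosine similarity to one named catalog signature, then a
#' two-sided Welch t-test between the groups. Used for hotspot/etiology
#' comparisons such as TP53 R249S carriers versus an aflatoxin-like
#' signature.
#'
#' @param counts samples x 96 motif count matrix.
#' @param catalog 96 x K catalog matrix.
#' @param signature catalog column name to test against.
#' @param group_a,group_b sample id vectors (each of size >= 2 after
#'   excluding zero-mutation samples).
#' @return list with `t_statistic`, `df`, `p_value`, group means and sizes.
#' @export
variant_group_similarity_test <- function(counts, catalog, signature,
                                          group_a, group_b) {
  if (!signature %in% colnames(catalog)) stop("unknown catalog signature: ", signature)
  catalog <- catalog[motif_labels(), , drop = FALSE]
  usable <- rownames(counts)[rowSums(counts) > 0]
  ga <- intersect(group_a, usable); gb <- intersect(group_b, usable)
  if (length(ga) < 2L || length(gb) < 2L)
    stop("each group needs at least 2 samples with mutations")
  freq <- motif_frequencies(counts[c(ga, gb), , drop = FALSE])
  cs <- drop(cosine_matrix(t(freq), catalog[, signature, drop = FALSE]))
  tt <- stats::t.test(cs[ga], cs[gb])
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(cs[ga]), mean_b = mean(cs[gb]),
       n_a = length(ga), n_b = length(gb))
}
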