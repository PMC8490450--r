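# Independent oracles used to check the implementation paths. Each is a
# deliberately naive, brute-force formulation kept separate from the package
# internals.

# Benjamini-Hochberg step-up, literal formulation: sort p ascending,
# q_(i) = min_{j >= i} p_(j) * m / j, map back to the original order.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration: sum the probabilities of all tables (same margins) whose
# probability does not exceed the observed one. The (1 + 1e-7) factor is the
# standard floating-point guard for probability ties.
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Per-record motif counter: complement lookup and strand collapse written
# longhand, one record at a time.
count_motifs_brute <- function(variants, sample_ids) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  labels <- hccsubtypes::motif_labels()
  out <- matrix(0L, length(sample_ids), 96,
                dimnames = list(sample_ids, labels))
  for (i in seq_len(nrow(variants))) {
    ref <- variants$ref[i]; alt <- variants$alt[i]; ctx <- variants$context[i]
    if (is.na(ctx) || nchar(ctx) != 3L) next
    if (!ref %in% names(comp) || !alt %in% names(comp) || ref == alt) next
    chars <- strsplit(ctx, "")[[1L]]
    if (any(!chars %in% names(comp)) || chars[2L] != ref) next
    if (ref %in% c("A", "G")) {
      ref2 <- comp[[ref]]; alt2 <- comp[[alt]]
      chars <- rev(unname(comp[chars]))
    } else {
      ref2 <- ref; alt2 <- alt
    }
    lab <- paste0(chars[1L], "[", ref2, ">", alt2, "]", chars[3L])
    out[variants$sample_id[i], lab] <- out[variants$sample_id[i], lab] + 1L
  }
  out
}

# Random valid variant table over the given samples.
random_variant_table <- function(n_records, sample_ids) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_records, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  ctx <- paste0(sample(bases, n_records, TRUE), ref, sample(bases, n_records, TRUE))
  data.frame(sample_id = sample(sample_ids, n_records, replace = TRUE),
             chrom = "1", pos = seq_len(n_records), ref = ref, alt = alt,
             gene = NA_character_, protein_change = NA_character_,
             context = ctx, stringsAsFactors = FALSE)
}

# Small labeled expression toy: k classes with exclusive marker blocks.
toy_marker_expression <- function(n_per_class = 6L, markers_per_class = 10L,
                                  n_noise_genes = 30L, effect = 3,
                                  classes = c("A", "B"), sd = 0.3,
                                  seed = 11L) {
  set.seed(seed)
  k <- length(classes)
  n_genes <- k * markers_per_class + n_noise_genes
  genes <- sprintf("g%03d", seq_len(n_genes))
  labels <- rep(classes, each = n_per_class)
  m <- matrix(rnorm(n_genes * length(labels), 0, sd), n_genes,
              dimnames = list(genes, sprintf("s%02d", seq_along(labels))))
  for (i in seq_len(k)) {
    rows <- (i - 1L) * markers_per_class + seq_len(markers_per_class)
    m[rows, labels == classes[i]] <- m[rows, labels == classes[i]] + effect
  }
  list(expr = m, labels = setNames(labels, colnames(m)),
       markers = split(genes[seq_len(k * markers_per_class)],
                       rep(classes, each = markers_per_class)))
}
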