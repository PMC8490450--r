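# Motif counting with strand collapse, per-class profiles, NMF signature
# extraction and catalog matching.

test_that("canonical_motif collapses purine-strand records", {
  expect_equal(canonical_motif("C", "T", "ACG"), "A[C>T]G")
  expect_equal(canonical_motif("G", "T", "AGC"), "G[C>A]T")
  expect_equal(canonical_motif("A", "T", "TAT"), "A[T>A]A")
  expect_true(is.na(canonical_motif("C", "T", "ANG")))
  expect_true(is.na(canonical_motif("C", "C", "ACG")))
  expect_true(is.na(canonical_motif("C", "T", "AAG")))  # middle != ref
})

test_that("a record and its reverse-complement representation share a motif", {
  set.seed(9)
  vt <- random_variant_table(300L, "s")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) chartr("ACGT", "TGCA",
                           sapply(lapply(strsplit(x, ""), rev), paste, collapse = ""))
  m1 <- canonical_motif(vt$ref, vt$alt, vt$context)
  m2 <- canonical_motif(unname(comp[vt$ref]), unname(comp[vt$alt]), rc(vt$context))
  expect_identical(m1, m2)
})

test_that("count_motifs matches the brute-force per-record counter", {
  # fixed toy: 3 identical C>T records in one motif
  vt <- data.frame(sample_id = "s1", chrom = "1", pos = 1:3, ref = "C",
                   alt = "T", gene = NA, protein_change = NA, context = "ACG")
  m <- count_motifs(vt)
  expect_equal(m["s1", "A[C>T]G"], 3L, ignore_attr = TRUE)
  expect_equal(sum(m), 3L)
  # indel-like record is skipped and reported
  vt2 <- rbind(vt, data.frame(sample_id = "s1", chrom = "1", pos = 4,
                              ref = "CA", alt = "C", gene = NA,
                              protein_change = NA, context = NA))
  expect_message(m2 <- count_motifs(vt2), "skipped 1")
  expect_equal(attr(m2, "skipped"), 1L)
  expect_equal(sum(m2), 3L)
  # random tables equal the independent counter
  set.seed(101)
  for (i in 1:20) {
    ids <- paste0("s", 1:4)
    vt3 <- random_variant_table(200L, ids)
    expect_equal(unclass(count_motifs(vt3, ids)),
                 count_motifs_brute(vt3, ids), ignore_attr = TRUE)
  }
  # zero-SNV samples are retained as zero rows
  m4 <- count_motifs(vt, sample_ids = c("s1", "empty"))
  expect_equal(sum(m4["empty", ]), 0L)
})

test_that("class motif profiles are per-class medians of frequencies", {
  counts <- rbind(s1 = c(20, 80), s2 = c(40, 60))
  counts <- cbind(counts, matrix(0L, 2, 94))
  colnames(counts) <- motif_labels()
  prof <- class_motif_profile(counts, setNames(c("X", "X"), c("s1", "s2")))
  expect_equal(unname(prof["X", 1:2]), c(0.3, 0.7))
  # a single-sample class is that sample's frequency vector
  prof2 <- class_motif_profile(counts, setNames(c("X", "Y"), c("s1", "s2")))
  expect_equal(unname(prof2["Y", 1:2]), c(0.4, 0.6))
})

test_that("cosine similarity closed forms", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("rank-1 motif matrices are recovered exactly by k = 1 NMF", {
  prof <- default_planted_signatures()[, 1]
  counts <- t(vapply(1:6, function(i) as.integer(round(prof * 1000 * i)),
                     integer(96)))
  rownames(counts) <- paste0("s", 1:6)
  colnames(counts) <- motif_labels()
  mod <- extract_signatures(counts, k = 1, n_restarts = 3, seed = 4)
  expect_gte(cosine_similarity(mod$signatures[, 1], prof), 0.999)
  expect_true(all(diff(mod$error_trace) <= 1e-9 * mod$error_trace[-length(mod$error_trace)]))
})

test_that("signature extraction is deterministic and validates k", {
  set.seed(12)
  counts <- matrix(rpois(5 * 96, 3), 5, dimnames = list(paste0("s", 1:5),
                                                        motif_labels()))
  m1 <- extract_signatures(counts, k = 2, n_restarts = 3, seed = 7)
  m2 <- extract_signatures(counts, k = 2, n_restarts = 3, seed = 7)
  expect_equal(m1$signatures, m2$signatures)
  expect_equal(m1$exposures, m2$exposures)
  expect_equal(colSums(m1$signatures), c(S1 = 1, S2 = 1), tolerance = 1e-9)
  # exposures ordered by total contribution, descending
  expect_true(diff(rowSums(m1$exposures)) <= 0)
  expect_error(extract_signatures(counts, k = 6, n_restarts = 1, seed = 1),
               "achievable rank")
})

test_that("catalog matching aligns by motif label", {
  prof <- default_planted_signatures()
  counts <- t(vapply(1:6, function(i)
    as.integer(round(prof[, (i %% 3) + 1] * 500)), integer(96)))
  dimnames(counts) <- list(paste0("s", 1:6), motif_labels())
  mod <- extract_signatures(counts, k = 3, n_restarts = 5, seed = 2)
  sim <- match_catalog(mod, prof)
  # the model's own generators are in the catalog: each attains cosine ~1
  expect_true(all(apply(sim, 2, max) > 0.99))
  # permuting catalog rows (with labels) changes nothing
  sim2 <- match_catalog(mod, prof[sample(96), ])
  expect_equal(sim2, sim)
  bad <- prof; rownames(bad)[1] <- "Z[Z>Z]Z"
  expect_error(match_catalog(mod, bad), "labels")
})

test_that("per-sample catalog similarity excludes zero-mutation samples", {
  cat0 <- default_catalog()
  counts <- rbind(s1 = as.integer(round(cat0[, "aflatoxin_like"] * 400)),
                  s2 = integer(96))
  colnames(counts) <- motif_labels()
  cls <- setNames(c("X", "X"), c("s1", "s2"))
  expect_warning(res <- sample_catalog_similarity(counts, cat0, cls),
                 "zero-mutation")
  expect_equal(unname(which.max(res["X", ])),
               which(colnames(cat0) == "aflatoxin_like"))
  expect_gt(res["X", "aflatoxin_like"], 0.99)
})

test_that("exposure_by_class normalizes per sample then takes class medians", {
  E <- rbind(S1 = c(2, 1, 0), S2 = c(2, 3, 0))
  colnames(E) <- paste0("s", 1:3)
  mod <- structure(list(exposures = E), class = "signature_model")
  cls <- setNames(c("X", "X", "X"), colnames(E))
  expect_warning(res <- exposure_by_class(mod, cls), "zero-exposure")
  # normalized exposures: (0.5, 0.25) and (0.5, 0.75); medians by brute force
  expect_equal(unname(res["X", ]), c(median(c(0.5, 0.25)), median(c(0.5, 0.75))))
})

test_that("group similarity test separates planted from orthogonal profiles", {
  cat0 <- default_catalog()
  set.seed(31)
  mk <- function(p, n) t(vapply(seq_len(n), function(i)
    as.integer(rmultinom(1, 400, p)), integer(96)))
  counts <- rbind(mk(cat0[, "aflatoxin_like"], 10), mk(cat0[, "tdecay_tc"], 10))
  dimnames(counts) <- list(paste0("s", 1:20), motif_labels())
  res <- variant_group_similarity_test(counts, cat0, "aflatoxin_like",
                                       paste0("s", 1:10), paste0("s", 11:20))
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$mean_a, res$mean_b)
  expect_error(variant_group_similarity_test(counts, cat0, "aflatoxin_like",
                                             "s1", paste0("s", 11:20)),
               "at least 2")
})

test_that("contexts are filled from a reference FASTA with mismatch checks", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTACGTAC", ">chr2", "TTTTCCCCGG"), fa)
  vt <- data.frame(sample_id = "s1", chrom = c("chr1", "chr2", "chr1", "chr1"),
                   pos = c(2L, 5L, 1L, 3L),
                   ref = c("C", "C", "A", "T"), alt = c("T", "A", "G", "A"),
                   gene = NA, protein_change = NA, context = NA,
                   stringsAsFactors = FALSE)
  expect_warning(out <- context_from_fasta(vt, fa), "disagree")
  expect_equal(out$context, c("ACG", "TCC", NA, NA))  # edge + mismatch -> NA
})
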