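# Class-level copy-number comparison.

toy_cn <- function() {
  feats <- data.frame(feature_id = paste0("f", 1:4), chrom = c("1", "1", "2", "2"),
                      start = c(100, 200, 100, 200), end = c(150, 250, 150, 250),
                      stringsAsFactors = FALSE)
  vals <- matrix(c(-0.8, -0.9, 0, 0.1,
                   -0.7, -0.8, 0.1, 0,
                   0, 0.1, 0, -0.1,
                   0.1, 0, 0.05, 0), 4,
                 dimnames = list(feats$feature_id, paste0("s", 1:4)))
  calls <- matrix(as.integer(c(-1, -1, 0, 0,
                               -1, -1, 0, 0,
                               0, 0, 0, 0,
                               0, 0, 0, 0)), 4,
                  dimnames = dimnames(vals))
  cn_table(feats, vals, calls)
}

test_that("cn_table validates its grids", {
  expect_error(cn_table(data.frame(feature_id = c("a", "a")),
                        matrix(0, 2, 2, dimnames = list(NULL, c("s1", "s2")))),
               "duplicate")
  feats <- data.frame(feature_id = "a", chrom = "1", start = 10, end = 5)
  expect_error(cn_table(feats, matrix(0, 1, 1, dimnames = list("a", "s1"))),
               "start > end")
  feats2 <- data.frame(feature_id = "a")
  expect_error(cn_table(feats2, matrix(0, 1, 2, dimnames = list("a", c("s1", "s2"))),
                        calls = matrix(3L, 1, 2)), "calls outside")
})

test_that("class means and difference tracks are antisymmetric", {
  cn <- toy_cn()
  classes <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  res <- class_mean_cn(cn, classes)
  expect_equal(res$means$A, rowMeans(cn$values[, 1:2]), ignore_attr = TRUE)
  # identical samples in a class: mean equals any member
  cn2 <- cn; cn2$values[, 2] <- cn2$values[, 1]
  res2 <- class_mean_cn(cn2, classes)
  expect_equal(res2$means$A, cn2$values[, 1], ignore_attr = TRUE)
  # antisymmetry under swapping the pair
  flipped <- setNames(c("B", "B", "A", "A"), paste0("s", 1:4))
  res3 <- class_mean_cn(cn, flipped)
  expect_equal(res3$differences$A_minus_B, -res$differences$A_minus_B)
})

test_that("a planted step is detected by the pairwise Welch test", {
  set.seed(55)
  n <- 30
  feats <- data.frame(feature_id = paste0("f", 1:50), chrom = "1",
                      start = 1:50 * 100, end = 1:50 * 100 + 50)
  vals <- matrix(rnorm(50 * 2 * n, 0, 0.1), 50,
                 dimnames = list(feats$feature_id,
                                 c(paste0("a", 1:n), paste0("b", 1:n))))
  vals[1:10, 1:n] <- vals[1:10, 1:n] + 0.5   # step 5x jitter SD
  cn <- cn_table(feats, vals)
  classes <- setNames(rep(c("A", "B"), each = n), colnames(vals))
  res <- pairwise_cn_ttest(cn, classes, "A", "B")
  expect_true(all(res$significant[match(paste0("f", 1:10), res$feature_id)]))
  expect_lt(mean(res$significant[match(paste0("f", 11:50), res$feature_id)]), 0.2)
  # a class of size 1 is refused
  expect_error(pairwise_cn_ttest(cn, setNames(c("A", rep("B", 2 * n - 1)),
                                              colnames(vals)), "A", "B"),
               "at least 2")
})

test_that("segment Fisher test matches enumeration and flags planted events", {
  # 0/10 vs 0/10 altered: p = 1
  feats <- data.frame(feature_id = "f1", chrom = "1", start = 1, end = 2)
  mk_cn <- function(calls_row) {
    v <- matrix(as.numeric(calls_row), 1,
                dimnames = list("f1", paste0("s", seq_along(calls_row))))
    cn_table(feats, v, matrix(as.integer(calls_row), 1))
  }
  cls <- setNames(rep(c("A", "B"), each = 10), paste0("s", 1:20))
  r0 <- segment_fisher(mk_cn(rep(0L, 20)), cls, "A", "B", "loss")
  expect_equal(r0$p_value, 1)
  # 10/10 vs 0/10: two-sided p = 2 / choose(20, 10)
  r1 <- segment_fisher(mk_cn(rep(c(-1L, 0L), each = 10)), cls, "A", "B", "loss")
  expect_equal(r1$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(r1$p_value, fisher_enum(10, 0, 0, 10), tolerance = 1e-9)
  expect_equal(r1$class_a_altered, 10L)
})

test_that("planted class-specific losses survive BH among null segments", {
  set.seed(77)
  n <- 40; n_seg <- 500; n_signal <- 5
  feats <- data.frame(feature_id = paste0("f", 1:n_seg), chrom = "1",
                      start = 1:n_seg * 10, end = 1:n_seg * 10 + 5)
  calls <- matrix(0L, n_seg, 2 * n,
                  dimnames = list(feats$feature_id,
                                  c(paste0("a", 1:n), paste0("b", 1:n))))
  # null segments: sparse random losses in both classes
  noise <- matrix(rbinom(n_seg * 2 * n, 1, 0.05), n_seg) * -1L
  calls <- calls + noise
  # planted: loss at 0.8 vs 0.1 penetrance
  for (i in seq_len(n_signal)) {
    calls[i, 1:n] <- -as.integer(runif(n) < 0.8)
    calls[i, n + 1:n] <- -as.integer(runif(n) < 0.1)
  }
  cn <- cn_table(feats, calls + 0, calls)
  classes <- setNames(rep(c("A", "B"), each = n), colnames(calls))
  res <- segment_fisher(cn, classes, "A", "B", "loss")
  expect_true(all(res$significant[match(paste0("f", 1:n_signal), res$feature_id)]))
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
  expect_equal(res$fdr, bh_bruteforce(res$p_value), tolerance = 1e-12)
  # significant count is monotone non-increasing as the cutoff drops
  counts <- vapply(c(0.2, 0.1, 0.05, 0.01, 0.001),
                   function(q) sum(res$fdr < q), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("expression-copy-number correlation handles exact and degenerate cases", {
  feats <- data.frame(feature_id = "BAP1", chrom = "3", start = 1, end = 2)
  cnv <- matrix(c(-1, 0, 1, -1, 0, 1), 1,
                dimnames = list("BAP1", paste0("s", 1:6)))
  cn <- cn_table(feats, cnv, matrix(as.integer(cnv), 1))
  expr <- matrix(cnv, 1, dimnames = dimnames(cnv))  # expression == CN
  classes <- setNames(rep(c("X", "Y"), 3), colnames(cnv))
  res <- expr_cn_correlation(expr, cn, "BAP1", classes)
  expect_equal(res$r[res$class == "overall"], 1, tolerance = 1e-9)
  # constant CN within a class: NA with warning
  cn$calls[1, c(1, 3, 5)] <- 0L
  cn$values[1, c(1, 3, 5)] <- 0
  expect_warning(res2 <- expr_cn_correlation(expr, cn, "BAP1", classes),
                 "constant")
  expect_true(is.na(res2$r[res2$class == "X"]))
})

test_that("gene alteration frequency counts calls by direction", {
  feats <- data.frame(feature_id = "g", chrom = "1", start = 1, end = 2)
  calls <- matrix(c(-1L, 0L, 0L, 1L), 1,
                  dimnames = list("g", paste0("s", 1:4)))
  cn <- cn_table(feats, calls + 0, calls)
  cls <- setNames(rep("A", 4), colnames(calls))
  expect_equal(gene_alteration_frequency(cn, "g", cls, "loss"), c(A = 0.25))
  expect_equal(gene_alteration_frequency(cn, "g", cls, "gain"), c(A = 0.25))
  expect_equal(gene_alteration_frequency(cn, "g", cls, "any"), c(A = 0.5))
  all_loss <- matrix(rep(-1L, 4), 1, dimnames = dimnames(calls))
  cn2 <- cn_table(feats, all_loss + 0, all_loss)
  expect_equal(gene_alteration_frequency(cn2, "g", cls, "loss"), c(A = 1))
})

test_that("fisher.test equals hypergeometric enumeration on spot tables", {
  for (tab in list(c(2, 0, 0, 2), c(3, 5, 2, 8), c(0, 7, 4, 1), c(6, 6, 6, 6))) {
    ft <- fisher.test(matrix(tab, 2))$p.value
    expect_equal(ft, fisher_enum(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})
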