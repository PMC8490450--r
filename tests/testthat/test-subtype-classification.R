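# Gene filtering, centering, centroid correlation and the subtype rules.

test_that("filter_genes keeps expressed genes and ranks by MAD", {
  m <- rbind(flat = rep(5, 6),
             var1 = c(1, 9, 1, 9, 1, 9) + 2,
             var2 = c(4, 6, 4, 6, 4, 6),
             low  = rep(0.2, 6))
  colnames(m) <- paste0("s", 1:6)
  # hand MADs: flat 0, var1 and var2 positive, low filtered out by floor
  expect_identical(filter_genes(m, min_expr = 1, min_expr_fraction = 0.7,
                                top_n_variable = 2),
                   c("var1", "var2"))
  # constant gene excluded whenever top_n < total survivors
  expect_false("flat" %in% filter_genes(m, 1, 0.7, 2))
  # fraction 0 passes the floor for everything
  expect_setequal(filter_genes(m, 10, 0, 4), rownames(m))
  expect_warning(filter_genes(m, 1, 0.7, 10), "exceeds")
})

test_that("median_center zeroes gene medians and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(0, 0, 10))
  colnames(m) <- paste0("s", 1:3)
  cm <- median_center(m)
  expect_equal(unname(cm["a", ]), c(-1, 0, 1))
  expect_equal(unname(cm["b", ]), c(0, 0, 10))
  expect_true(is_centered(cm))
  expect_equal(unclass(median_center(cm)), unclass(cm), ignore_attr = TRUE)
})

test_that("spearman_to_centroid matches the closed form", {
  m <- matrix(c(1, 2, 3, 4,          # identical ranks
                4, 3, 2, 1,          # reversed ranks
                2, 1, 4, 3),         # d^2 sum = 4 -> rho = 0.6
              4, dimnames = list(paste0("g", 1:4), c("same", "rev", "mix")))
  centroid <- setNames(c(10, 20, 30, 40), paste0("g", 1:4))
  rho <- spearman_to_centroid(m, centroid)
  expect_equal(unname(rho), c(1, -1, 0.6), tolerance = 1e-12)
  expect_error(spearman_to_centroid(m[1:2, , drop = FALSE], centroid[1:2]),
               "at least 3")
})

test_that("the CCA-Like threshold is mean - 1 sample SD, inclusive", {
  rhos <- c(c1 = 0.80, c2 = 0.75, c3 = 0.70, h1 = 0.72, h2 = 0.70, h3 = 0.40)
  res <- classify_cca_like(rhos, c("c1", "c2", "c3"))
  expect_equal(res$threshold, 0.70, tolerance = 1e-12)
  expect_equal(unname(res$labels[c("h1", "h2", "h3")]),
               c("CCA-Like", "CCA-Like", "HCC"))   # h2 exactly at threshold
  expect_equal(unname(res$labels[c("c1", "c2", "c3")]), rep("CCA", 3))
  # brute-force recomputation of the threshold
  cca <- rhos[1:3]
  expect_equal(res$threshold,
               sum(cca) / 3 - sqrt(sum((cca - mean(cca))^2) / 2))
  # all below threshold: no CCA-Like
  res2 <- classify_cca_like(c(rhos[1:3], h1 = 0.1, h2 = 0.2), c("c1", "c2", "c3"))
  expect_false(any(res2$labels == "CCA-Like"))
  expect_error(classify_cca_like(rhos[-1], c("c1", "c2")), "missing")
})

test_that("the Blast-Like rule takes the upper tertile, inclusive, CCA-Like exempt", {
  rhos <- setNames(seq(0.1, 0.9, by = 0.1), paste0("t", 1:9))
  labels <- setNames(rep("HCC", 9), names(rhos))
  res <- classify_blast_like(rhos, labels)
  expect_equal(res$tertile_cutoff, unname(quantile(rhos, 2 / 3, type = 7)))
  expect_setequal(names(res$labels)[res$labels == "Blast-Like"],
                  c("t7", "t8", "t9"))
  # everyone already CCA-Like: nothing to relabel
  all_cl <- setNames(rep("CCA-Like", 9), names(rhos))
  res2 <- classify_blast_like(rhos, all_cl)
  expect_false(any(res2$labels == "Blast-Like"))
  # ties at the cutoff are all included
  rhos3 <- setNames(c(0.1, 0.2, 0.5, 0.5, 0.5, 0.5), paste0("t", 1:6))
  labels3 <- setNames(rep("HCC", 6), names(rhos3))
  res3 <- classify_blast_like(rhos3, labels3)
  expect_equal(sum(res3$labels == "Blast-Like"), 4L)
})

test_that("cohort merging anchors per-gene medians", {
  ga <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3,
               dimnames = list(c("g1", "g2", "g3"), c("a1", "a2", "a3")))
  gb <- ga + 3
  colnames(gb) <- c("b1", "b2", "b3")
  merged <- merge_cohorts(ga, gb, colnames(ga), colnames(gb))
  expect_equal(ncol(merged), 6L)
  # per-gene anchor medians agree after merging
  expect_equal(apply(merged[, 1:3], 1, median), apply(merged[, 4:6], 1, median),
               tolerance = 1e-9)
  # the shift equals the anchor-median difference (+3 here)
  expect_equal(merged[, "a1"], ga[, "a1"] + 3, ignore_attr = TRUE)
  # identical anchors: shift 0, plain concatenation
  gb2 <- ga; colnames(gb2) <- c("b1", "b2", "b3")
  merged2 <- merge_cohorts(ga, gb2, colnames(ga), colnames(gb2))
  expect_equal(unclass(merged2), cbind(ga, gb2), ignore_attr = TRUE)
  # order invariance of samples
  merged3 <- merge_cohorts(ga[, c(3, 1, 2)], gb, colnames(ga), colnames(gb))
  expect_equal(merged3[, colnames(merged)], merged[, colnames(merged)],
               ignore_attr = TRUE)
})

test_that("noise-free mixtures are recovered exactly", {
  cfg <- sim_config(n_per_class = c("CCA" = 8L, "CCA-Like" = 8L,
                                    "Blast-Like" = 8L, "HCC" = 8L),
                    n_genes = 600L, markers_per_program = 80L,
                    noise_sd = 0, seed = 7L)
  co <- simulate_expression(cfg)
  cca_ids <- names(co$truth$true_class)[co$truth$true_class == "CCA"]
  asg <- assign_subtypes(co$expr, cca_ids, co$centroids,
                         config = list(min_expr = 1, min_expr_fraction = 0.7,
                                       top_n_variable = 400L))
  expect_identical(asg$label, unname(co$truth$true_class[asg$sample_id]))
})

test_that("labels are invariant to a strictly monotone per-sample transform", {
  cfg <- sim_config(n_per_class = c("CCA" = 10L, "CCA-Like" = 10L,
                                    "Blast-Like" = 10L, "HCC" = 10L),
                    n_genes = 600L, markers_per_program = 80L, seed = 21L)
  co <- simulate_expression(cfg)
  cca_ids <- names(co$truth$true_class)[co$truth$true_class == "CCA"]
  config <- list(min_expr = -Inf, min_expr_fraction = 0, top_n_variable = 600L)
  asg1 <- assign_subtypes(co$expr, cca_ids, co$centroids, config = config)
  # increasing affine transform commutes with median centering, so the whole
  # pipeline is invariant to it
  tr <- expression_matrix(2 * unclass(co$expr) + 3)
  asg2 <- assign_subtypes(tr, cca_ids, co$centroids, config = config)
  expect_identical(asg2$label, asg1$label)
  # the correlation step itself is invariant to any strictly monotone
  # per-sample transform (Spearman sees only ranks)
  centered <- median_center(co$expr)
  rho_a <- spearman_to_centroid(centered, co$centroids$hepatoblast)
  rho_b <- spearman_to_centroid(exp(unclass(centered) / 4), co$centroids$hepatoblast)
  expect_equal(rho_a, rho_b, tolerance = 1e-12)
})

test_that("normals pass through and a CCA-only cohort stays CCA", {
  cfg <- sim_config(n_per_class = c("CCA" = 8L, "CCA-Like" = 6L,
                                    "Blast-Like" = 6L, "HCC" = 6L),
                    n_normal = 5L, n_genes = 600L, markers_per_program = 80L,
                    seed = 5L)
  co <- simulate_expression(cfg)
  tc <- co$truth$true_class
  asg <- assign_subtypes(co$expr, names(tc)[tc == "CCA"], co$centroids,
                         config = list(min_expr = 1, min_expr_fraction = 0.7,
                                       top_n_variable = 400L),
                         normal_ids = names(tc)[tc == "Normal"])
  expect_true(all(asg$label[match(names(tc)[tc == "Normal"], asg$sample_id)] == "Normal"))

  only_cca <- co$expr[, names(tc)[tc == "CCA"]]
  asg2 <- assign_subtypes(expression_matrix(only_cca), names(tc)[tc == "CCA"],
                          co$centroids,
                          config = list(min_expr = 1, min_expr_fraction = 0.7,
                                        top_n_variable = 400L))
  expect_true(all(asg2$label == "CCA"))
})

test_that("assignment is deterministic and records its cutoffs", {
  cfg <- sim_config(n_per_class = c("CCA" = 8L, "CCA-Like" = 8L,
                                    "Blast-Like" = 8L, "HCC" = 8L),
                    n_genes = 600L, markers_per_program = 80L, seed = 13L)
  co <- simulate_expression(cfg)
  cca_ids <- names(co$truth$true_class)[co$truth$true_class == "CCA"]
  config <- list(min_expr = 1, min_expr_fraction = 0.7, top_n_variable = 400L)
  a1 <- assign_subtypes(co$expr, cca_ids, co$centroids, config = config)
  a2 <- assign_subtypes(co$expr, cca_ids, co$centroids, config = config)
  expect_identical(a1, a2)
  expect_true(all(a1$rho_cca[a1$label == "CCA-Like"] >= a1$threshold_used))
  bl <- a1$label == "Blast-Like"
  expect_true(all(a1$rho_hepatoblast[bl] >= a1$tertile_cutoff_used))
  expect_true(all(a1$rho_cca[bl] < a1$threshold_used))
})
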