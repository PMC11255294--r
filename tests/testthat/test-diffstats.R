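test_that("rank-sum AUC matches pairwise counting on fixed examples", {
  r <- rank_sum_auc(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$auc, 1)
  expect_equal(r$U, 9)

  expect_equal(rank_sum_auc(c(1, 2), c(1, 2))$auc, 0.5)

  r3 <- rank_sum_auc(c(2, 4, 6), c(1, 3, 5))
  expect_equal(r3$U, 6)
  expect_equal(r3$auc, 6 / 9)
})

test_that("AUC complementarity and exact p equal enumeration on random data", {
  withr::local_seed(13)
  for (i in 1:40) {
    n_a <- sample(2:6, 1)
    n_b <- sample(2:6, 1)
    a <- sample(1:6, n_a, replace = TRUE)  # plenty of ties
    b <- sample(1:6, n_b, replace = TRUE)
    fwd <- rank_sum_auc(a, b)
    rev <- rank_sum_auc(b, a)
    expect_equal(fwd$auc + rev$auc, 1)
    expect_equal(fwd$auc, oracle_auc(a, b))
    expect_equal(fwd$p, oracle_exact_p(a, b))
    alt <- sample(c("greater", "less"), 1)
    expect_equal(rank_sum_auc(a, b, alternative = alt)$p,
                 oracle_exact_p(a, b, alternative = alt))
  }
  expect_error(rank_sum_auc(numeric(0), 1), "non-empty")
})

test_that("large-sample p approximates the exact Wilcoxon closely", {
  withr::local_seed(14)
  a <- rnorm(30, 0.5)
  b <- rnorm(25)
  ours <- rank_sum_auc(a, b)$p
  ref <- wilcox.test(a, b, correct = TRUE, exact = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.05, 1.0)), c(0.10, 1.0))
  withr::local_seed(15)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p))
  # monotone: sorted inputs yield non-decreasing padj
  expect_true(all(diff(bh_adjust(sort(p))) >= 0))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("one-vs-rest differential testing recovers planted signatures", {
  d <- small_multiome(seed = 42)
  labels <- d$truth$labels
  nr <- lognorm_rna(d$rna)
  diff <- differential_features(nr, labels[colnames(nr)], "ILC2")
  sig <- d$truth$signature_genes$ILC2
  hits <- diff$feature_id[diff$padj < 0.05 & diff$avg_log2fc > 0]
  expect_gte(mean(sig %in% hits), 0.95)
  # a feature identical in both groups scores auc 0.5, lfc 0
  flat <- matrix(1, 1, length(labels),
                 dimnames = list("flat", names(labels)))
  m2 <- rbind(as.matrix(nr)[1:3, ], flat)
  d2 <- differential_features(m2, labels, "ILC2")
  expect_equal(d2[d2$feature_id == "flat", "auc"], 0.5)
  expect_equal(d2[d2$feature_id == "flat", "avg_log2fc"], 0)
})

test_that("NB Wald statistics vanish on constant regions", {
  counts <- matrix(50, 3, 6,
                   dimnames = list(paste0("r", 1:3), paste0("s", 1:6)))
  counts[2, ] <- c(10, 10, 10, 10, 10, 10)
  counts[3, ] <- 0
  res <- nb_wald_differential(counts, rep(c("A", "B"), each = 3))
  expect_lt(abs(res$log2fc[1]), 1e-6)
  expect_gt(res$p[1], 0.99)
  expect_true(is.na(res$padj[3]))
})

test_that("NB Wald agrees with DESeq2 discoveries on planted data", {
  skip_if_not_installed("DESeq2")
  b <- generate_bulk_counts(600, 3, 60, 2, seed = 77)
  ours <- nb_wald_differential(b$counts, b$condition)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    b$counts, data.frame(condition = factor(b$condition)), ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  our_hits <- ours$feature_id[!is.na(ours$padj) & ours$padj < 0.05]
  ref_hits <- rownames(ref)[!is.na(ref$padj) & ref$padj < 0.05]
  jac <- length(intersect(our_hits, ref_hits)) /
    length(union(our_hits, ref_hits))
  expect_gt(jac, 0.7)
  expect_gt(cor(ours$log2fc, ref$log2FoldChange, use = "complete.obs"),
            0.98)
})

test_that("Spearman correlation equals rank-then-Pearson and is monotone-invariant", {
  expect_equal(spearman_corr(1:10, (1:10)^3), 1)
  expect_equal(spearman_corr(1:10, rev(1:10)), -1)
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 1, 2)), -0.5)
  withr::local_seed(16)
  x <- rnorm(40)
  y <- rnorm(40)
  expect_equal(spearman_corr(x, y), cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_equal(spearman_corr(exp(x), y), spearman_corr(x, y))
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("the condition linear model reduces to the two-sample t test", {
  withr::local_seed(17)
  scores <- c(rnorm(20), rnorm(15, 0.4))
  cond <- rep(c("pre", "post"), c(20, 15))
  res <- ols_condition_test(scores, cond, reference = "pre")
  tt <- t.test(scores[cond == "post"], scores[cond == "pre"],
               var.equal = TRUE)
  expect_equal(res$coefficients$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$coefficients$t, unname(tt$statistic), tolerance = 1e-10)

  # identical groups: coefficient 0, p = 1
  same <- rep(c(1, 2, 3), 2)
  r2 <- ols_condition_test(same, rep(c("a", "b"), each = 3))
  expect_equal(r2$coefficients$estimate, 0)
  expect_equal(r2$coefficients$p, 1)
  expect_error(ols_condition_test(1:4, c("a", "a", "a", "b")), ">= 2")
})
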