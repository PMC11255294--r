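test_that("condition region sets split by direction and validate emptiness", {
  tab <- data.frame(feature_id = paste0("r", 1:6),
                    log2fc = c(2, -1, 3, -2, 0.5, -0.1),
                    padj = c(0.01, 0.01, 0.2, 0.04, 0.01, 0.6))
  up <- derive_condition_regions(tab, "up")
  dn <- derive_condition_regions(tab, "down")
  expect_setequal(up, c("r1", "r5"))
  expect_setequal(dn, c("r2", "r4"))
  expect_length(intersect(up, dn), 0)

  none <- data.frame(feature_id = "r1", log2fc = 1, padj = 1)
  expect_error(derive_condition_regions(none, "up"), "no region")
})

test_that("control-region sampling is seeded and bounded", {
  pool <- make_regions("chr1", (0:99) * 1000, (0:99) * 1000 + 500)
  s1 <- sample_control_regions(pool, 20, seed = 4)
  s2 <- sample_control_regions(pool, 20, seed = 4)
  expect_identical(GenomicRanges::start(s1), GenomicRanges::start(s2))
  s3 <- sample_control_regions(pool, 20, seed = 5)
  expect_false(identical(GenomicRanges::start(s1),
                         GenomicRanges::start(s3)))
  all_of_them <- sample_control_regions(pool, 100, seed = 1)
  expect_length(all_of_them, 100)
  expect_error(sample_control_regions(pool, 101), "exceeds")
})

test_that("patient scoring produces equal scores for identical nuclei", {
  regions <- make_regions("chr1", c(0, 1000), c(500, 1500))
  frag <- function(barcodes) {
    make_fragments("chr1", rep(c(100, 1100), length(barcodes)),
                   rep(c(200, 1200), length(barcodes)),
                   rep(barcodes, each = 2))
  }
  samples <- list(
    list(sample_id = "s1", condition = "A", fragments = frag(c("a1", "a2")),
         barcodes = c("a1", "a2")),
    list(sample_id = "s2", condition = "B", fragments = frag(c("b1", "b2")),
         barcodes = c("b1", "b2")))
  st <- score_patient_samples(samples, regions)
  expect_true(all(abs(st$score - st$score[1]) < 1e-12))
  expect_equal(st$condition, c("A", "A", "B", "B"))
})

test_that("nuclei without fragments at the set are dropped with a warning", {
  regions <- make_regions("chr1", 0, 500)
  samples <- list(list(
    sample_id = "s1", condition = "A",
    fragments = make_fragments("chr1", 100, 200, "n1"),
    barcodes = c("n1", "n_empty")))
  expect_warning(st <- score_patient_samples(samples, regions), "zero")
  expect_equal(st$cell_id, "n1")
})

test_that("condition comparison reports top-90% subsets and the t test", {
  withr::local_seed(71)
  st <- data.frame(cell_id = sprintf("n%03d", 1:120),
                   sample_id = rep(c("s1", "s2", "s3", "s4"), each = 30),
                   condition = rep(c("pre", "post"), each = 60),
                   score = c(rnorm(60), rnorm(60, 0.8)))
  cc <- compare_conditions(st, reference = "pre")
  expect_equal(vapply(cc$display_scores, length, integer(1)),
               setNames(rep(27L, 4), c("s1", "s2", "s3", "s4")))
  tt <- t.test(st$score[st$condition == "post"],
               st$score[st$condition == "pre"], var.equal = TRUE)
  expect_equal(cc$model$coefficients$p, tt$p.value, tolerance = 1e-10)

  grouped <- compare_conditions(st, grouping = c(pre = "any", post = "any2"),
                                reference = "any")
  expect_equal(grouped$model$coefficients$level, "any2")
  expect_error(compare_conditions(st, grouping = c(pre = "x")), "misses")
})

test_that("monotone planted fractions yield monotone condition means", {
  sig <- make_regions("chrS", (0:39) * 2500, (0:39) * 2500 + 500)
  bg <- make_regions("chrB", (0:79) * 2500, (0:79) * 2500 + 500)
  pools <- generate_patient_pools(2, 50, sig, bg,
                                  c(low = 0.1, mid = 0.4, high = 0.8),
                                  depth = 300, seed = 72)
  st <- score_patient_samples(pools$samples, sig)
  means <- tapply(st$score, st$condition, mean)[c("low", "mid", "high")]
  expect_true(all(diff(means) > 0))
})

test_that("gene-score differential finds nothing between identical samples", {
  genes <- make_regions("chr1", (0:19) * 5000, (0:19) * 5000 + 2000,
                        id = sprintf("g%02d", 1:20),
                        strand = rep(c("+", "-"), 10))
  withr::local_seed(73)
  base_frag <- function(seed, barcode) {
    withr::with_seed(seed, {
      s0 <- sample.int(100000, 400)
      make_fragments("chr1", s0, s0 + 100, rep(barcode, 400))
    })
  }
  samples <- lapply(1:6, function(i) {
    list(sample_id = paste0("s", i),
         condition = rep(c("pre", "post"), each = 3)[i],
         fragments = base_frag(1000 + i, paste0("n", i)),
         barcodes = paste0("n", i))
  })
  res <- gene_score_differential(samples, genes)
  expect_equal(sum(res$padj < 0.05, na.rm = TRUE), 0)
})
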