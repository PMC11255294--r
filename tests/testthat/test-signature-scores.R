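test_that("signature mean expression equals the column-mean oracle", {
  withr::local_seed(23)
  m <- matrix(rexp(60 * 15), 60, 15,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("c%02d", 1:15)))
  genes <- sample(rownames(m), 20)
  sig <- signature_set("T", genes)
  sc <- mean_expression_score(m, sig)
  expect_equal(as.numeric(sc), unname(colMeans(m[genes, ])),
               tolerance = 1e-12)
  expect_equal(attr(sc, "fraction_found"), 1)

  one <- signature_set("one", rownames(m)[5])
  expect_equal(as.numeric(mean_expression_score(m, one)), m[5, ],
               ignore_attr = TRUE)

  zero <- matrix(0, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_equal(as.numeric(mean_expression_score(zero,
                                                signature_set("z", "a"))),
               c(0, 0, 0))
  expect_error(mean_expression_score(m, signature_set("none", "absent")),
               "no genes")
})

test_that("fragment-region counting equals the quadratic overlap oracle", {
  withr::local_seed(24)
  for (i in 1:3) {
    frag_df <- random_fragment_df(300, n_cells = 6)
    rs0 <- sort(sample.int(4800, 40)) - 1L
    region_df <- data.frame(chrom = sample(c("chr1", "chr2"), 40,
                                           replace = TRUE),
                            start = rs0, end = rs0 + 120)
    # drop overlapping regions so the oracle needs no merge logic
    keep <- rep(TRUE, 40)
    for (a in 2:40) for (b in 1:(a - 1)) {
      if (keep[b] && region_df$chrom[a] == region_df$chrom[b] &&
          max(region_df$start[c(a, b)]) < min(region_df$end[c(a, b)])) {
        keep[a] <- FALSE
      }
    }
    region_df <- region_df[keep, ]
    cells <- paste0("c", 1:6)
    ids <- paste0("r", seq_len(nrow(region_df)))
    counts <- region_set_fragment_counts(
      df_to_fragments(frag_df),
      make_regions(region_df$chrom, region_df$start, region_df$end,
                   id = ids),
      cell_ids = cells)
    oracle <- oracle_overlap_counts(frag_df, region_df, cells)
    rownames(oracle) <- ids
    expect_equal(as.matrix(counts)[ids, ], oracle)
  }
})

test_that("per-cell region scores reduce to column means without TF-IDF", {
  counts <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                   dimnames = list(paste0("r", 1:3), c("c1", "c2")))
  sc <- per_cell_region_score(counts, normalize = "none")
  expect_equal(as.numeric(sc), c(2, 5))
  uni <- matrix(2, 4, 3, dimnames = list(paste0("r", 1:4), paste0("c", 1:3)))
  tf <- per_cell_region_score(uni)
  expect_true(all(abs(tf - tf[1]) < 1e-12))
})

test_that("aggregate accessibility separates planted cell types", {
  d <- small_multiome(seed = 31)
  sig_peaks <- d$truth$signature_peaks$ILC2
  regions <- d$genome$peaks[match(sig_peaks,
                                  S4Vectors::mcols(d$genome$peaks)$id)]
  sc <- aggregate_gene_accessibility(d$fragments, regions,
                                     cell_ids = colnames(d$atac))
  labels <- d$truth$labels[names(sc)]
  r <- rank_sum_auc(sc[labels == "ILC2"], sc[labels == "ILC1"])
  expect_gt(r$auc, 0.95)
})

test_that("rank classification labels by mean signature rank with ties undetermined", {
  sigs <- list(signature_set("A", c("g1", "g2")),
               signature_set("B", c("g3", "g4")))
  m <- matrix(c(5, 6, 0, 0,
                0, 0, 5, 6,
                3, 4, 4, 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  res <- rank_classifier(m, sigs)
  expect_equal(res$label, c("A", "B", "Undetermined"))

  # invariant to strictly monotone per-cell transforms
  withr::local_seed(25)
  rnd <- matrix(rnorm(40 * 30), 40, 30,
                dimnames = list(sprintf("g%02d", 1:40),
                                sprintf("c%02d", 1:30)))
  sigs2 <- list(signature_set("A", sprintf("g%02d", 1:8)),
                signature_set("B", sprintf("g%02d", 9:16)))
  base <- rank_classifier(rnd, sigs2)
  expect_equal(rank_classifier(exp(rnd), sigs2)$label, base$label)

  # labels equal an independent midrank recomputation
  oracle_labels <- apply(rnd, 2, function(x) {
    r <- rank(x)
    sa <- mean(r[1:8]); sb <- mean(r[9:16])
    if (abs(sa - sb) <= 1e-12) "Undetermined" else if (sa > sb) "A" else "B"
  })
  expect_equal(base$label, unname(oracle_labels))
})

test_that("gene-activity windows extend strand-aware upstream flanks", {
  genes <- make_regions("chr1", c(1000, 1000), c(2000, 2000),
                        id = c("plus", "minus"), strand = c("+", "-"))
  # "+" gene: window [0, 2000) after clipping; "-" gene: [1000, 4000)
  frags <- make_fragments("chr1", c(500, 2100, 4100), c(600, 2200, 4200),
                          c("c1", "c1", "c1"))
  m <- gene_activity_matrix(frags, genes, flank = 2000, cell_ids = "c1")
  expect_equal(as.numeric(m["plus", ]), 1)   # only [500,600)
  expect_equal(as.numeric(m["minus", ]), 1)  # only [2100,2200)
})

test_that("gene activity sums per sample and requires strands", {
  genes <- make_regions("chr1", 1000, 2000, id = "g", strand = "+")
  frags <- make_fragments("chr1", c(1100, 1200, 1300), c(1150, 1250, 1350),
                          c("n1", "n2", "n3"))
  grp <- c(n1 = "s1", n2 = "s1", n3 = "s2")
  m <- gene_activity_matrix(frags, genes, cell_ids = c("n1", "n2", "n3"),
                            group = grp)
  expect_equal(as.numeric(m["g", c("s1", "s2")]), c(2, 1))
  unstranded <- make_regions("chr1", 1, 10, id = "u")
  expect_error(gene_activity_matrix(frags, unstranded), "stranded")
})

test_that("TSS windows follow gene orientation exactly", {
  genes <- make_regions("chr1", c(1000, 1000), c(2000, 2000),
                        id = c("plus", "minus"), strand = c("+", "-"))
  # "+" TSS at 1000 -> [700, 1500); "-" TSS at 2000 -> [1500, 2300)
  probes <- list(c(699, 700), c(700, 701), c(1499, 1500), c(1500, 1501),
                 c(2299, 2300), c(2300, 2301))
  frags <- do.call(rbind, probes)
  fr <- make_fragments("chr1", frags[, 1], frags[, 2],
                       paste0("c", seq_len(nrow(frags))))
  sig <- tss_window_signal(fr, genes)
  expect_equal(unname(sig["plus"]), 2)   # [700,701) and [1499,1500) only
  expect_equal(unname(sig["minus"]), 2)  # [1500,1501) and [2299,2300) only

  # uniform tiling: signal proportional to the 800-bp window width
  tile0 <- seq(0, 4999, by = 1)
  cover <- make_fragments("chr1", tile0, tile0 + 1, "c1")
  sig2 <- tss_window_signal(cover, genes)
  expect_equal(unname(sig2), c(800, 800))
})

test_that("hierarchical clustering recovers block-structured lineage sets", {
  block <- rbind(matrix(rep(c(5, 0, 0), each = 6), 6, 3, byrow = FALSE),
                 matrix(rep(c(0, 5, 0), each = 6), 6, 3, byrow = FALSE))
  block <- block + matrix(seq(-0.1, 0.1, length.out = 36), 12, 3)
  rownames(block) <- sprintf("f%02d", 1:12)
  colnames(block) <- c("ILC1", "ILC2", "ILC3")
  sets <- lineage_specific_sets(block, k = 2)
  expect_setequal(sets$ILC1$members, sprintf("f%02d", 1:6))
  expect_setequal(sets$ILC2$members, sprintf("f%02d", 7:12))

  # permutation of feature order leaves memberships unchanged
  withr::local_seed(26)
  perm <- sample(12)
  sets2 <- lineage_specific_sets(block[perm, ], k = 2)
  expect_setequal(sets2$ILC1$members, sets$ILC1$members)

  flat <- matrix(1, 3, 3)
  expect_error(lineage_specific_sets(flat, 2), "zero variance")
  expect_error(lineage_specific_sets(block, 20), "exceeds")
})
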