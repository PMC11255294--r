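# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths: AUC by explicit pairwise counting, exact
# rank-sum p by subset enumeration, BH by the literal step-up formula,
# interval overlap by an O(n^2) scan on 0-based half-open coordinates.

oracle_auc <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    if (x > y) wins <- wins + 1 else if (x == y) wins <- wins + 0.5
  }
  wins / (length(a) * length(b))
}

oracle_exact_p <- function(a, b, alternative = "two.sided") {
  n_a <- length(a)
  n <- n_a + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * length(b) / 2
  u_all <- apply(combn(n, n_a), 2, function(ix) {
    sum(r[ix]) - n_a * (n_a + 1) / 2
  })
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
         greater = mean(u_all >= u_obs - eps),
         less = mean(u_all <= u_obs + eps))
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- sorted * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# fragments/regions as 0-based half-open data.frames:
# (chrom, start, end[, barcode, count])
oracle_overlap_counts <- function(frag_df, region_df, cell_ids) {
  out <- matrix(0, nrow = nrow(region_df), ncol = length(cell_ids),
                dimnames = list(NULL, cell_ids))
  for (i in seq_len(nrow(region_df))) {
    for (j in seq_len(nrow(frag_df))) {
      if (frag_df$chrom[j] == region_df$chrom[i] &&
          max(frag_df$start[j], region_df$start[i]) <
            min(frag_df$end[j], region_df$end[i])) {
        col <- match(frag_df$barcode[j], cell_ids)
        if (!is.na(col)) out[i, col] <- out[i, col] + frag_df$count[j]
      }
    }
  }
  out
}

# builders converting 0-based half-open coordinates to package objects
make_regions <- function(chrom, start0, end0, id = NULL, strand = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1,
                                                end = end0))
  if (!is.null(strand)) GenomicRanges::strand(gr) <- strand
  S4Vectors::mcols(gr)$id <-
    if (is.null(id)) paste0("r", seq_along(gr)) else id
  gr
}

make_fragments <- function(chrom, start0, end0, barcode, count = 1L) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1,
                                                end = end0))
  S4Vectors::mcols(gr)$barcode <- barcode
  S4Vectors::mcols(gr)$count <- as.integer(rep_len(count, length(gr)))
  gr
}

random_fragment_df <- function(n, n_cells = 5, chroms = c("chr1", "chr2"),
                               span = 5000) {
  start0 <- sample.int(span, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start0,
             end = start0 + sample.int(300, n, replace = TRUE),
             barcode = paste0("c", sample.int(n_cells, n, replace = TRUE)),
             count = sample.int(3, n, replace = TRUE))
}

df_to_fragments <- function(df) {
  make_fragments(df$chrom, df$start, df$end, df$barcode, df$count)
}

small_multiome <- function(seed = 1, n_cells = 100, rna_effect = 4,
                           atac_effect = 3) {
  generate_multiome(sim_config(
    cell_types = c(ILC1 = n_cells, ILC2 = n_cells),
    n_genes = 300, n_peaks = 600,
    signature_size_genes = 25, signature_size_peaks = 50,
    rna_effect = rna_effect, atac_effect = atac_effect,
    n_motifs = 20, motif_size = 25, seed = seed))
}
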