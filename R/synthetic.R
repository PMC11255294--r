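#' Simulation configuration for the synthetic multiome generator
#'
#' Defaults describe a two-type (ILC1/ILC2) multiome experiment with
#' negative-binomial RNA counts, near-binary Poisson peak counts, per-cell
#' library-size variation, a mitochondrial gene subset, and one planted
#' regulator whose motif peaks coincide with the ILC2 signature peaks and
#' whose gene sits in the ILC2 RNA signature.
#'
#' @param cell_types named integer vector: cells per type.
#' @param n_genes,n_peaks total features (genes include `n_mito_genes`
#'   mitochondrial genes).
#' @param signature_size_genes,signature_size_peaks signature features per
#'   type; signatures are disjoint across types.
#' @param rna_effect,atac_effect fold-change multiplier (> 1) applied to a
#'   type's signature features in cells of that type.
#' @param rna_dispersion NB dispersion alpha (variance `mu + alpha*mu^2`).
#' @param base_rna_mean,base_peak_rate baseline per-feature expected counts.
#' @param libsize_sigma log-normal sd of the per-cell library-size factor.
#' @param mito_fraction_mean target expected mitochondrial UMI fraction.
#' @param n_mito_genes number of mitochondrial genes (IDs `mt-1`, ...).
#' @param n_motifs motifs in the motif-peak map (first one is the planted
#'   regulator, the rest decoys).
#' @param motif_size member peaks per motif.
#' @param regulator_overlap fraction of the planted motif's peaks drawn from
#'   the target type's signature peaks.
#' @param seed integer seed; all randomness flows from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(cell_types = c(ILC1 = 300, ILC2 = 300),
                       n_genes = 1000, n_peaks = 2000,
                       signature_size_genes = 50, signature_size_peaks = 100,
                       rna_effect = 4, atac_effect = 3,
                       rna_dispersion = 0.5,
                       base_rna_mean = 2, base_peak_rate = 0.2,
                       libsize_sigma = 0.3,
                       mito_fraction_mean = 0.05, n_mito_genes = 10,
                       n_motifs = 60, motif_size = 50,
                       regulator_overlap = 0.8,
                       seed = 1L) {
  cfg <- list(cell_types = cell_types, n_genes = n_genes, n_peaks = n_peaks,
              signature_size_genes = signature_size_genes,
              signature_size_peaks = signature_size_peaks,
              rna_effect = rna_effect, atac_effect = atac_effect,
              rna_dispersion = rna_dispersion,
              base_rna_mean = base_rna_mean, base_peak_rate = base_peak_rate,
              libsize_sigma = libsize_sigma,
              mito_fraction_mean = mito_fraction_mean,
              n_mito_genes = n_mito_genes,
              n_motifs = n_motifs, motif_size = motif_size,
              regulator_overlap = regulator_overlap,
              seed = as.integer(seed))
  n_types <- length(cfg$cell_types)
  if (n_types < 2) stop("need at least 2 cell types")
  if (is.null(names(cfg$cell_types))) stop("cell_types must be named")
  if (any(cfg$cell_types < 1)) stop("each type needs at least one cell")
  if (cfg$rna_effect < 1 || cfg$atac_effect < 1) {
    stop("effect sizes must be >= 1")
  }
  if (cfg$mito_fraction_mean < 0 || cfg$mito_fraction_mean >= 1) {
    stop("mito_fraction_mean must be in [0,1)")
  }
  if (cfg$regulator_overlap < 0 || cfg$regulator_overlap > 1) {
    stop("regulator_overlap must be in [0,1]")
  }
  if (n_types * cfg$signature_size_genes + cfg$n_mito_genes > cfg$n_genes) {
    stop("signature genes plus mito genes exceed n_genes")
  }
  if (n_types * cfg$signature_size_peaks > cfg$n_peaks) {
    stop("signature peaks exceed n_peaks")
  }
  if (cfg$rna_dispersion <= 0) stop("rna_dispersion must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic genome layout for simulated peaks and genes
#'
#' One chromosome per 1000 peaks; 500-bp peaks spaced 2 kb apart. Gene j is
#' a 2-kb body centred on peak j, with alternating strand, so accessibility
#' planted in peak j is recovered by the gene-activity window of gene j.
#'
#' @param n_peaks,n_genes counts; requires `n_genes <= n_peaks`.
#' @return list with `peaks` (`GRanges`, unstranded, `id` column) and
#'   `genes` (`GRanges`, stranded, `id` column).
#' @export
synthetic_genome <- function(n_peaks, n_genes) {
  if (n_genes > n_peaks) stop("synthetic genome requires n_genes <= n_peaks")
  k <- seq_len(n_peaks)
  chrom <- paste0("chr", (k - 1) %/% 1000 + 1)
  start0 <- 1000 + ((k - 1) %% 1000) * 2500
  peaks <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(start = start0 + 1,
                                                   end = start0 + 500))
  S4Vectors::mcols(peaks)$id <- sprintf("peak%05d", k)
  j <- seq_len(n_genes)
  gstart0 <- pmax(start0[j] - 750, 0)
  genes <- GenomicRanges::GRanges(chrom[j],
                                  IRanges::IRanges(start = gstart0 + 1,
                                                   end = gstart0 + 2000),
                                  strand = ifelse(j %% 2 == 1, "+", "-"))
  S4Vectors::mcols(genes)$id <- sprintf("gene%04d", j)
  list(peaks = peaks, genes = genes)
}

#' Generate a synthetic multiome dataset with planted ground truth
#'
#' RNA counts are negative binomial with per-cell log-normal library-size
#' factors and a mitochondrial gene subset tuned to the target mitochondrial
#' fraction; peak counts are Poisson with type-specific enrichment of each
#' type's signature peaks; fragments are placed uniformly inside peaks (one
#' record per count unit) on the synthetic genome; one motif (the planted
#' regulator) draws most of its member peaks from the last type's signature
#' peaks and is paired with a gene in that type's RNA signature.
#'
#' @param config a [sim_config()].
#' @return list with `rna`, `atac` (cell-feature matrices), `fragments`
#'   (`GRanges` with barcode/count), `signatures` (gene sets),
#'   `peak_signatures` (region-ID sets), `motif_map`, `genome`
#'   (peaks + gene models), and `truth` (labels, signature IDs, planted
#'   regulator, TF-to-motif map).
#' @export
generate_multiome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  types <- names(cfg$cell_types)
  n_types <- length(types)
  n_cells <- sum(cfg$cell_types)
  labels <- rep(types, cfg$cell_types)
  barcodes <- sprintf("cell%05d", seq_len(n_cells))

  n_reg_genes <- cfg$n_genes - cfg$n_mito_genes
  gene_ids <- c(sprintf("gene%04d", seq_len(n_reg_genes)),
                paste0("mt-", seq_len(cfg$n_mito_genes)))
  mito_ids <- gene_ids[(n_reg_genes + 1):cfg$n_genes]
  sig_genes <- lapply(seq_len(n_types), function(t) {
    gene_ids[((t - 1) * cfg$signature_size_genes + 1):
               (t * cfg$signature_size_genes)]
  })
  names(sig_genes) <- types

  genome <- synthetic_genome(cfg$n_peaks, n_reg_genes)
  peak_ids <- S4Vectors::mcols(genome$peaks)$id
  sig_peaks <- lapply(seq_len(n_types), function(t) {
    peak_ids[((t - 1) * cfg$signature_size_peaks + 1):
               (t * cfg$signature_size_peaks)]
  })
  names(sig_peaks) <- types

  # RNA: NB(mean = base * effect^[signature of own type] * libsize)
  rna <- withr::with_seed(cfg$seed + 1L, {
    lib <- stats::rlnorm(n_cells, -cfg$libsize_sigma^2 / 2, cfg$libsize_sigma)
    mu <- matrix(cfg$base_rna_mean, nrow = cfg$n_genes, ncol = n_cells,
                 dimnames = list(gene_ids, barcodes))
    for (t in seq_len(n_types)) {
      own <- labels == types[t]
      mu[sig_genes[[t]], own] <- mu[sig_genes[[t]], own] * cfg$rna_effect
    }
    # mito means chosen so E[mito]/E[total] matches the target fraction
    nonmito_total <- Matrix::colSums(mu[seq_len(n_reg_genes), , drop = FALSE])
    m <- cfg$mito_fraction_mean
    mito_per_gene <- nonmito_total * m / (1 - m) / cfg$n_mito_genes
    mu[mito_ids, ] <- matrix(mito_per_gene, nrow = cfg$n_mito_genes,
                             ncol = n_cells, byrow = TRUE)
    mu <- sweep(mu, 2, lib, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / cfg$rna_dispersion),
                     nrow = cfg$n_genes, dimnames = dimnames(mu))
    cell_feature_matrix(counts, modality = "rna")
  })

  # ATAC: Poisson(rate * effect^[signature of own type] * libsize)
  atac <- withr::with_seed(cfg$seed + 2L, {
    lib <- stats::rlnorm(n_cells, -cfg$libsize_sigma^2 / 2, cfg$libsize_sigma)
    rate <- matrix(cfg$base_peak_rate, nrow = cfg$n_peaks, ncol = n_cells,
                   dimnames = list(peak_ids, barcodes))
    for (t in seq_len(n_types)) {
      own <- labels == types[t]
      rate[sig_peaks[[t]], own] <- rate[sig_peaks[[t]], own] * cfg$atac_effect
    }
    rate <- sweep(rate, 2, lib, `*`)
    counts <- matrix(stats::rpois(length(rate), as.vector(rate)),
                     nrow = cfg$n_peaks, dimnames = dimnames(rate))
    cell_feature_matrix(counts, modality = "atac_peak")
  })

  # fragments: one record per ATAC count unit, uniform inside the peak
  fragments <- withr::with_seed(cfg$seed + 3L, {
    sp <- .as_sparse(atac)
    trip <- Matrix::summary(sp)
    peak_idx <- rep(trip$i, trip$x)
    cell_idx <- rep(trip$j, trip$x)
    frag_len <- 100L
    p_start0 <- GenomicRanges::start(genome$peaks)[peak_idx] - 1L
    off <- floor(stats::runif(length(peak_idx), 0,
                              GenomicRanges::width(genome$peaks)[peak_idx] -
                                frag_len + 1))
    s0 <- p_start0 + off
    gr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(genome$peaks))[peak_idx],
      IRanges::IRanges(start = s0 + 1, end = s0 + frag_len))
    S4Vectors::mcols(gr)$barcode <- barcodes[cell_idx]
    S4Vectors::mcols(gr)$count <- 1L
    gr
  })

  # planted regulator + decoy motifs
  target_type <- types[n_types]
  motif_map <- withr::with_seed(cfg$seed + 4L, {
    motif_ids <- c(sprintf("motif%03d_%s", 1L, "regulator"),
                   sprintf("motif%03d", seq_len(cfg$n_motifs)[-1]))
    n_in_sig <- round(cfg$regulator_overlap * cfg$motif_size)
    nonsig <- setdiff(peak_ids, unlist(sig_peaks))
    planted <- c(sample(sig_peaks[[target_type]], n_in_sig),
                 sample(nonsig, cfg$motif_size - n_in_sig))
    member <- lapply(seq_len(cfg$n_motifs), function(k) {
      if (k == 1) planted else sample(nonsig, cfg$motif_size)
    })
    i <- rep(seq_len(cfg$n_motifs), lengths(member))
    j <- match(unlist(member), peak_ids)
    motif_peak_map(Matrix::sparseMatrix(i = i, j = j, x = 1,
                                        dims = c(cfg$n_motifs, cfg$n_peaks)),
                   motif_ids, peak_ids)
  })
  regulator_motif <- rownames(motif_map$membership)[1]
  regulator_gene <- sig_genes[[target_type]][1]
  decoy_genes <- setdiff(gene_ids[seq_len(n_reg_genes)],
                         unlist(sig_genes))[seq_len(cfg$n_motifs - 1)]
  tf_motif_map <- data.frame(
    gene = c(regulator_gene, decoy_genes),
    motif = rownames(motif_map$membership),
    stringsAsFactors = FALSE)

  signatures <- lapply(types, function(t) signature_set(t, sig_genes[[t]]))
  names(signatures) <- types
  peak_signatures <- lapply(types, function(t) {
    signature_set(t, sig_peaks[[t]], kind = "region")
  })
  names(peak_signatures) <- types

  list(rna = rna, atac = atac, fragments = fragments,
       signatures = signatures, peak_signatures = peak_signatures,
       motif_map = motif_map, genome = genome,
       truth = list(labels = stats::setNames(labels, barcodes),
                    signature_genes = sig_genes, signature_peaks = sig_peaks,
                    mito_genes = mito_ids,
                    regulator_gene = regulator_gene,
                    regulator_motif = regulator_motif,
                    target_type = target_type,
                    tf_motif_map = tf_motif_map))
}

#' Generate replicate-level bulk accessibility counts with planted effects
#'
#' Negative-binomial counts on a lognormal baseline across regions, with
#' log-normal per-sample size factors and the first `n_differential` regions
#' shifted by `planted_log2fc` in condition B.
#'
#' @param n_regions number of regions.
#' @param n_replicates_per_condition replicates in each of conditions A, B.
#' @param n_differential planted differential regions (0 for a null run).
#' @param planted_log2fc log2 fold change applied in condition B.
#' @param dispersion NB dispersion alpha.
#' @param seed integer seed.
#' @param base_mean_log_mean,base_mean_log_sd lognormal parameters of the
#'   per-region baseline mean.
#' @param sf_sigma log-normal sd of per-sample size factors.
#' @return list with `counts` (regions x samples), `condition` (labels) and
#'   `truth` (differential region IDs and their log2FC).
#' @export
generate_bulk_counts <- function(n_regions, n_replicates_per_condition,
                                 n_differential, planted_log2fc,
                                 dispersion = 0.1, seed = 1L,
                                 base_mean_log_mean = log(100),
                                 base_mean_log_sd = 0.7,
                                 sf_sigma = 0.2) {
  if (n_differential > n_regions) stop("n_differential exceeds n_regions")
  if (n_replicates_per_condition < 2) stop("need >= 2 replicates per condition")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (planted_log2fc == 0) n_differential <- 0L
  withr::with_seed(as.integer(seed), {
    n_rep <- n_replicates_per_condition
    condition <- rep(c("A", "B"), each = n_rep)
    sample_ids <- paste0(condition, rep(seq_len(n_rep), 2))
    region_ids <- sprintf("region%05d", seq_len(n_regions))
    base <- stats::rlnorm(n_regions, base_mean_log_mean, base_mean_log_sd)
    lfc <- numeric(n_regions)
    if (n_differential > 0) lfc[seq_len(n_differential)] <- planted_log2fc
    sf <- stats::rlnorm(2 * n_rep, -sf_sigma^2 / 2, sf_sigma)
    mu <- outer(base, sf) * 2^outer(lfc, as.numeric(condition == "B"))
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / dispersion),
                     nrow = n_regions,
                     dimnames = list(region_ids, sample_ids))
    list(counts = counts, condition = condition,
         truth = list(differential = region_ids[lfc != 0],
                      log2fc = lfc[lfc != 0]))
  })
}

#' Generate pooled patient-like nuclei with condition-dependent fractions
#'
#' Each nucleus is signature-positive (fragment rate in signature regions
#' multiplied by `positive_boost`) with its condition's probability; all
#' nuclei share the background-region rate. Fragments are placed uniformly
#' inside regions, one record per count unit.
#'
#' @param n_samples_per_condition samples per condition.
#' @param nuclei_per_sample nuclei per sample.
#' @param signature_regions,background_regions `GRanges` region sets.
#' @param positive_fraction_by_condition named numeric in `[0,1]`, one entry
#'   per condition.
#' @param depth expected fragments per (negative) nucleus.
#' @param seed integer seed.
#' @param positive_boost rate multiplier in signature regions for positive
#'   nuclei.
#' @return list with `samples` (each: sample_id, condition, fragments,
#'   barcodes), the two region sets, and `truth` (per-nucleus positivity and
#'   the planted fractions).
#' @export
generate_patient_pools <- function(n_samples_per_condition, nuclei_per_sample,
                                   signature_regions, background_regions,
                                   positive_fraction_by_condition,
                                   depth = 500, seed = 1L,
                                   positive_boost = 3) {
  if (length(signature_regions) == 0 || length(background_regions) == 0) {
    stop("region sets must be non-empty")
  }
  fr <- positive_fraction_by_condition
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0,1]")
  if (is.null(names(fr))) names(fr) <- paste0("cond", seq_along(fr))
  regions <- suppressWarnings(c(signature_regions, background_regions))
  n_sig <- length(signature_regions)
  n_all <- length(regions)
  base_rate <- depth / n_all
  withr::with_seed(as.integer(seed), {
    samples <- list()
    truth_rows <- list()
    for (ci in seq_along(fr)) {
      for (si in seq_len(n_samples_per_condition)) {
        sample_id <- paste0(names(fr)[ci], "_s", si)
        barcodes <- sprintf("%s_n%04d", sample_id, seq_len(nuclei_per_sample))
        positive <- stats::runif(nuclei_per_sample) < fr[ci]
        rate <- matrix(base_rate, nrow = n_all, ncol = nuclei_per_sample)
        rate[seq_len(n_sig), positive] <- base_rate * positive_boost
        counts <- matrix(stats::rpois(length(rate), as.vector(rate)),
                         nrow = n_all)
        trip <- Matrix::summary(.as_sparse(counts))
        region_idx <- rep(trip$i, trip$x)
        nuc_idx <- rep(trip$j, trip$x)
        w <- GenomicRanges::width(regions)[region_idx]
        frag_len <- pmin(100L, w)
        off <- floor(stats::runif(length(region_idx), 0, w - frag_len + 1))
        s1 <- GenomicRanges::start(regions)[region_idx] + off
        gr <- GenomicRanges::GRanges(
          as.character(GenomicRanges::seqnames(regions))[region_idx],
          IRanges::IRanges(start = s1, end = s1 + frag_len - 1))
        S4Vectors::mcols(gr)$barcode <- barcodes[nuc_idx]
        S4Vectors::mcols(gr)$count <- 1L
        samples[[sample_id]] <- list(sample_id = sample_id,
                                     condition = names(fr)[ci],
                                     fragments = gr, barcodes = barcodes)
        truth_rows[[sample_id]] <- data.frame(sample_id = sample_id,
                                              condition = names(fr)[ci],
                                              barcode = barcodes,
                                              positive = positive)
      }
    }
    list(samples = samples,
         signature_regions = signature_regions,
         background_regions = background_regions,
         truth = list(nuclei = do.call(rbind, truth_rows),
                      positive_fraction = fr))
  })
}
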