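#' Per-cell mean expression over a gene signature
#'
#' Averages normalized expression over the signature genes present in the
#' matrix; absent genes are dropped (the fraction found is attached as an
#' attribute, and a message reports it when genes are missing).
#'
#' @param norm_rna genes x cells normalized matrix.
#' @param signature a gene [signature_set()].
#' @return named numeric, one score per cell, with attribute
#'   `fraction_found`.
#' @export
mean_expression_score <- function(norm_rna, signature) {
  stopifnot(inherits(signature, "signature_set"))
  present <- intersect(signature$members, rownames(norm_rna))
  if (length(present) == 0) {
    stop("no genes of signature '", signature$name, "' present in matrix")
  }
  frac <- length(present) / length(signature$members)
  if (frac < 1) {
    message("signature '", signature$name, "': ",
            round(100 * frac, 1), "% of genes present")
  }
  scores <- Matrix::colMeans(norm_rna[present, , drop = FALSE])
  scores <- stats::setNames(as.numeric(scores), colnames(norm_rna))
  attr(scores, "fraction_found") <- frac
  scores
}

#' Count fragments overlapping a region set, per cell
#'
#' Overlapping regions are merged first; a fragment contributes its count
#' to every merged region it overlaps (half-open overlap semantics: a
#' fragment ending where a region starts does not overlap it).
#'
#' @param fragments `GRanges` with `barcode` and `count` metadata columns.
#' @param regions `GRanges` region set.
#' @param cell_ids barcodes defining the columns (order preserved); default
#'   is barcodes in order of first appearance. Fragments from other
#'   barcodes are ignored.
#' @return sparse regions x cells count matrix (modality `atac_peak`).
#' @export
region_set_fragment_counts <- function(fragments, regions, cell_ids = NULL) {
  ids <- S4Vectors::mcols(regions)$id
  # min.gapwidth = 0: merge truly overlapping regions only, never
  # book-ended ones (which do not overlap under half-open semantics)
  merged <- GenomicRanges::reduce(regions, with.revmap = TRUE,
                                  ignore.strand = TRUE, min.gapwidth = 0L)
  revmap <- S4Vectors::mcols(merged)$revmap
  mids <- if (is.null(ids)) NULL else {
    vapply(revmap, function(ix) paste(ids[ix], collapse = ";"), character(1))
  }
  if (is.null(mids) || anyNA(mids) || anyDuplicated(mids)) {
    mids <- paste0(as.character(GenomicRanges::seqnames(merged)), ":",
                   GenomicRanges::start(merged) - 1, "-",
                   GenomicRanges::end(merged))
  }
  GenomicRanges::strand(merged) <- "*"
  barcodes <- S4Vectors::mcols(fragments)$barcode
  if (is.null(cell_ids)) cell_ids <- unique(barcodes)
  keep <- barcodes %in% cell_ids
  frags <- fragments[keep]
  hits <- GenomicRanges::findOverlaps(merged, frags, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- match(S4Vectors::mcols(frags)$barcode[S4Vectors::subjectHits(hits)],
             cell_ids)
  x <- S4Vectors::mcols(frags)$count[S4Vectors::subjectHits(hits)]
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(x),
                            dims = c(length(merged), length(cell_ids)))
  cell_feature_matrix(m, mids, cell_ids, modality = "atac_peak")
}

#' Per-cell score over a region-count matrix
#'
#' TF-IDF-normalizes (by default) and averages over all regions of the set
#' for each cell.
#'
#' @param region_counts regions x cells count matrix.
#' @param normalize `"tfidf"` (default) or `"none"`.
#' @param scale TF-IDF scale.
#' @return named numeric, one score per cell.
#' @export
per_cell_region_score <- function(region_counts, normalize = c("tfidf", "none"),
                                  scale = 1e4) {
  normalize <- match.arg(normalize)
  if (nrow(region_counts) == 0 || ncol(region_counts) == 0) {
    stop("need >= 1 region and >= 1 cell")
  }
  m <- if (normalize == "tfidf") tfidf_atac(region_counts, scale = scale)
       else .as_sparse(region_counts)
  stats::setNames(as.numeric(Matrix::colMeans(m)), colnames(region_counts))
}

#' Aggregate chromatin accessibility over a gene-linked region set
#'
#' Counts fragments per region per cell, then returns the per-cell mean of
#' the (by default TF-IDF-normalized) signal over the set — the per-cell
#' aggregate accessibility at a panel of marker-gene regions.
#'
#' @param fragments `GRanges` with barcode/count columns.
#' @param gene_regions `GRanges` regions linked to the gene set.
#' @param cell_ids barcodes defining the columns.
#' @param normalize `"tfidf"` or `"none"`.
#' @return named numeric, one score per cell.
#' @export
aggregate_gene_accessibility <- function(fragments, gene_regions,
                                         cell_ids = NULL,
                                         normalize = "tfidf") {
  if (length(gene_regions) == 0) stop("empty gene region set")
  counts <- region_set_fragment_counts(fragments, gene_regions, cell_ids)
  per_cell_region_score(counts, normalize = normalize)
}

#' Rank-based cell-type classification
#'
#' For each cell, all genes are ranked by normalized expression (ascending,
#' midranks for ties, so the highest expression receives the highest rank);
#' each signature's score is the mean rank of its genes, and the cell is
#' labelled with the top-scoring signature. An exact tie of the two best
#' scores yields `"Undetermined"`.
#'
#' @param norm_rna genes x cells normalized matrix.
#' @param signatures list of >= 2 gene [signature_set()]s.
#' @param tie_tol score difference at or below which the maxima count as
#'   tied.
#' @return data.frame: `cell_id`, one mean-rank score column per signature,
#'   `label`.
#' @export
rank_classifier <- function(norm_rna, signatures, tie_tol = 1e-12) {
  if (length(signatures) < 2) stop("need >= 2 signatures")
  m <- as.matrix(norm_rna)
  idx <- lapply(signatures, function(s) {
    ix <- which(rownames(m) %in% s$members)
    if (length(ix) == 0) {
      stop("no genes of signature '", s$name, "' present in matrix")
    }
    ix
  })
  sig_names <- vapply(signatures, function(s) s$name, character(1))
  ranks <- apply(m, 2, rank)
  scores <- vapply(idx, function(ix) {
    colMeans(ranks[ix, , drop = FALSE])
  }, numeric(ncol(m)))
  if (ncol(m) == 1) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- sig_names
  label <- apply(scores, 1, function(s) {
    ord <- order(s, decreasing = TRUE)
    if (length(s) > 1 && abs(s[ord[1]] - s[ord[2]]) <= tie_tol) {
      "Undetermined"
    } else {
      sig_names[ord[1]]
    }
  })
  out <- data.frame(cell_id = colnames(m), scores, label = label,
                    row.names = NULL, check.names = FALSE)
  out
}

#' Gene-activity matrix from fragments
#'
#' Sums fragment counts in each gene's body extended by `flank` bp upstream
#' of the TSS (strand-aware: the window is `[start - flank, end)` for `+`
#' genes and `[start, end + flank)` for `-` genes, clipped at the
#' chromosome start). With `group`, columns are summed per sample.
#'
#' @param fragments `GRanges` with barcode/count columns.
#' @param gene_models stranded `GRanges` with an `id` metadata column.
#' @param flank upstream extension in bp.
#' @param cell_ids barcodes defining the columns.
#' @param group optional named vector mapping barcode to sample ID; when
#'   given, the result is genes x samples.
#' @return sparse genes x cells (or genes x samples) count matrix.
#' @export
gene_activity_matrix <- function(fragments, gene_models, flank = 2000,
                                 cell_ids = NULL, group = NULL) {
  strands <- as.character(GenomicRanges::strand(gene_models))
  if (any(!strands %in% c("+", "-"))) {
    stop("all gene models must be stranded (+ or -)")
  }
  s <- GenomicRanges::start(gene_models)
  e <- GenomicRanges::end(gene_models)
  new_s <- ifelse(strands == "+", pmax(s - flank, 1), s)
  new_e <- ifelse(strands == "+", e, e + flank)
  windows <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(gene_models)),
    IRanges::IRanges(start = new_s, end = new_e))

  barcodes <- S4Vectors::mcols(fragments)$barcode
  if (is.null(cell_ids)) cell_ids <- unique(barcodes)
  keep <- barcodes %in% cell_ids
  frags <- fragments[keep]
  hits <- GenomicRanges::findOverlaps(windows, frags, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- match(S4Vectors::mcols(frags)$barcode[S4Vectors::subjectHits(hits)],
             cell_ids)
  x <- S4Vectors::mcols(frags)$count[S4Vectors::subjectHits(hits)]
  ids <- S4Vectors::mcols(gene_models)$id
  if (is.null(ids)) ids <- paste0("gene", seq_along(gene_models))
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(x),
                            dims = c(length(windows), length(cell_ids)))
  m <- cell_feature_matrix(m, ids, cell_ids, modality = "gene_activity")
  if (!is.null(group)) {
    samples <- group[colnames(m)]
    if (anyNA(samples)) stop("group is missing some barcodes")
    agg <- Matrix::sparseMatrix(i = seq_along(samples),
                                j = as.integer(factor(samples)),
                                x = 1,
                                dims = c(length(samples),
                                         nlevels(factor(samples))))
    out <- m %*% agg
    colnames(out) <- levels(factor(samples))
    rownames(out) <- rownames(m)
    m <- cell_feature_matrix(out, modality = "gene_activity")
  }
  m
}

#' Summed signal in strand-aware TSS windows
#'
#' The TSS is the gene-body start for `+` genes and its end for `-` genes;
#' the window spans `upstream` bp 5' of the TSS to `downstream` bp 3' of it
#' in gene orientation (half-open). Returns the summed fragment counts per
#' gene, the promoter-signal quantity correlated with expression for marks
#' such as H3K4me3.
#'
#' @param fragments `GRanges` with a `count` column (barcode optional).
#' @param gene_models stranded `GRanges` with an `id` column.
#' @param upstream,downstream window extent in bp around the TSS.
#' @return named numeric, one summed signal per gene.
#' @export
tss_window_signal <- function(fragments, gene_models, upstream = 300,
                              downstream = 500) {
  strands <- as.character(GenomicRanges::strand(gene_models))
  if (any(!strands %in% c("+", "-"))) {
    stop("all gene models must be stranded (+ or -)")
  }
  s <- GenomicRanges::start(gene_models)
  e <- GenomicRanges::end(gene_models)
  # 0-based TSS: start-1 for "+", end for "-"
  win_s <- ifelse(strands == "+", s - upstream, e - downstream + 1)
  win_e <- ifelse(strands == "+", s + downstream - 1, e + upstream)
  windows <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(gene_models)),
    IRanges::IRanges(start = pmax(win_s, 1), end = win_e))
  hits <- GenomicRanges::findOverlaps(windows, fragments,
                                      ignore.strand = TRUE)
  counts <- S4Vectors::mcols(fragments)$count
  if (is.null(counts)) counts <- rep(1, length(fragments))
  sig <- tapply(counts[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits),
                       levels = seq_along(windows)),
                sum, default = 0)
  ids <- S4Vectors::mcols(gene_models)$id
  if (is.null(ids)) ids <- paste0("gene", seq_along(gene_models))
  stats::setNames(as.numeric(sig), ids)
}

#' Lineage-specific feature sets by hierarchical clustering
#'
#' Z-scores each (already differential) feature across groups, clusters
#' features by average-linkage hierarchical clustering of Euclidean
#' distances, cuts the tree into `k` clusters, and assigns each cluster to
#' the group with the highest cluster-mean signal.
#'
#' @param signal features x groups matrix (e.g. mean normalized signal of
#'   differential promoters per lineage).
#' @param k number of clusters (>= 2).
#' @return named list of [signature_set()]s, one per group that received at
#'   least one cluster.
#' @export
lineage_specific_sets <- function(signal, k) {
  m <- as.matrix(signal)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(m)) stop("k exceeds number of features")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("feature(s) with zero variance across groups cannot be z-scored")
  }
  z <- (m - rowMeans(m)) / sds
  cl <- stats::cutree(stats::hclust(stats::dist(z), method = "average"), k)
  groups <- colnames(m)
  if (is.null(groups)) groups <- paste0("group", seq_len(ncol(m)))
  assignment <- vapply(seq_len(k), function(ci) {
    groups[which.max(colMeans(z[cl == ci, , drop = FALSE]))]
  }, character(1))
  out <- list()
  for (g in unique(assignment)) {
    members <- rownames(m)[cl %in% which(assignment == g)]
    out[[g]] <- signature_set(g, members)
  }
  out
}
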