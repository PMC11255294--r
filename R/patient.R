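#' Derive a condition-specific region set from a bulk differential table
#'
#' Selects the regions significant at `padj < padj_max` whose log2 fold
#' change matches the requested direction — e.g. the signature sites of
#' accessibility gained in one condition.
#'
#' @param bulk_diff data.frame from [nb_wald_differential()].
#' @param direction `"up"` (log2FC > 0) or `"down"`.
#' @param padj_max adjusted-p cutoff.
#' @return character vector of surviving region IDs.
#' @export
derive_condition_regions <- function(bulk_diff, direction = c("up", "down"),
                                     padj_max = 0.05) {
  direction <- match.arg(direction)
  sel <- !is.na(bulk_diff$padj) & bulk_diff$padj < padj_max &
    (if (direction == "up") bulk_diff$log2fc > 0 else bulk_diff$log2fc < 0)
  if (!any(sel)) stop("no region passes padj < ", padj_max,
                      " with direction '", direction, "'")
  bulk_diff$feature_id[sel]
}

#' Sample size-matched random control regions
#'
#' Uniform sample without replacement from a pool of shared accessible
#' regions, deterministic under the seed; used as the negative control for
#' signature-region scoring.
#'
#' @param shared_regions `GRanges` (or any vector) pool.
#' @param n number of regions to draw.
#' @param seed integer seed.
#' @return subset of `shared_regions`, length `n`.
#' @export
sample_control_regions <- function(shared_regions, n, seed = 1L) {
  if (n > length(shared_regions)) {
    stop("n (", n, ") exceeds pool size (", length(shared_regions), ")")
  }
  withr::with_seed(as.integer(seed), {
    shared_regions[sample(length(shared_regions), n)]
  })
}

#' Score pooled patient nuclei at a region set
#'
#' Counts fragments per region per nucleus within each sample, merges the
#' per-sample matrices over the common regions, TF-IDF-normalizes the
#' merged matrix (so scores are comparable across samples) and averages
#' over the set per nucleus. Nuclei with zero fragments at the set are
#' dropped with a warning.
#'
#' @param samples list of patient samples, each a list with `sample_id`,
#'   `condition`, `fragments` (`GRanges` with barcode/count) and optionally
#'   `barcodes`.
#' @param regions `GRanges` region set.
#' @param normalize `"tfidf"` or `"none"`.
#' @return data.frame: `cell_id`, `sample_id`, `condition`, `score`.
#' @export
score_patient_samples <- function(samples, regions,
                                  normalize = c("tfidf", "none")) {
  normalize <- match.arg(normalize)
  if (length(regions) == 0) stop("empty region set")
  mats <- lapply(samples, function(s) {
    region_set_fragment_counts(s$fragments, regions,
                               cell_ids = s$barcodes)
  })
  merged <- do.call(cbind, mats)
  annot <- data.frame(
    cell_id = unlist(lapply(mats, colnames)),
    sample_id = rep(vapply(samples, `[[`, character(1), "sample_id"),
                    vapply(mats, ncol, integer(1))),
    condition = rep(vapply(samples, `[[`, character(1), "condition"),
                    vapply(mats, ncol, integer(1))),
    row.names = NULL)
  empty <- Matrix::colSums(merged) == 0
  if (any(empty)) {
    warning(sum(empty), " nucleus/nuclei with zero fragments at the region",
            " set dropped")
    merged <- merged[, !empty, drop = FALSE]
    annot <- annot[!empty, , drop = FALSE]
  }
  annot$score <- as.numeric(per_cell_region_score(merged,
                                                  normalize = normalize))
  rownames(annot) <- NULL
  annot
}

#' Compare per-nucleus scores across patient conditions
#'
#' Fits the categorical linear model of [ols_condition_test()] on the
#' per-nucleus scores (optionally after collapsing conditions through a
#' grouping map) and summarizes each sample's distribution: its mean and
#' its top-90% subset of scores, the portion shown in the violin displays.
#'
#' @param score_table data.frame from [score_patient_samples()].
#' @param grouping optional named character vector mapping condition to a
#'   collapsed category.
#' @param reference reference condition level.
#' @param top_fraction fraction of highest scores retained in the display
#'   subset.
#' @return list: `model` (from [ols_condition_test()]), `sample_summary`
#'   (per-sample n and mean), `display_scores` (per-sample top subset).
#' @export
compare_conditions <- function(score_table, grouping = NULL,
                               reference = NULL, top_fraction = 0.9) {
  tab <- score_table
  if (!is.null(grouping)) {
    mapped <- grouping[tab$condition]
    if (anyNA(mapped)) stop("grouping map misses condition(s): ",
                            paste(setdiff(unique(tab$condition),
                                          names(grouping)), collapse = ", "))
    tab$condition <- unname(mapped)
  }
  model <- ols_condition_test(tab$score, tab$condition,
                              reference = reference)
  by_sample <- split(tab, tab$sample_id)
  sample_summary <- do.call(rbind, lapply(by_sample, function(d) {
    data.frame(sample_id = d$sample_id[1], condition = d$condition[1],
               n = nrow(d), mean_score = mean(d$score), row.names = NULL)
  }))
  display_scores <- lapply(by_sample, function(d) {
    k <- ceiling(top_fraction * nrow(d))
    sort(d$score, decreasing = TRUE)[seq_len(k)]
  })
  rownames(sample_summary) <- NULL
  list(model = model, sample_summary = sample_summary,
       display_scores = display_scores)
}

#' Differential gene-level accessibility between conditions
#'
#' Builds the genes x samples gene-activity matrix (gene bodies plus a
#' 2-kb upstream flank, summed per sample) and tests it with the
#' negative-binomial Wald test, treating samples as biological replicates
#' of their condition.
#'
#' @param samples list of patient samples (see [score_patient_samples()]).
#' @param gene_models stranded `GRanges` with `id` column.
#' @param flank upstream extension in bp.
#' @return data.frame from [nb_wald_differential()], one row per gene.
#' @export
gene_score_differential <- function(samples, gene_models, flank = 2000) {
  mats <- lapply(samples, function(s) {
    m <- gene_activity_matrix(s$fragments, gene_models, flank = flank,
                              cell_ids = s$barcodes)
    Matrix::rowSums(m)
  })
  counts <- do.call(cbind, mats)
  colnames(counts) <- vapply(samples, `[[`, character(1), "sample_id")
  condition <- vapply(samples, `[[`, character(1), "condition")
  nb_wald_differential(counts, condition)
}
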