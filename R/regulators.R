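#' Rank candidate transcription-factor regulators
#'
#' Joins one-vs-rest differential expression of TF genes with differential
#' motif deviation of their motifs, keeps TFs passing the four-part filter
#' (RNA `padj < padj_max` and positive RNA log fold change; motif
#' `padj < padj_max` and positive motif group-mean difference), and ranks by
#' the mean of the two AUCs — the TFs with the highest combined AUC are the
#' top candidates. Ties break by RNA AUC, then lexical gene ID. A gene
#' mapping to several motifs keeps its best-scoring pair.
#'
#' @param rna_diff data.frame from [differential_features()] on RNA,
#'   restricted to (or at least covering) TF genes.
#' @param motif_diff data.frame from [differential_features()] on the motif
#'   deviation matrix (use `delog = FALSE`); `avg_log2fc` there holds the
#'   group-mean difference of z-scores.
#' @param tf_motif_map data.frame with columns `gene`, `motif`.
#' @param padj_max significance cutoff applied to both modalities.
#' @return data.frame of all joined pairs (best per gene), sorted with
#'   passing TFs first, then descending combined AUC: columns
#'   `tf_gene_id`, `motif_id`, `rna_auc`, `motif_auc`, `rna_padj`,
#'   `motif_padj`, `rna_log2fc`, `motif_delta`, `combined`, `passed_filter`,
#'   `rank` (NA for non-passing rows).
#' @export
candidate_regulators <- function(rna_diff, motif_diff, tf_motif_map,
                                 padj_max = 0.05) {
  if (nrow(tf_motif_map) == 0) stop("empty TF-to-motif map")
  rna <- rna_diff[match(tf_motif_map$gene, rna_diff$feature_id), ]
  mot <- motif_diff[match(tf_motif_map$motif, motif_diff$feature_id), ]
  ok <- !is.na(rna$feature_id) & !is.na(mot$feature_id)
  if (!any(ok)) stop("no TF gene/motif pair found in both tables")
  out <- data.frame(tf_gene_id = tf_motif_map$gene[ok],
                    motif_id = tf_motif_map$motif[ok],
                    rna_auc = rna$auc[ok], motif_auc = mot$auc[ok],
                    rna_padj = rna$padj[ok], motif_padj = mot$padj[ok],
                    rna_log2fc = rna$avg_log2fc[ok],
                    motif_delta = mot$avg_log2fc[ok],
                    row.names = NULL)
  out$combined <- (out$rna_auc + out$motif_auc) / 2
  out$passed_filter <- out$rna_padj < padj_max & out$rna_log2fc > 0 &
    out$motif_padj < padj_max & out$motif_delta > 0
  # one row per gene: keep the best combined score
  ord <- order(out$tf_gene_id, -out$combined, -out$rna_auc, out$motif_id)
  out <- out[ord, ]
  out <- out[!duplicated(out$tf_gene_id), ]
  ord <- order(-out$passed_filter, -out$combined, -out$rna_auc,
               out$tf_gene_id)
  out <- out[ord, ]
  out$rank <- NA_integer_
  out$rank[out$passed_filter] <- seq_len(sum(out$passed_filter))
  rownames(out) <- NULL
  out
}
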