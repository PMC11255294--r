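#' Nucleus-level QC thresholds
#'
#' All bounds are strict: a nucleus is kept only when its totals lie
#' strictly inside the (min, max) intervals and its mitochondrial fraction
#' is strictly below `mito_max`. Defaults are the standard multiome cutoffs
#' for sorted ILC nuclei: RNA total in (1000, 25000), ATAC total in
#' (5000, 70000), mitochondrial fraction below 20%.
#'
#' @param rna_min,rna_max strict bounds on per-nucleus RNA total.
#' @param atac_min,atac_max strict bounds on per-nucleus ATAC total.
#' @param mito_max strict upper bound on mitochondrial UMI fraction.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(rna_min = 1000, rna_max = 25000,
                          atac_min = 5000, atac_max = 70000,
                          mito_max = 0.20) {
  if (rna_min >= rna_max) stop("rna_min must be < rna_max")
  if (atac_min >= atac_max) stop("atac_min must be < atac_max")
  if (mito_max <= 0 || mito_max >= 1) stop("mito_max must be in (0,1)")
  structure(list(rna_min = rna_min, rna_max = rna_max,
                 atac_min = atac_min, atac_max = atac_max,
                 mito_max = mito_max),
            class = "qc_thresholds")
}

#' Filter nuclei on paired RNA/ATAC totals and mitochondrial fraction
#'
#' A nucleus passes iff `rna_min < total RNA < rna_max`,
#' `atac_min < total ATAC < atac_max`, and mitochondrial fraction
#' `< mito_max` — all bounds strict, so boundary values are removed.
#' The mitochondrial fraction is computed on RNA UMI counts over the
#' designated mitochondrial genes.
#'
#' @param rna,atac count matrices sharing cell IDs (columns); cells present
#'   in both modalities are evaluated.
#' @param mito_gene_ids RNA feature IDs counted as mitochondrial; must be
#'   present in `rna`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `kept` (cell IDs passing all filters, in input order)
#'   and `qc` (per-cell data.frame of totals, mito fraction, pass flag for
#'   every shared cell).
#' @export
filter_nuclei <- function(rna, atac, mito_gene_ids,
                          thresholds = qc_thresholds()) {
  cells <- intersect(colnames(rna), colnames(atac))
  if (length(cells) == 0) stop("RNA and ATAC matrices share no cell IDs")
  if (length(mito_gene_ids) == 0) {
    stop("mito_gene_ids is empty; mitochondrial filtering needs >= 1 gene")
  }
  missing <- setdiff(mito_gene_ids, rownames(rna))
  if (length(missing) > 0) {
    stop("mito genes absent from RNA matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  rna_tot <- Matrix::colSums(rna[, cells, drop = FALSE])
  atac_tot <- Matrix::colSums(atac[, cells, drop = FALSE])
  mito_tot <- Matrix::colSums(rna[mito_gene_ids, cells, drop = FALSE])
  mito_frac <- ifelse(rna_tot > 0, mito_tot / rna_tot, 0)
  th <- thresholds
  pass <- rna_tot > th$rna_min & rna_tot < th$rna_max &
    atac_tot > th$atac_min & atac_tot < th$atac_max &
    mito_frac < th$mito_max
  qc <- data.frame(cell_id = cells, rna_total = as.numeric(rna_tot),
                   atac_total = as.numeric(atac_tot),
                   mito_fraction = as.numeric(mito_frac),
                   pass = as.logical(pass), row.names = NULL)
  list(kept = cells[pass], qc = qc)
}

#' Minimum-UMI cell filter
#'
#' Removes cells with fewer than `min_umi` total counts (cells with exactly
#' `min_umi` are kept).
#'
#' @param rna count matrix, genes x cells.
#' @param min_umi minimum total UMI count to keep a cell.
#' @return character vector of kept cell IDs.
#' @export
filter_min_umi <- function(rna, min_umi = 200) {
  totals <- Matrix::colSums(rna)
  colnames(rna)[totals >= min_umi]
}

#' Cap identical-sequence duplicates
#'
#' Keeps the first `max_copies` occurrences of each key in input order and
#' drops later ones; reads beyond the cap are excluded. Keys identify
#' identical sequences — at fragment resolution, the (chrom, start, end,
#' strand) tuple.
#'
#' @param read_keys vector of keys, one per read, in file order.
#' @param max_copies occurrences retained per key.
#' @return integer indices (1-based, increasing) of the retained reads.
#' @export
cap_duplicates <- function(read_keys, max_copies = 5) {
  if (length(read_keys) == 0) return(integer(0))
  occurrence <- stats::ave(seq_along(read_keys), read_keys,
                           FUN = seq_along)
  which(occurrence <= max_copies)
}
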