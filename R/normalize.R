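#' Library-size log-normalization of RNA counts
#'
#' `value = ln(1 + scale * count / cell_total)`: per-cell proportions scaled
#' to a common library size and log-transformed, the standard pre-testing
#' normalization for UMI counts.
#'
#' @param counts genes x cells count matrix.
#' @param scale library-size target (default 1e4).
#' @return normalized matrix with a `"lognorm"` method attribute.
#' @export
lognorm_rna <- function(counts, scale = 1e4) {
  m <- .as_sparse(counts)
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(m)[totals == 0], 5), collapse = ", "))
  }
  out <- m %*% Matrix::Diagonal(x = scale / totals)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "modality") <- "normalized"
  attr(out, "method") <- "lognorm"
  out
}

#' TF-IDF normalization of ATAC peak counts
#'
#' Term frequency `TF_ij = x_ij / cell_total_j`, inverse document frequency
#' `IDF_i = n_cells / feature_total_i` (non-binarized by default), combined
#' as `ln(1 + scale * TF * IDF)`. Down-weights ubiquitously open regions.
#' Peaks with zero total are dropped with a warning.
#'
#' @param counts peaks x cells count matrix.
#' @param scale multiplier inside the log (default 1e4).
#' @param binarize_idf compute IDF on the binarized matrix
#'   (`n_cells / n_cells_with_signal`) instead of raw totals.
#' @return normalized matrix (possibly fewer rows) with a `"tfidf"` method
#'   attribute.
#' @export
tfidf_atac <- function(counts, scale = 1e4, binarize_idf = FALSE) {
  m <- .as_sparse(counts)
  cell_tot <- Matrix::colSums(m)
  if (any(cell_tot == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(m)[cell_tot == 0], 5), collapse = ", "))
  }
  feat_tot <- if (binarize_idf) {
    Matrix::rowSums(m > 0)
  } else {
    Matrix::rowSums(m)
  }
  if (any(feat_tot == 0)) {
    warning(sum(feat_tot == 0), " feature(s) with zero total dropped")
    keep <- feat_tot > 0
    m <- m[keep, , drop = FALSE]
    feat_tot <- feat_tot[keep]
  }
  tf <- m %*% Matrix::Diagonal(x = 1 / cell_tot)
  out <- Matrix::Diagonal(x = ncol(m) / feat_tot) %*% tf
  out@x <- log1p(scale * out@x)
  dimnames(out) <- dimnames(m)
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "modality") <- "normalized"
  attr(out, "method") <- "tfidf"
  out
}

#' Median-of-ratios size factors for replicated bulk counts
#'
#' For each sample, the size factor is the median over reference regions
#' (those with a positive geometric mean across samples) of the ratio of
#' the sample's count to the region's geometric mean.
#'
#' @param bulk_counts regions x samples count matrix (>= 2 samples).
#' @return positive numeric vector, one factor per sample.
#' @export
median_ratio_size_factors <- function(bulk_counts) {
  m <- as.matrix(bulk_counts)
  if (ncol(m) < 2) stop("need >= 2 samples")
  log_geo <- rowMeans(log(m))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no region has positive counts in all samples")
  sf <- apply(m[use, , drop = FALSE], 2, function(x) {
    exp(stats::median(log(x) - log_geo[use]))
  })
  stats::setNames(as.numeric(sf), colnames(m))
}

#' Center each feature at zero mean across cells
#'
#' @param mat features x cells matrix of finite values.
#' @return dense matrix with every row mean 0 and a `"mean_centered"`
#'   method attribute.
#' @export
mean_center <- function(mat) {
  m <- as.matrix(mat)
  out <- m - rowMeans(m)
  attr(out, "method") <- "mean_centered"
  out
}
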