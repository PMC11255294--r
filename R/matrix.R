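#' Construct a cell-feature matrix
#'
#' The package's central container: a sparse features x cells matrix
#' (`Matrix::dgCMatrix`) with unique feature and cell identifiers as
#' dimnames and a `modality` attribute recording what the values are.
#' Count modalities must hold nonnegative integers.
#'
#' @param values matrix-like, features x cells; coerced to `dgCMatrix`.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to existing rownames.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   existing colnames.
#' @param modality one of `"rna"`, `"atac_peak"`, `"gene_activity"`,
#'   `"motif_score"`, `"normalized"`.
#' @return a `dgCMatrix` with dimnames set and a `modality` attribute.
#' @export
cell_feature_matrix <- function(values, feature_ids = rownames(values),
                                cell_ids = colnames(values),
                                modality = c("rna", "atac_peak",
                                             "gene_activity", "motif_score",
                                             "normalized")) {
  modality <- match.arg(modality)
  m <- methods::as(methods::as(methods::as(values, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (is.null(feature_ids) || is.null(cell_ids)) {
    stop("feature_ids and cell_ids are required")
  }
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(m)) {
    stop("feature_ids length (", length(feature_ids),
         ") does not match matrix rows (", nrow(m), ")")
  }
  if (length(cell_ids) != ncol(m)) {
    stop("cell_ids length (", length(cell_ids),
         ") does not match matrix columns (", ncol(m), ")")
  }
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (any(m@x < 0)) stop("negative values are not allowed")
  if (modality %in% c("rna", "atac_peak") && any(m@x != floor(m@x))) {
    stop("count matrix (modality '", modality, "') has non-integer entries")
  }
  dimnames(m) <- list(feature_ids, cell_ids)
  attr(m, "modality") <- modality
  m
}

#' Modality of a cell-feature matrix
#' @param x a matrix produced by [cell_feature_matrix()] or a normalizer.
#' @return the modality string, or `NA` if unset.
#' @export
matrix_modality <- function(x) {
  mod <- attr(x, "modality")
  if (is.null(mod)) NA_character_ else mod
}

# internal: sparse coercion that keeps dimnames, no modality policing
.as_sparse <- function(values) {
  methods::as(methods::as(methods::as(values, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}
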