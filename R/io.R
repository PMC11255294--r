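#' Read a sparse count matrix from Matrix Market plus ID files
#'
#' Reads the CellRanger-style triplet layout: a Matrix Market coordinate
#' file (1-based on disk, as the format requires) plus one-column TSV files
#' listing feature and cell (barcode) identifiers in row/column order.
#'
#' @param mtx_path path to the `.mtx` file.
#' @param features_path path to a one-column TSV of feature IDs.
#' @param barcodes_path path to a one-column TSV of cell barcodes.
#' @param modality passed to [cell_feature_matrix()].
#' @return a features x cells sparse matrix with IDs attached.
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path,
                              modality = "rna") {
  m <- Matrix::readMM(mtx_path)
  features <- readLines(features_path)
  features <- features[nzchar(features)]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(features) != nrow(m)) {
    stop("features file has ", length(features), " entries but matrix declares ",
         nrow(m), " rows")
  }
  if (length(barcodes) != ncol(m)) {
    stop("barcodes file has ", length(barcodes), " entries but matrix declares ",
         ncol(m), " columns")
  }
  cell_feature_matrix(m, features, barcodes, modality = modality)
}

#' Write a sparse matrix as Matrix Market plus ID files
#'
#' @param mat features x cells matrix with dimnames.
#' @param mtx_path,features_path,barcodes_path output paths.
#' @return invisibly, the three paths.
#' @export
write_count_matrix <- function(mat, mtx_path, features_path, barcodes_path) {
  Matrix::writeMM(.as_sparse(mat), mtx_path)
  writeLines(rownames(mat), features_path)
  writeLines(colnames(mat), barcodes_path)
  invisible(c(mtx_path, features_path, barcodes_path))
}

#' Read genomic regions from a BED file
#'
#' BED is 0-based half-open on disk; regions are returned as a `GRanges`
#' (1-based closed, the Bioconductor convention) so that the half-open
#' overlap semantics are preserved exactly: a BED fragment `[100,200)` does
#' not overlap a BED region `[200,300)`. Column 4, when present, supplies
#' region IDs; column 6 the strand.
#'
#' @param path BED3/BED6 file (optionally gzipped).
#' @return `GRanges` with an `id` metadata column; strand `*` when absent.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  start0 <- suppressWarnings(as.numeric(df[[2]]))
  end0 <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start0) || anyNA(end0) ||
      any(start0 != floor(start0)) || any(end0 != floor(end0))) {
    stop("non-integer coordinates in BED file")
  }
  if (any(start0 < 0)) stop("negative start coordinate in BED file")
  if (any(start0 >= end0)) {
    bad <- which(start0 >= end0)[1]
    stop("invalid interval at line ", bad, ": start (", start0[bad],
         ") must be < end (", end0[bad], ")")
  }
  ids <- if (ncol(df) >= 4) df[[4]] else paste0(df[[1]], ":", start0, "-", end0)
  strand <- if (ncol(df) >= 6) df[[6]] else rep(".", nrow(df))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = strand)
  S4Vectors::mcols(gr)$id <- ids
  gr
}

#' Write regions to BED
#'
#' Emits BED6 when any strand is set or `force_bed6 = TRUE`, else BED3 with
#' the `id` column appended when present (BED4).
#'
#' @param regions a `GRanges`.
#' @param path output path.
#' @param force_bed6 always write 6 columns.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path, force_bed6 = FALSE) {
  strands <- as.character(GenomicRanges::strand(regions))
  ids <- S4Vectors::mcols(regions)$id
  if (is.null(ids)) ids <- rep(".", length(regions))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions),
                   id = ids, stringsAsFactors = FALSE)
  if (force_bed6 || any(strands %in% c("+", "-"))) {
    df$score <- 0L
    df$strand <- ifelse(strands %in% c("+", "-"), strands, ".")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ATAC fragments file
#'
#' Five-column TSV (chrom, start, end, barcode, count), BED-style 0-based
#' half-open coordinates, optionally gzipped. Returned as a `GRanges`
#' (1-based closed) with `barcode` and `count` metadata columns, in file
#' order.
#'
#' @param path fragments TSV path.
#' @return `GRanges` with `barcode` and `count` columns; empty for an empty
#'   file.
#' @export
read_fragments <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#",
                      col.names = c("chrom", "start", "end", "barcode",
                                    "count"),
                      colClasses = c("character", "numeric", "numeric",
                                     "character", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), barcode = character(),
                          count = numeric()))
      }
      stop("malformed fragments file '", path, "': ", conditionMessage(e))
    })
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$count)) {
    stop("malformed fragments file: non-numeric coordinates or counts")
  }
  if (any(df$start >= df$end)) stop("fragment with start >= end")
  if (any(df$count < 1 | df$count != floor(df$count))) {
    stop("fragment counts must be integers >= 1")
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start = df$start + 1,
                                                end = df$end))
  S4Vectors::mcols(gr)$barcode <- df$barcode
  S4Vectors::mcols(gr)$count <- as.integer(df$count)
  gr
}

#' Write fragments to a 5-column TSV
#'
#' @param fragments `GRanges` with `barcode` and `count` metadata columns.
#' @param path output path; written gzipped when it ends in `.gz`.
#' @return invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(fragments)),
                   start = GenomicRanges::start(fragments) - 1L,
                   end = GenomicRanges::end(fragments),
                   barcode = S4Vectors::mcols(fragments)$barcode,
                   count = S4Vectors::mcols(fragments)$count)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a signature set
#'
#' A named list of member gene IDs (or region IDs) characteristic of one
#' cell type, used for per-cell scoring and classification.
#'
#' @param name cell-type label.
#' @param members character vector of unique member IDs.
#' @param kind `"gene"` or `"region"`.
#' @return a `signature_set` object.
#' @export
signature_set <- function(name, members, kind = c("gene", "region")) {
  kind <- match.arg(kind)
  members <- as.character(members)
  if (length(members) == 0) stop("signature '", name, "' is empty")
  if (anyDuplicated(members)) {
    stop("signature '", name, "' has duplicate members")
  }
  structure(list(name = name, members = members, kind = kind),
            class = "signature_set")
}

#' @exportS3Method base::print
print.signature_set <- function(x, ...) {
  cat("signature_set '", x$name, "' (", x$kind, "): ", length(x$members),
      " members\n", sep = "")
  invisible(x)
}

#' Read signature sets from JSON
#'
#' Expects a JSON object mapping cell-type name to an array of member IDs.
#'
#' @param path JSON path.
#' @param kind `"gene"` or `"region"`.
#' @return named list of [signature_set()] objects.
#' @export
read_signatures <- function(path, kind = "gene") {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(obj) && !is.character(obj)) stop("expected a JSON object")
  if (length(obj) == 0) stop("no signatures in file")
  sets <- lapply(names(obj), function(nm) {
    signature_set(nm, unlist(obj[[nm]]), kind = kind)
  })
  stats::setNames(sets, names(obj))
}

#' Write signature sets to JSON
#'
#' @param signatures named list of [signature_set()] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_signatures <- function(signatures, path) {
  obj <- lapply(signatures, function(s) s$members)
  names(obj) <- vapply(signatures, function(s) s$name, character(1))
  jsonlite::write_json(obj, path, pretty = TRUE)
  invisible(path)
}
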