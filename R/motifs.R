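#' Construct a motif-peak membership map
#'
#' @param membership binary motifs x peaks matrix (any matrix-like).
#' @param motif_ids,peak_ids identifiers; default existing dimnames.
#' @param gc optional per-peak GC fraction in `[0,1]`, used as a second
#'   background-matching dimension.
#' @return a `motif_peak_map` list with a sparse 0/1 `membership` matrix.
#' @export
motif_peak_map <- function(membership, motif_ids = rownames(membership),
                           peak_ids = colnames(membership), gc = NULL) {
  m <- .as_sparse(membership)
  if (is.null(motif_ids) || is.null(peak_ids)) {
    stop("motif and peak ids are required")
  }
  if (length(motif_ids) != nrow(m) || length(peak_ids) != ncol(m)) {
    stop("id lengths do not match membership dimensions")
  }
  if (any(!m@x %in% c(0, 1))) stop("membership must be binary")
  if (any(Matrix::rowSums(m) == 0)) {
    stop("every motif needs >= 1 member peak")
  }
  if (!is.null(gc)) {
    if (length(gc) != ncol(m)) stop("gc length must match peaks")
    if (any(gc < 0 | gc > 1)) stop("gc fractions must be in [0,1]")
  }
  dimnames(m) <- list(motif_ids, peak_ids)
  structure(list(membership = m, gc = gc), class = "motif_peak_map")
}

#' Sample accessibility-matched background peaks
#'
#' Peaks are binned by log mean accessibility (and GC fraction when the map
#' provides one, on a 2-D grid); each peak's backgrounds are drawn uniformly
#' with replacement from its own bin, so background sets preserve the
#' coverage (and GC) profile of the foreground. Bins left empty are merged
#' into their nearest occupied neighbour by construction (sampling uses
#' occupied bins only).
#'
#' @param atac_counts peaks x cells count matrix.
#' @param motif_map a [motif_peak_map()] (source of the optional GC).
#' @param n_bins bins per matching dimension.
#' @param n_background background peaks drawn per peak.
#' @param seed integer seed; sampling is deterministic given it.
#' @return integer matrix, peaks x `n_background`, of background peak
#'   indices.
#' @export
match_background_peaks <- function(atac_counts, motif_map = NULL,
                                   n_bins = 50, n_background = 50,
                                   seed = 1L) {
  m <- .as_sparse(atac_counts)
  n_peaks <- nrow(m)
  mean_acc <- log1p(Matrix::rowMeans(m))
  bin_index <- function(x, k) {
    if (diff(range(x)) == 0) return(rep(1L, length(x)))
    cut(x, breaks = k, labels = FALSE, include.lowest = TRUE)
  }
  acc_bin <- bin_index(mean_acc, n_bins)
  gc <- if (!is.null(motif_map)) motif_map$gc else NULL
  bins <- if (is.null(gc)) {
    acc_bin
  } else {
    gc_bins <- ceiling(sqrt(n_bins))
    (acc_bin - 1L) * gc_bins + bin_index(gc, gc_bins)
  }
  withr::with_seed(as.integer(seed), {
    out <- matrix(0L, nrow = n_peaks, ncol = n_background)
    for (b in unique(bins)) {
      members <- which(bins == b)
      out[members, ] <- sample(members,
                               length(members) * n_background,
                               replace = TRUE)
    }
    rownames(out) <- rownames(m)
    out
  })
}

#' Per-cell motif deviation z-scores
#'
#' For each motif and cell, the raw deviation is the relative excess of
#' observed counts in the motif's peaks over the expectation under the
#' cell's depth and each peak's share of total accessibility:
#' `raw = (observed - expected) / expected` with
#' `expected = cell_total * sum(peak_share)`. The z-score standardizes the
#' raw deviation against the same quantity computed on accessibility-matched
#' background peak sets.
#'
#' @param atac_counts peaks x cells count matrix.
#' @param motif_map a [motif_peak_map()]; peak IDs must match the matrix.
#' @param backgrounds matrix from [match_background_peaks()]; when `NULL`
#'   it is computed with the defaults and `seed`.
#' @param seed used only when `backgrounds` is `NULL`.
#' @return list: `z` (motifs x cells z-score matrix, modality
#'   `motif_score`), `raw` (raw deviations). Motifs with zero expected
#'   counts are dropped with a warning.
#' @export
motif_deviations <- function(atac_counts, motif_map, backgrounds = NULL,
                             seed = 1L) {
  m <- .as_sparse(atac_counts)
  mm <- motif_map$membership
  if (!identical(colnames(mm), rownames(m))) {
    if (!all(colnames(mm) %in% rownames(m))) {
      stop("motif map references peaks absent from the ATAC matrix")
    }
    m <- m[colnames(mm), , drop = FALSE]
  }
  if (is.null(backgrounds)) {
    backgrounds <- match_background_peaks(m, motif_map, seed = seed)
  }
  peak_tot <- Matrix::rowSums(m)
  grand <- sum(peak_tot)
  if (grand == 0) stop("ATAC matrix is all zero")
  share <- peak_tot / grand
  cell_tot <- Matrix::colSums(m)

  raw_dev <- function(member) {
    # member: motifs x peaks 0/1 (sparse)
    observed <- as.matrix(member %*% m)
    expected <- as.numeric(member %*% share) %o% cell_tot
    dev <- (observed - expected) / expected
    dev[expected == 0] <- 0  # cells with zero depth carry no signal
    dev
  }

  exp_share <- as.numeric(mm %*% share)
  drop <- exp_share == 0
  if (any(drop)) {
    warning(sum(drop), " motif(s) with zero expected counts dropped")
    mm <- mm[!drop, , drop = FALSE]
  }
  raw <- raw_dev(mm)

  n_motifs <- nrow(mm)
  sizes <- Matrix::rowSums(mm)
  member_idx <- lapply(seq_len(n_motifs), function(k) which(mm[k, ] != 0))
  n_bg <- ncol(backgrounds)
  bg_sum <- matrix(0, nrow = n_motifs, ncol = ncol(m))
  bg_sumsq <- matrix(0, nrow = n_motifs, ncol = ncol(m))
  for (it in seq_len(n_bg)) {
    bg_peaks <- lapply(member_idx, function(ix) backgrounds[ix, it])
    i <- rep(seq_len(n_motifs), sizes)
    # a background set may sample the same peak twice; multiplicity counts
    bmm <- Matrix::sparseMatrix(i = i, j = unlist(bg_peaks), x = 1,
                                dims = dim(mm))
    bobs <- as.matrix(bmm %*% m)
    bexp <- as.numeric(bmm %*% share) %o% cell_tot
    bexp[bexp == 0] <- NA_real_
    bdev <- (bobs - bexp) / bexp
    bdev[is.na(bdev)] <- 0
    bg_sum <- bg_sum + bdev
    bg_sumsq <- bg_sumsq + bdev^2
  }
  bg_mean <- bg_sum / n_bg
  bg_sd <- sqrt(pmax(bg_sumsq / n_bg - bg_mean^2, 0) * n_bg / (n_bg - 1))
  bg_sd[bg_sd == 0] <- NA_real_
  z <- (raw - bg_mean) / bg_sd
  z[is.na(z)] <- 0
  dimnames(z) <- list(rownames(mm), colnames(m))
  dimnames(raw) <- dimnames(z)
  attr(z, "modality") <- "motif_score"
  list(z = z, raw = raw)
}
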