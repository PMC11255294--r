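#' Read a pipeline run configuration
#'
#' YAML with optional blocks: `seed`, `sim` (overrides for [sim_config()]),
#' `qc` (overrides for [qc_thresholds()]), `diff` (`padj_max`), `motifs`
#' (`n_background`, `n_bins`), and `out_dir`. Unknown fields error so typos
#' do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a config list built in code.
#' @export
validate_run_config <- function(config) {
  known <- c("seed", "sim", "qc", "diff", "motifs", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$sim <- config$sim %||% list()
  config$qc <- config$qc %||% list()
  config$diff <- config$diff %||% list()
  config$motifs <- config$motifs %||% list()
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full multiome analysis pipeline on simulated data
#'
#' Executes simulate, QC, normalization, one-vs-rest differential testing
#' (RNA and motif deviations), motif deviation scoring, and candidate
#' regulator ranking, writing every intermediate in the package's standard
#' formats plus a JSON manifest recording seeds, parameters and per-stage
#' dimensions.
#'
#' @param config list from [read_run_config()] / [validate_run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[plasticore] ", ...)
  manifest <- list(package_version = as.character(utils::packageVersion("plasticore")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say(name, " done in ",
        round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2), "s")
    res
  }

  sim_cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  data <- stage("simulate", generate_multiome(sim_cfg))
  write_count_matrix(data$rna, file.path(out_dir, "rna.mtx"),
                     file.path(out_dir, "rna_features.tsv"),
                     file.path(out_dir, "barcodes.tsv"))
  write_count_matrix(data$atac, file.path(out_dir, "atac.mtx"),
                     file.path(out_dir, "atac_features.tsv"),
                     file.path(out_dir, "barcodes.tsv"))
  write_fragments(data$fragments, file.path(out_dir, "fragments.tsv.gz"))
  write_signatures(data$signatures, file.path(out_dir, "signatures.json"))
  write_regions_bed(data$genome$peaks, file.path(out_dir, "peaks.bed"))
  write_regions_bed(data$genome$genes, file.path(out_dir, "genes.bed"),
                    force_bed6 = TRUE)
  manifest$stages$simulate <- list(n_genes = nrow(data$rna),
                                   n_peaks = nrow(data$atac),
                                   n_cells = ncol(data$rna),
                                   sim = config$sim)

  # QC thresholds default to the simulated count scale rather than the
  # deep-sequencing defaults of qc_thresholds()
  qc_defaults <- list(rna_min = 100, rna_max = 1e6,
                      atac_min = 50, atac_max = 1e6, mito_max = 0.20)
  th <- do.call(qc_thresholds, utils::modifyList(qc_defaults, config$qc))
  qc <- stage("qc", filter_nuclei(data$rna, data$atac,
                                  data$truth$mito_genes, th))
  utils::write.table(qc$qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(qc$kept, file.path(out_dir, "kept_barcodes.tsv"))
  manifest$stages$qc <- list(n_input = nrow(qc$qc),
                             n_kept = length(qc$kept),
                             thresholds = unclass(th))
  if (length(qc$kept) < 4) stop("stage 'qc' failed: fewer than 4 nuclei kept")
  rna <- data$rna[, qc$kept, drop = FALSE]
  atac <- data$atac[, qc$kept, drop = FALSE]
  labels <- data$truth$labels[qc$kept]

  norm_rna <- stage("normalize", lognorm_rna(rna))
  norm_atac <- tfidf_atac(atac)
  manifest$stages$normalize <- list(rna_method = "lognorm",
                                    atac_method = "tfidf")

  padj_max <- config$diff$padj_max %||% 0.05
  target <- data$truth$target_type
  tf_genes <- intersect(data$truth$tf_motif_map$gene, rownames(norm_rna))
  rna_diff <- stage("diff",
                    differential_features(norm_rna[tf_genes, , drop = FALSE],
                                          labels, target))
  utils::write.table(rna_diff, file.path(out_dir, "rna_differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$diff <- list(n_tf_genes = length(tf_genes),
                               target_group = target,
                               padj_max = padj_max)

  dev <- stage("motifs", motif_deviations(atac, data$motif_map,
                                          seed = config$seed + 10L))
  motif_diff <- differential_features(dev$z, labels, target, delog = FALSE)
  utils::write.table(motif_diff, file.path(out_dir, "motif_differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$motifs <- list(n_motifs = nrow(dev$z),
                                 n_background = config$motifs$n_background %||% 50)

  regs <- stage("regulators",
                candidate_regulators(rna_diff, motif_diff,
                                     data$truth$tf_motif_map,
                                     padj_max = padj_max))
  utils::write.table(regs, file.path(out_dir, "regulators.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$regulators <- list(n_pairs = nrow(regs),
                                     n_passing = sum(regs$passed_filter),
                                     top = regs$tf_gene_id[1])

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
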