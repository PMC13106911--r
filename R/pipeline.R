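#' Pipeline configuration
#'
#' Collects every threshold and algorithm parameter of the post-search
#' pipeline, validated up front and recorded verbatim in the run manifest.
#'
#' @param q_threshold Precursor q-value cutoff (strict), default 0.01.
#' @param target_organism Organism precursors must be unambiguously assigned
#'   to, default `"Homo sapiens"`.
#' @param min_precursors Minimum observed precursors per cell, default 500.
#' @param min_coverage Minimum per-precursor sample-coverage fraction,
#'   default 0.5 (boundary inclusive).
#' @param svd_components,svd_tol,svd_max_iter [svd_impute()] settings.
#' @param min_shared Minimum shared precursors per cell pair in [maxlfq()].
#' @param run_combat,run_histone Stage toggles for batch correction and
#'   histone normalization.
#' @param min_histones Minimum histone proteins for normalization, default 3.
#' @param rollup_min_members Minimum mapped proteins per gene set, default 3.
#' @param n_components Principal components to retain/test, default 10.
#' @param scale_pca Unit-scale features before PCA, default `FALSE`.
#' @param eigencor_variables Metadata variables correlated with components.
#' @param alpha BH-adjusted significance level, default 0.05.
#' @param ibaq_top_n Restrict the iBAQ table to the top N abundant proteins
#'   observed in more than half the cells, default 500.
#' @param ibaq_min_len,ibaq_max_len,ibaq_missed_cleavages,ibaq_proline_rule
#'   In-silico digestion settings for iBAQ.
#' @param reference_genes Optional gene list flagged in the iBAQ table.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed governs simulation when used via
#'   [write_synthetic_dataset()]).
#' @return A validated list of class `scp_config`.
#' @export
scp_config <- function(q_threshold = 0.01,
                       target_organism = "Homo sapiens",
                       min_precursors = 500,
                       min_coverage = 0.5,
                       svd_components = 5,
                       svd_tol = 1e-2,
                       svd_max_iter = 100,
                       min_shared = 1,
                       run_combat = TRUE,
                       run_histone = TRUE,
                       min_histones = 3,
                       rollup_min_members = 3,
                       n_components = 10,
                       scale_pca = FALSE,
                       eigencor_variables = "diameter_um",
                       alpha = 0.05,
                       ibaq_top_n = 500,
                       ibaq_min_len = 6,
                       ibaq_max_len = 50,
                       ibaq_missed_cleavages = 0,
                       ibaq_proline_rule = FALSE,
                       reference_genes = NULL,
                       seed = 1) {
  stopifnot(q_threshold > 0, q_threshold <= 1,
            min_coverage >= 0, min_coverage <= 1,
            min_precursors >= 0, svd_components >= 1,
            n_components >= 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "scp_config")
}

#' Run the full post-search pipeline
#'
#' Executes the filtering cascade (q-value, species ambiguity, keratins, cell
#' QC, coverage), median-relative scaling, iterative-SVD imputation, MaxLFQ
#' protein summarization, chip batch correction, histone-median
#' normalization, iBAQ ranking, gene-set rollup, and PCA with
#' component-phenotype correlation.
#'
#' @param report Precursor records (data frame from [read_precursor_report()]
#'   or a file path).
#' @param annotations Protein annotations (data frame from [read_fasta()] or
#'   a FASTA path).
#' @param metadata Cell metadata with `cell_id`, `chip_id`, `diameter_um`
#'   (data frame or TSV path).
#' @param genesets Optional gene sets ([read_gmt()] list or GMT path).
#' @param config An [scp_config()].
#' @param outdir Optional output directory: matrices, tables, the filter
#'   report and a JSON manifest are written there.
#' @return A list of class `scp_result`: `protein_matrix` (corrected,
#'   normalized log2 protein-by-cell matrix), `precursor_matrix` (imputed),
#'   `term_matrix`, `ibaq`, `pca`, `term_pca`, `eigencor`, `filter_report`,
#'   `completeness`, `histone_factors`, `combat_model`, `config`, and
#'   `manifest`.
#' @export
run_pipeline <- function(report, annotations, metadata, genesets = NULL,
                         config = scp_config(), outdir = NULL) {
  stopifnot(inherits(config, "scp_config"))
  if (is.character(report)) report <- read_precursor_report(report)
  if (is.character(annotations)) annotations <- read_fasta(annotations)
  if (is.character(metadata)) {
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  if (is.character(genesets)) genesets <- read_gmt(genesets)
  stopifnot(all(c("cell_id", "chip_id", "diameter_um") %in% names(metadata)))
  unknown <- setdiff(unique(report$run_id), metadata$cell_id)
  if (length(unknown)) {
    stop("run(s) in report without cell metadata: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }

  fr <- filter_report_new()
  n0 <- nrow(report)
  rec <- filter_qvalue(report, config$q_threshold)
  fr <- filter_report_add(fr, "q_value", n0, nrow(rec))
  n1 <- nrow(rec)
  rec <- filter_species_unambiguous(rec, annotations, config$target_organism)
  fr <- filter_report_add(fr, "species_unambiguous", n1, nrow(rec))
  n2 <- nrow(rec)
  rec <- filter_keratins(rec, annotations)
  fr <- filter_report_add(fr, "keratin", n2, nrow(rec))

  mat <- build_matrix(rec)
  n_prec0 <- nrow(mat)
  n_cell0 <- ncol(mat)
  mat <- filter_cells_min_precursors(mat, config$min_precursors)
  fr <- filter_report_add(fr, "cell_min_precursors", n_cell0, ncol(mat),
                          unit = "cells")
  fr$cells_removed <- attr(mat, "cells_removed")

  # iBAQ works on raw (pre-normalization) linear intensities of the retained
  # cells, before the coverage filter
  linear <- 2^mat
  attr(linear, "precursor_info") <- attr(mat, "precursor_info")
  ibaq <- compute_ibaq(linear, annotations = annotations,
                       min_len = config$ibaq_min_len,
                       max_len = config$ibaq_max_len,
                       missed_cleavages = config$ibaq_missed_cleavages,
                       proline_rule = config$ibaq_proline_rule,
                       top_n = config$ibaq_top_n,
                       reference_genes = config$reference_genes)

  mat <- filter_precursor_coverage(mat, config$min_coverage)
  fr <- filter_report_add(fr, "precursor_coverage", n_prec0, nrow(mat),
                          unit = "precursors")
  completeness <- completeness_profile(mat)

  centered <- median_center_rows(mat)
  imputed <- svd_impute(centered, n_components = config$svd_components,
                        tol = config$svd_tol,
                        max_iter = config$svd_max_iter)
  prot <- summarize_all_proteins(imputed, min_shared = config$min_shared)

  combat_model <- NULL
  if (config$run_combat) {
    chips <- metadata$chip_id[match(colnames(prot), metadata$cell_id)]
    if (length(unique(chips)) > 1L) {
      cc <- combat_correct(prot, chips)
      prot <- cc$corrected
      combat_model <- cc$model
    }
  }
  histone_factors <- NULL
  if (config$run_histone) {
    hn <- histone_normalize(prot, annotations = annotations,
                            min_histones = config$min_histones)
    prot <- hn$normalized
    histone_factors <- hn$factors
  }

  term_matrix <- NULL
  term_pca <- NULL
  if (!is.null(genesets) && length(genesets)) {
    term_matrix <- tryCatch(
      rollup_go(prot, genesets, min_members = config$rollup_min_members),
      error = function(e) {
        warning("gene-set rollup skipped: ", conditionMessage(e))
        NULL
      })
  }

  pca <- pca_cells(prot, n_components = config$n_components,
                   scale = config$scale_pca)
  ec <- eigencor(pca, metadata, config$eigencor_variables,
                 n_components = config$n_components, alpha = config$alpha)
  if (!is.null(term_matrix)) {
    term_pca <- pca_cells(term_matrix,
                          n_components = min(config$n_components,
                                             nrow(term_matrix),
                                             ncol(term_matrix) - 1L),
                          scale = config$scale_pca)
  }

  manifest <- list(
    package = "scpquant",
    version = as.character(utils::packageVersion("scpquant")),
    config = unclass(config),
    intensity_scale = paste("report intensities are linear;",
                            "matrices are log2 from build_matrix onward"),
    stages = fr$stages,
    cells_removed = fr$cells_removed,
    n_precursors_final = nrow(mat),
    n_proteins = nrow(prot),
    n_cells = ncol(prot),
    completeness = completeness,
    svd_converged = attr(imputed, "converged"),
    combat_batches = if (is.null(combat_model)) NULL else combat_model$batches
  )

  result <- structure(list(
    protein_matrix = prot, precursor_matrix = imputed,
    term_matrix = term_matrix, ibaq = ibaq, pca = pca, term_pca = term_pca,
    eigencor = ec, filter_report = fr, completeness = completeness,
    histone_factors = histone_factors, combat_model = combat_model,
    metadata = metadata, config = config, manifest = manifest
  ), class = "scp_result")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_matrix(prot, file.path(outdir, "protein_matrix.tsv"))
    write_matrix(imputed, file.path(outdir, "precursor_matrix_imputed.tsv"))
    if (!is.null(term_matrix)) {
      write_matrix(term_matrix, file.path(outdir, "term_matrix.tsv"))
    }
    utils::write.table(ibaq$table, file.path(outdir, "ibaq_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ec, file.path(outdir, "eigencor.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(histone_factors)) {
      utils::write.table(histone_factors,
                         file.path(outdir, "normalization_factors.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(scores = as.data.frame(pca$scores),
           loadings = as.data.frame(pca$loadings),
           explained_variance_fraction = pca$explained_variance_fraction),
      file.path(outdir, "pca.json"), digits = NA, pretty = TRUE)
    write_manifest(manifest, file.path(outdir, "manifest.json"))
  }
  result
}

#' @export
print.scp_result <- function(x, ...) {
  cat("scpquant pipeline result\n")
  print(x$filter_report)
  cat(sprintf("final: %d precursors x %d cells -> %d proteins\n",
              nrow(x$precursor_matrix), ncol(x$precursor_matrix),
              nrow(x$protein_matrix)))
  cat(sprintf("PC1 explains %.1f%% of variance\n",
              100 * x$pca$explained_variance_fraction[1]))
  invisible(x)
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper around [synthetic_truth()] / [simulate_dataset()] used
#' by the command-line interface.
#'
#' @param dir Output directory.
#' @param truth A `synthetic_truth`; defaults to [default_paper_scale()].
#' @return The [simulate_dataset()] result, invisibly.
#' @export
write_synthetic_dataset <- function(dir, truth = default_paper_scale()) {
  invisible(simulate_dataset(truth, dir = dir))
}
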