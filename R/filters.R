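#' Default histone gene-symbol patterns
#'
#' Regular expressions matching current HGNC histone gene symbols (H1-*, H2A*,
#' H2B*, H3*, H4* cluster/variant genes) and the legacy HIST* nomenclature.
#' Shipped as a plain-text data file so the list can be audited and replaced.
#'
#' @return Character vector of regular expressions.
#' @export
default_histone_patterns <- function() {
  path <- system.file("extdata", "histone_gene_patterns.txt",
                      package = "scpquant")
  if (path == "") {                    # during development, pre-install
    return(c("^H1-[0-9]", "^H2A", "^H2B", "^H3", "^H4", "^HIST"))
  }
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Flag keratin and histone contaminant classes on protein annotations
#'
#' Keratins are genes matching `^KRT[0-9]+` (case-insensitive); this
#' deliberately excludes keratin-associated proteins (`KRTAP*`), which are not
#' keratins. Histones are genes matching any of `histone_patterns`.
#'
#' @param annotations Data frame with a `gene_symbol` column.
#' @param histone_patterns Regular expressions; see
#'   [default_histone_patterns()].
#' @return `annotations` with logical columns `is_keratin` and `is_histone`
#'   set (replacing any existing values).
#' @export
flag_contaminant_classes <- function(annotations,
                                     histone_patterns =
                                       default_histone_patterns()) {
  stopifnot(is.data.frame(annotations), "gene_symbol" %in% names(annotations))
  gene <- annotations$gene_symbol
  annotations$is_keratin <- grepl("^KRT[0-9]+", gene, ignore.case = TRUE)
  hist_rx <- paste(histone_patterns, collapse = "|")
  annotations$is_histone <- grepl(hist_rx, gene)
  annotations
}

# -- filter-report bookkeeping -----------------------------------------------

#' Create an empty filter report
#'
#' A filter report logs record/precursor/cell counts through every stage of
#' the filtering cascade so the manifest can reconcile them exactly.
#'
#' @return An object of class `filter_report`.
#' @export
filter_report_new <- function() {
  structure(list(stages = list(), cells_removed = character(0)),
            class = "filter_report")
}

#' Append a stage to a filter report
#'
#' @param report A `filter_report`.
#' @param stage Stage name.
#' @param n_in,n_out Record (or unit) counts entering and leaving the stage.
#' @param unit What is being counted (`"records"`, `"precursors"`, `"cells"`).
#' @return The updated report.
#' @export
filter_report_add <- function(report, stage, n_in, n_out, unit = "records") {
  stopifnot(inherits(report, "filter_report"), n_out <= n_in)
  report$stages[[stage]] <- list(unit = unit, n_in = n_in, n_out = n_out,
                                 n_removed = n_in - n_out)
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter cascade:\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-28s %8d -> %8d %s (-%d)\n",
                nm, s$n_in, s$n_out, s$unit, s$n_removed))
  }
  if (length(x$cells_removed)) {
    cat("  cells removed:", paste(x$cells_removed, collapse = ", "), "\n")
  }
  invisible(x)
}

# -- record-level filters ----------------------------------------------------

#' Filter precursor records by identification q-value
#'
#' Keeps records with `q_value < threshold` (strict inequality: a record at
#' exactly the threshold is removed).
#'
#' @param records Precursor record data frame from [read_precursor_report()].
#' @param threshold FDR q-value cutoff, default 0.01.
#' @return The filtered records.
#' @export
filter_qvalue <- function(records, threshold = 0.01) {
  stopifnot(is.data.frame(records), "q_value" %in% names(records))
  records[records$q_value < threshold, , drop = FALSE]
}

#' Keep only precursors unambiguously assigned to one organism
#'
#' A record is kept iff every accession in its protein group is annotated
#' with `target_organism`. Groups mixing human and (say) bovine accessions are
#' removed: their peptides cannot be attributed to the human proteome without
#' risking quantitation from serum contamination.
#'
#' @param records Precursor record data frame.
#' @param annotations Protein annotation data frame from [read_fasta()];
#'   every accession occurring in `records` must be annotated.
#' @param target_organism Organism to require, default `"Homo sapiens"`.
#' @return The filtered records.
#' @export
filter_species_unambiguous <- function(records, annotations,
                                       target_organism = "Homo sapiens") {
  org <- stats::setNames(annotations$organism, annotations$accession)
  groups <- split_groups(records$protein_group)
  keep <- vapply(groups, function(accs) {
    o <- org[accs]
    if (anyNA(o)) {
      stop("no annotation for accession: ", accs[is.na(o)][1L])
    }
    all(o == target_organism)
  }, logical(1))
  records[keep, , drop = FALSE]
}

#' Remove precursors mapping to keratin contaminants
#'
#' A record is removed if any accession in its protein group is flagged
#' `is_keratin` in the annotations.
#'
#' @inheritParams filter_species_unambiguous
#' @return The filtered records.
#' @export
filter_keratins <- function(records, annotations) {
  if (!"is_keratin" %in% names(annotations)) {
    annotations <- flag_contaminant_classes(annotations)
  }
  ker <- stats::setNames(annotations$is_keratin, annotations$accession)
  groups <- split_groups(records$protein_group)
  keep <- vapply(groups, function(accs) {
    k <- ker[accs]
    if (anyNA(k)) stop("no annotation for accession: ", accs[is.na(k)][1L])
    !any(k)
  }, logical(1))
  records[keep, , drop = FALSE]
}

# -- matrix construction and matrix-level filters ----------------------------

#' Build a precursor-by-cell log2 intensity matrix
#'
#' Rows are precursors (modified sequence + charge), columns are cells (runs).
#' Values are `log2(intensity)`; entries are missing where the precursor was
#' not observed (no record, or a record without usable intensity).
#'
#' @param records Filtered precursor record data frame.
#' @param on_duplicate What to do with duplicate (precursor, run) pairs:
#'   `"error"` (default) or `"max"` (keep the highest intensity).
#' @return A numeric matrix with attributes `precursor_info` (data frame with
#'   `precursor_id`, `modified_sequence`, `charge`, `protein_group`,
#'   `gene_symbols`) describing the rows.
#' @export
build_matrix <- function(records, on_duplicate = c("error", "max")) {
  on_duplicate <- match.arg(on_duplicate)
  stopifnot(nrow(records) > 0)
  pid <- paste0(records$modified_sequence, "/", records$charge)
  key <- paste0(pid, "\r", records$run_id)
  if (anyDuplicated(key)) {
    if (on_duplicate == "error") {
      d <- key[duplicated(key)][1L]
      stop("duplicate precursor-run pair: ", sub("\r", " in run ", d))
    }
    ord <- order(key, -records$intensity, na.last = TRUE)
    records <- records[ord, , drop = FALSE]
    records <- records[!duplicated(key[ord]), , drop = FALSE]
    pid <- paste0(records$modified_sequence, "/", records$charge)
  }
  rows <- unique(pid)
  cols <- unique(records$run_id)
  mat <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
  mat[cbind(match(pid, rows), match(records$run_id, cols))] <-
    log2(records$intensity)
  first <- !duplicated(pid)
  attr(mat, "precursor_info") <- data.frame(
    precursor_id = pid[first],
    modified_sequence = records$modified_sequence[first],
    charge = records$charge[first],
    protein_group = records$protein_group[first],
    gene_symbols = records$gene_symbols[first],
    stringsAsFactors = FALSE
  )[match(rows, pid[first]), , drop = FALSE]
  mat
}

#' Remove cells with too few identified precursors
#'
#' Cells (columns) with fewer than `min_precursors` observed precursors are
#' dropped (strict: a cell at exactly the threshold is kept). Counts are taken
#' after the record-level filters.
#'
#' @param mat Precursor matrix from [build_matrix()].
#' @param min_precursors Minimum observed precursors per cell, default 500.
#' @return The filtered matrix, with attribute `cells_removed` listing the
#'   dropped cell ids.
#' @export
filter_cells_min_precursors <- function(mat, min_precursors = 500) {
  counts <- colSums(!is.na(mat))
  keep <- counts >= min_precursors
  if (!any(keep)) {
    stop("all cells have < ", min_precursors, " identified precursors; ",
         "review the min_precursors threshold")
  }
  out <- mat[, keep, drop = FALSE]
  attr(out, "precursor_info") <- attr(mat, "precursor_info")
  attr(out, "cells_removed") <- colnames(mat)[!keep]
  out
}

#' Remove precursors with insufficient sample coverage
#'
#' A precursor is kept iff it is observed in at least `min_fraction` of the
#' remaining cells (boundary inclusive: exactly 50% coverage is retained
#' under the default).
#'
#' @param mat Precursor matrix (after cell filtering).
#' @param min_fraction Minimum observed fraction of cells, default 0.5.
#' @return The filtered matrix with its `precursor_info` attribute subset.
#' @export
filter_precursor_coverage <- function(mat, min_fraction = 0.5) {
  frac <- rowMeans(!is.na(mat))
  keep <- frac >= min_fraction - 1e-12
  out <- mat[keep, , drop = FALSE]
  info <- attr(mat, "precursor_info")
  if (!is.null(info)) {
    attr(out, "precursor_info") <- info[keep, , drop = FALSE]
  }
  out
}

#' Precursor completeness profile
#'
#' For each coverage threshold t in `thresholds`, the number of precursors
#' observed in at least a fraction t of cells, plus the overall fraction of
#' observed matrix entries.
#'
#' @param mat Precursor matrix.
#' @param thresholds Coverage thresholds, default 0.1 ... 1.0.
#' @return A list with `counts` (named integer vector per threshold) and
#'   `completeness` (observed-entry fraction).
#' @export
completeness_profile <- function(mat, thresholds = seq(0.1, 1, by = 0.1)) {
  if (length(mat) == 0L || nrow(mat) == 0L) {
    return(list(counts = stats::setNames(rep(0L, length(thresholds)),
                                         sprintf("%.1f", thresholds)),
                completeness = 0))
  }
  frac <- rowMeans(!is.na(mat))
  counts <- vapply(thresholds, function(t) sum(frac >= t - 1e-12), integer(1))
  list(counts = stats::setNames(counts, sprintf("%.1f", thresholds)),
       completeness = mean(!is.na(mat)))
}
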