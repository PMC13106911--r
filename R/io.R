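#' Default Spectronaut-style column mapping for precursor reports
#'
#' Long-format DIA precursor reports name their columns differently between
#' search engines and export templates. A dialect maps the canonical field
#' names used throughout this package to the column headers found in the file.
#' The default mirrors a Spectronaut report export.
#'
#' @param ... Named overrides, e.g. `intensity = "FG.Quantity"`.
#' @return Named character vector mapping canonical field -> file column.
#' @export
#' @examples
#' spectronaut_dialect()
#' spectronaut_dialect(intensity = "FG.Quantity")
spectronaut_dialect <- function(...) {
  dialect <- c(
    run_id            = "R.FileName",
    protein_group     = "PG.ProteinGroups",
    gene_symbols      = "PG.Genes",
    organisms         = "PG.Organisms",
    modified_sequence = "EG.ModifiedSequence",
    charge            = "FG.Charge",
    q_value           = "EG.Qvalue",
    intensity         = "FG.MS2Quantity"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(dialect))
    if (length(bad)) {
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    }
    dialect[names(overrides)] <- overrides
  }
  dialect
}

# Intensity strings treated as missing before numeric coercion.
.missing_intensity_tokens <- c("", "NA", "NaN", "nan", "Filtered", "filtered")

#' Read a long-format precursor identification/intensity report
#'
#' Reads a tab-separated precursor report (one row per precursor x run) into a
#' canonical data frame. Multi-accession protein groups stay semicolon-joined;
#' use [split_groups()] to expand them. Intensities are linear-scale;
#' unparseable, empty or zero intensities become `NA` (an identified precursor
#' without usable quantitation). Strictly negative intensities are rejected.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Named mapping from canonical fields to column names; see
#'   [spectronaut_dialect()].
#' @return A `data.frame` with columns `run_id`, `protein_group`,
#'   `gene_symbols`, `organisms`, `modified_sequence`, `charge` (integer),
#'   `q_value` (numeric), `intensity` (numeric, `NA` = missing), one row per
#'   data row of the file, in file order.
#' @export
read_precursor_report <- function(path, dialect = spectronaut_dialect()) {
  if (!file.exists(path)) stop("precursor report not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           na.strings = NULL, showProgress = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols)) {
    stop("precursor report is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    run_id            = raw[[dialect[["run_id"]]]],
    protein_group     = raw[[dialect[["protein_group"]]]],
    gene_symbols      = raw[[dialect[["gene_symbols"]]]],
    organisms         = raw[[dialect[["organisms"]]]],
    modified_sequence = raw[[dialect[["modified_sequence"]]]],
    charge            = as.integer(raw[[dialect[["charge"]]]]),
    q_value           = as.numeric(raw[[dialect[["q_value"]]]]),
    stringsAsFactors  = FALSE
  )
  int_chr <- raw[[dialect[["intensity"]]]]
  int_chr[int_chr %in% .missing_intensity_tokens] <- NA_character_
  intensity <- suppressWarnings(as.numeric(int_chr))
  neg <- which(!is.na(intensity) & intensity < 0)
  if (length(neg)) {
    stop("negative intensity at data row ", neg[1L],
         " (value ", int_chr[neg[1L]], ")")
  }
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  out$intensity <- intensity
  if (anyNA(out$q_value)) {
    stop("unparseable q-value at data row ", which(is.na(out$q_value))[1L])
  }
  # group-wise fields must stay aligned accession-for-accession
  n_acc <- lengths(strsplit(out$protein_group, ";", fixed = TRUE))
  n_org <- lengths(strsplit(out$organisms, ";", fixed = TRUE))
  bad <- which(n_acc != n_org)
  if (length(bad)) {
    stop("protein_group/organisms length mismatch at data row ", bad[1L])
  }
  out
}

#' Split semicolon-joined protein-group fields
#'
#' @param x Character vector of semicolon-delimited values.
#' @return List of character vectors.
#' @export
split_groups <- function(x) strsplit(x, ";", fixed = TRUE)

#' Read a protein FASTA with UniProt-style headers
#'
#' Parses headers of the form `db|ACCESSION|NAME Description OS=<organism>
#' OX=... GN=<gene> ...`. The organism is taken from `OS=` up to the next
#' ` XX=` token; a missing `GN=` falls back to the accession. Keratin and
#' histone contaminant-class flags are computed with
#' [flag_contaminant_classes()].
#'
#' @param path Path to a FASTA file.
#' @param histone_patterns Regular expressions defining histone gene symbols;
#'   see [default_histone_patterns()].
#' @return A `data.frame` with columns `accession`, `gene_symbol`, `organism`,
#'   `sequence`, `is_keratin`, `is_histone`.
#' @export
read_fasta <- function(path, histone_patterns = default_histone_patterns()) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  accession <- sub("^[^|]*\\|([^|]+)\\|.*$", "\\1", headers)
  no_bar <- !grepl("\\|", headers)
  accession[no_bar] <- sub("\\s.*$", "", headers[no_bar])
  if (anyDuplicated(accession)) {
    stop("duplicate accession in FASTA: ",
         accession[duplicated(accession)][1L])
  }
  organism <- rep(NA_character_, length(headers))
  has_os <- grepl("OS=", headers, fixed = TRUE)
  os_part <- sub("^.*OS=", "", headers)
  organism[has_os] <- sub("\\s+[A-Z]{2}=.*$", "", os_part[has_os])
  gene <- rep(NA_character_, length(headers))
  has_gn <- grepl("GN=", headers, fixed = TRUE)
  gene[has_gn] <- sub("\\s.*$", "", sub("^.*GN=", "", headers[has_gn]))
  gene[!has_gn | is.na(gene) | gene == ""] <-
    accession[!has_gn | is.na(gene) | gene == ""]
  sequence <- as.character(seqs)
  if (any(nchar(sequence) == 0L)) {
    stop("empty sequence for accession: ", accession[nchar(sequence) == 0L][1L])
  }
  ann <- data.frame(
    accession = accession, gene_symbol = gene, organism = organism,
    sequence = unname(sequence), stringsAsFactors = FALSE
  )
  flag_contaminant_classes(ann, histone_patterns = histone_patterns)
}

#' Read a GMT gene-set file
#'
#' Each GMT line is `term_id TAB description TAB gene1 TAB gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (term id -> member genes) with a
#'   `term_names` attribute carrying the descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("GMT file is empty: ", path)
    sets <- list()
    attr(sets, "term_names") <- character(0)
    return(sets)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate GMT term id: ", ids[duplicated(ids)][1L])
  }
  descs <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- ids
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("GMT term with no member genes: ", ids[empty][1L])
  attr(sets, "term_names") <- stats::setNames(descs, ids)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  nm <- attr(sets, "term_names")
  descs <- if (is.null(nm)) names(sets) else unname(nm[names(sets)])
  lines <- mapply(function(id, d, genes) {
    paste(c(id, d, genes), collapse = "\t")
  }, names(sets), descs, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a feature-by-cell matrix as TSV
#'
#' The first column (`feature`) holds row names; missing entries are written
#' as empty cells. Values round-trip losslessly (written with 17 significant
#' digits).
#'
#' @param mat Numeric matrix with row and column names; `NA` = missing.
#' @param path Output / input path.
#' @return `write_matrix`: `path` invisibly; `read_matrix`: the matrix.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  chr <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  chr[is.na(mat)] <- ""
  df <- data.frame(feature = rownames(mat), chr, stringsAsFactors = FALSE)
  names(df) <- c("feature", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "", showProgress = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1L]]
  mat
}

#' Write a JSON run manifest
#'
#' Records parameters, seeds and stage counts for a pipeline run.
#'
#' @param manifest A named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
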