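# Synthetic single-cell DIA dataset generator.
#
# Emulates the statistical structure of a nanowell-chip single-cell DIA
# experiment: per-protein base abundances, per-precursor offsets, a cell-size
# (diameter) scaling axis with per-protein responsiveness, per-chip batch
# location/scale effects, gene-set (pathway) covariation, a per-cell nuisance
# loading factor, bovine-serum and keratin contaminants, and both
# intensity-dependent (MNAR) and completely-random (MCAR) missingness.
# Ground truth is returned alongside the generated files so every downstream
# stage has a recovery test.

#' Construct synthetic-truth generator parameters
#'
#' @param n_cells Number of single cells (>= 4).
#' @param n_chips Number of processing chips (batches); cells are assigned in
#'   consecutive blocks.
#' @param n_proteins Number of proteins in the FASTA (>= 10), including
#'   contaminants.
#' @param precursor_lambda Poisson rate; precursors per protein are
#'   `1 + rpois(precursor_lambda)` capped at 30 (each precursor is one
#'   tryptic peptide of the protein).
#' @param protein_base_mean,protein_base_sd Mean/SD of per-protein base log2
#'   abundance alpha_p.
#' @param precursor_offset_sd SD of per-precursor log2 offsets beta_j.
#' @param size_coefficient Log2-intensity change per log2-diameter change
#'   (the cell-size scaling factor s).
#' @param size_response_sd SD of the per-protein size responsiveness u_p
#'   (multiplier on the size term, mean 1, truncated at 0). Histone proteins
#'   are pinned at u = 1: they track the per-cell reference level, which is
#'   exactly the assumption the histone-median normalization encodes.
#' @param diameter_range Cell diameter range in micrometres, default 17-36.
#' @param batch_shift_sd SD of per-chip additive log2 shifts b_k.
#' @param batch_scale_sdlog SD (log scale) of per-chip multiplicative noise
#'   scales; 0 disables scale effects.
#' @param n_modules Number of covarying gene-set modules.
#' @param module_fraction Fraction of non-contaminant proteins assigned to a
#'   module.
#' @param module_sd SD of per-(module, cell) effects.
#' @param nuisance_sd SD of a per-cell loading factor shared by all proteins
#'   (what histone normalization is meant to remove).
#' @param noise_sd Residual log2 noise SD.
#' @param mnar_midpoint_log2,mnar_slope Logistic missingness link: an entry
#'   with true log2 intensity x is observed with probability
#'   `plogis(mnar_slope * (x - mnar_midpoint_log2))`; `mnar_slope = 0`
#'   disables intensity-dependent missingness (always observed).
#' @param mcar_rate Additional completely-at-random dropout probability.
#' @param contaminant_fraction Fraction of proteins that are contaminants
#'   (half bovine serum, half human keratin).
#' @param ambiguous_fraction Fraction of bovine-contaminant precursors whose
#'   protein group also lists a human accession (species-ambiguous records).
#' @param n_histones Number of designated histone proteins.
#' @param histone_boost_log2 Added to histone base abundance (histones are
#'   among the most abundant cellular proteins).
#' @param q_fail_rate Fraction of report rows drawn with q-value >= 0.01.
#' @param seed Integer seed; the whole dataset is reproducible given it.
#' @return An object of class `synthetic_truth` (validated parameter list).
#' @export
synthetic_truth <- function(n_cells = 48,
                            n_chips = 2,
                            n_proteins = 1100,
                            precursor_lambda = 2.2,
                            protein_base_mean = 14,
                            protein_base_sd = 2,
                            precursor_offset_sd = 1,
                            size_coefficient = 1,
                            size_response_sd = 0.8,
                            diameter_range = c(17, 36),
                            batch_shift_sd = 0.5,
                            batch_scale_sdlog = 0.1,
                            n_modules = 10,
                            module_fraction = 0.6,
                            module_sd = 0.5,
                            nuisance_sd = 0.3,
                            noise_sd = 0.5,
                            mnar_midpoint_log2 = 13,
                            mnar_slope = 0.6,
                            mcar_rate = 0.05,
                            contaminant_fraction = 0.05,
                            ambiguous_fraction = 0.3,
                            n_histones = 8,
                            histone_boost_log2 = 2,
                            q_fail_rate = 0.02,
                            seed = 1) {
  stopifnot(n_cells >= 4, n_proteins >= 10, n_chips >= 1,
            diameter_range[1] > 0, diameter_range[2] > diameter_range[1],
            noise_sd >= 0, mnar_slope >= 0, batch_scale_sdlog >= 0)
  rates <- c(mcar_rate = mcar_rate, contaminant_fraction = contaminant_fraction,
             ambiguous_fraction = ambiguous_fraction, q_fail_rate = q_fail_rate,
             module_fraction = module_fraction)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stop("rate parameter(s) outside [0, 1]: ",
         paste(names(rates)[bad], collapse = ", "))
  }
  structure(as.list(environment()), class = "synthetic_truth")
}

#' Generator parameters at the scale of a 48-cell chip study
#'
#' Returns [synthetic_truth()] defaults calibrated so that a generated
#' dataset, after the standard filtering cascade, has per-cell precursor
#' counts and precursor completeness of the same order of magnitude as a
#' single-chip (48-nanowell) single-cell DIA study of primary human cells:
#' on the order of 2-3 thousand observed precursors per cell and roughly half
#' of all retained precursors observed in at least half of the cells.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_truth()].
#' @return A `synthetic_truth` object.
#' @export
default_paper_scale <- function(seed = 1, ...) {
  synthetic_truth(seed = seed, ...)
}

# amino acids excluding K and R (cleavage sites placed explicitly)
.aa_no_kr <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
               "N", "P", "Q", "S", "T", "V", "W", "Y")

.default_histone_symbols <- c("H2AC4", "H2AZ1", "H2BC11", "H3C1", "H3-3A",
                              "H4C1", "H1-2", "H1-4", "H2AC20", "H2BC21",
                              "H3C15", "H4C3", "H2BC12", "H1-5")

# build one protein as n_pep tryptic fragments, each ending in K/R,
# interior residues drawn from the non-K/R alphabet
.make_peptides <- function(n_pep, min_len = 6, max_len = 30) {
  lens <- sample(seq(min_len, max_len), n_pep, replace = TRUE)
  vapply(lens, function(l) {
    paste0(paste(sample(.aa_no_kr, l - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, "")
}

#' Simulate a complete synthetic single-cell DIA dataset
#'
#' Draws a dataset under the generative model of [synthetic_truth()]: the
#' true log2 intensity of precursor j (of protein p) in cell c is
#' `alpha_p + beta_j + s * u_p * (log2 d_c - mean log2 d) + b_chip(c) +
#' module effect + nu_c + Normal(0, noise_sd * batch_scale_chip(c))`;
#' the observed linear intensity is `2^x`; each entry is observed with
#' probability `plogis(mnar_slope * (x - mnar_midpoint)) * (1 - mcar_rate)`.
#' Contaminant proteins (bovine serum, human keratins) and a configurable
#' fraction of q-value failures are injected; designated histone proteins are
#' abundant and size-neutral (u = 1).
#'
#' @param truth A `synthetic_truth` parameter object.
#' @param dir Optional output directory; when given, the precursor report
#'   (`report.tsv`), FASTA (`proteins.fasta`), metadata (`metadata.tsv`),
#'   gene sets (`genesets.gmt`) and realized ground truth (`truth.json`) are
#'   written there.
#' @return A list with `report` (precursor record data frame in canonical
#'   columns), `annotations` (as [read_fasta()]), `metadata`, `genesets`,
#'   `truth` (realized ground-truth record) and, when `dir` is given,
#'   `paths`.
#' @export
simulate_dataset <- function(truth, dir = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  p <- truth

  # -- cells -----------------------------------------------------------------
  cell_id <- sprintf("cell_%03d", seq_len(p$n_cells))
  chip_size <- ceiling(p$n_cells / p$n_chips)
  chip_idx <- rep(seq_len(p$n_chips), each = chip_size)[seq_len(p$n_cells)]
  chip_id <- sprintf("chip_%02d", chip_idx)
  diameter <- stats::runif(p$n_cells, p$diameter_range[1], p$diameter_range[2])
  size_term_cell <- log2(diameter) - mean(log2(diameter))
  batch_shift <- stats::rnorm(p$n_chips, 0, p$batch_shift_sd)
  batch_scale <- exp(stats::rnorm(p$n_chips, 0, p$batch_scale_sdlog))
  nu <- stats::rnorm(p$n_cells, 0, p$nuisance_sd)

  # -- protein classes -------------------------------------------------------
  n_cont <- round(p$contaminant_fraction * p$n_proteins)
  n_bovine <- ceiling(n_cont / 2)
  n_keratin <- n_cont - n_bovine
  n_human <- p$n_proteins - n_cont
  n_hist <- min(p$n_histones, n_human, length(.default_histone_symbols))
  class <- c(rep("human", n_human), rep("bovine", n_bovine),
             rep("keratin", n_keratin))
  accession <- character(p$n_proteins)
  gene <- character(p$n_proteins)
  organism <- character(p$n_proteins)
  accession[class == "human"] <- sprintf("SYNH%04d", seq_len(n_human))
  accession[class == "bovine"] <- sprintf("SYNB%04d", seq_len(n_bovine))
  accession[class == "keratin"] <- sprintf("SYNK%04d", seq_len(n_keratin))
  gene[class == "human"] <- sprintf("GENE%04d", seq_len(n_human))
  gene[class == "human"][seq_len(n_hist)] <-
    .default_histone_symbols[seq_len(n_hist)]
  gene[class == "bovine"] <- sprintf("BTGENE%03d", seq_len(n_bovine))
  gene[class == "keratin"] <- paste0("KRT", seq_len(n_keratin))
  organism[class != "bovine"] <- "Homo sapiens"
  organism[class == "bovine"] <- "Bos taurus"
  is_histone_true <- class == "human" & gene %in% .default_histone_symbols

  # -- sequences / precursors ------------------------------------------------
  n_pep <- pmin(1L + stats::rpois(p$n_proteins, p$precursor_lambda), 30L)
  peptides <- lapply(n_pep, .make_peptides)
  all_pep <- unlist(peptides)
  while (anyDuplicated(all_pep)) {          # enforce globally unique peptides
    dup <- which(duplicated(all_pep))
    repl <- .make_peptides(length(dup))
    all_pep[dup] <- repl
  }
  prot_of_prec <- rep(seq_len(p$n_proteins), n_pep)
  n_prec <- length(all_pep)
  charge <- sample(2:3, n_prec, replace = TRUE)

  sequences <- vapply(split(all_pep, prot_of_prec)[
    as.character(seq_len(p$n_proteins))], paste, "", collapse = "")

  # -- effects ---------------------------------------------------------------
  alpha <- stats::rnorm(p$n_proteins, p$protein_base_mean, p$protein_base_sd)
  alpha[is_histone_true] <- alpha[is_histone_true] + p$histone_boost_log2
  beta <- stats::rnorm(n_prec, 0, p$precursor_offset_sd)
  u <- pmax(stats::rnorm(p$n_proteins, 1, p$size_response_sd), 0)
  u[is_histone_true] <- 1
  module <- rep(NA_integer_, p$n_proteins)
  eligible <- which(class == "human" & !is_histone_true)
  in_module <- eligible[stats::runif(length(eligible)) < p$module_fraction]
  module[in_module] <- sample(seq_len(p$n_modules), length(in_module),
                              replace = TRUE)
  module_effect <- matrix(stats::rnorm(p$n_modules * p$n_cells, 0,
                                       p$module_sd),
                          p$n_modules, p$n_cells)

  # -- true intensities and observation --------------------------------------
  # precursor x cell true log2 intensity
  x <- matrix(alpha[prot_of_prec] + beta, n_prec, p$n_cells)
  x <- x + outer(p$size_coefficient * u[prot_of_prec], size_term_cell)
  x <- x + matrix(batch_shift[chip_idx], n_prec, p$n_cells, byrow = TRUE)
  mod_rows <- !is.na(module[prot_of_prec])
  x[mod_rows, ] <- x[mod_rows, ] +
    module_effect[module[prot_of_prec][mod_rows], , drop = FALSE]
  x <- x + matrix(nu, n_prec, p$n_cells, byrow = TRUE)
  noise_scale <- p$noise_sd * batch_scale[chip_idx]
  x <- x + matrix(stats::rnorm(n_prec * p$n_cells), n_prec, p$n_cells) *
    matrix(noise_scale, n_prec, p$n_cells, byrow = TRUE)

  p_obs <- if (p$mnar_slope > 0) {
    stats::plogis(p$mnar_slope * (x - p$mnar_midpoint_log2))
  } else {
    matrix(1, n_prec, p$n_cells)
  }
  p_obs <- p_obs * (1 - p$mcar_rate)
  observed <- matrix(stats::runif(n_prec * p$n_cells), n_prec, p$n_cells) <
    p_obs

  # -- species-ambiguous bovine groups ---------------------------------------
  group_of_prec <- accession[prot_of_prec]
  genes_of_prec <- gene[prot_of_prec]
  orgs_of_prec <- organism[prot_of_prec]
  bov_prec <- which(class[prot_of_prec] == "bovine")
  if (length(bov_prec) && p$ambiguous_fraction > 0 && n_human > 0) {
    amb <- bov_prec[stats::runif(length(bov_prec)) < p$ambiguous_fraction]
    if (length(amb)) {
      partner <- sample(which(class == "human"), length(amb), replace = TRUE)
      group_of_prec[amb] <- paste(accession[partner], accession[prot_of_prec][amb],
                                  sep = ";")
      genes_of_prec[amb] <- paste(gene[partner], gene[prot_of_prec][amb],
                                  sep = ";")
      orgs_of_prec[amb] <- paste(organism[partner],
                                 organism[prot_of_prec][amb], sep = ";")
    }
  }

  # -- long-format report ----------------------------------------------------
  idx <- which(observed, arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  jj <- idx[, 1L]
  cc <- idx[, 2L]
  n_rows <- nrow(idx)
  fail <- stats::runif(n_rows) < p$q_fail_rate
  q_vals <- ifelse(fail,
                   stats::runif(n_rows, 0.01, 0.2),
                   stats::runif(n_rows, 0, 0.0099))
  report <- data.frame(
    run_id = cell_id[cc],
    protein_group = group_of_prec[jj],
    gene_symbols = genes_of_prec[jj],
    organisms = orgs_of_prec[jj],
    modified_sequence = paste0("_", all_pep[jj], "_"),
    charge = charge[jj],
    q_value = round(q_vals, 6),
    intensity = as.numeric(sprintf("%.9g", 2^x[cbind(jj, cc)])),
    stringsAsFactors = FALSE
  )

  metadata <- data.frame(
    cell_id = cell_id, chip_id = chip_id,
    diameter_um = round(diameter, 2), passed_image_qc = TRUE,
    stringsAsFactors = FALSE
  )

  gsets <- lapply(seq_len(p$n_modules), function(m) {
    sort(gene[which(!is.na(module) & module == m)])
  })
  names(gsets) <- sprintf("GO:SYN%04d", seq_len(p$n_modules))
  gsets <- gsets[lengths(gsets) > 0L]
  attr(gsets, "term_names") <- stats::setNames(
    sprintf("synthetic module %d", as.integer(sub("GO:SYN", "", names(gsets)))),
    names(gsets))

  annotations <- flag_contaminant_classes(data.frame(
    accession = accession, gene_symbol = gene, organism = organism,
    sequence = unname(sequences), stringsAsFactors = FALSE
  ))

  truth_out <- list(
    parameters = unclass(p),
    accession = accession, gene = gene, organism = organism, class = class,
    is_histone = is_histone_true, alpha = alpha, u = u, module = module,
    n_precursors_per_protein = n_pep,
    precursor_protein = prot_of_prec, precursor_offset = beta,
    precursor_peptide = all_pep, precursor_charge = charge,
    cell_id = cell_id, chip_id = chip_id, diameter_um = diameter,
    batch_shift_log2 = batch_shift, batch_scale = batch_scale,
    nuisance = nu, module_effect = module_effect,
    contaminant_precursor = class[prot_of_prec] != "human"
  )

  out <- list(report = report, annotations = annotations, metadata = metadata,
              genesets = gsets, truth = truth_out)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      report = file.path(dir, "report.tsv"),
      fasta = file.path(dir, "proteins.fasta"),
      metadata = file.path(dir, "metadata.tsv"),
      gmt = file.path(dir, "genesets.gmt"),
      truth = file.path(dir, "truth.json")
    )
    .write_report_tsv(report, paths$report)
    .write_fasta(annotations, paths$fasta)
    utils::write.table(metadata, paths$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_gmt(gsets, paths$gmt)
    truth_json <- truth_out
    truth_json$module_effect <- NULL     # matrices serialize poorly; re-derive
    jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    out$paths <- paths
  }
  out
}

# write canonical records under Spectronaut-style column names
.write_report_tsv <- function(report, path,
                              dialect = spectronaut_dialect()) {
  df <- report
  names(df) <- unname(dialect[names(report)])
  df[[dialect[["intensity"]]]] <- sprintf("%.9g", report$intensity)
  df[[dialect[["q_value"]]]] <- sprintf("%.6g", report$q_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_fasta <- function(annotations, path) {
  header <- sprintf("%s|%s|%s_%s Synthetic protein OS=%s OX=%d GN=%s PE=1 SV=1",
                    ifelse(annotations$organism == "Homo sapiens", "sp", "tr"),
                    annotations$accession, annotations$gene_symbol,
                    ifelse(annotations$organism == "Homo sapiens",
                           "HUMAN", "BOVIN"),
                    annotations$organism,
                    ifelse(annotations$organism == "Homo sapiens",
                           9606L, 9913L),
                    annotations$gene_symbol)
  seqs <- Biostrings::AAStringSet(annotations$sequence)
  names(seqs) <- header
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
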