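# Filtering cascade: boundaries, hand counts, contaminant flags.

make_records <- function(q = 0.005, n = 1, run = "c1", group = "P1",
                         genes = "G1", orgs = "Homo sapiens",
                         pep = "_PEPK_", charge = 2L, intensity = 100) {
  data.frame(run_id = run, protein_group = group, gene_symbols = genes,
             organisms = orgs, modified_sequence = pep, charge = charge,
             q_value = q, intensity = intensity, stringsAsFactors = FALSE)
}

test_that("q-value filter is strict at the threshold", {
  rec <- do.call(rbind, lapply(
    c(0.009, 0.01, 0.0099, 0.011, 0.02, 0.5, 0.001, 0.005, 0.0001, 0.009),
    make_records))
  kept <- filter_qvalue(rec)
  expect_equal(nrow(kept), 6L)              # removes 0.01, 0.011, 0.02, 0.5
  expect_true(all(kept$q_value < 0.01))
  expect_equal(nrow(filter_qvalue(rec[0, ])), 0L)
})

ann_fixture <- data.frame(
  accession = c("H1", "H2", "B1", "K1", "HIS1"),
  gene_symbol = c("TP53", "ACTB", "ALB", "KRT10", "H2BC11"),
  organism = c(rep("Homo sapiens", 2), "Bos taurus", rep("Homo sapiens", 2)),
  sequence = "MAAAAAK", stringsAsFactors = FALSE
)

test_that("species filter requires every group member to be target organism", {
  rec <- rbind(make_records(group = "H1", orgs = "Homo sapiens"),
               make_records(group = "H2", orgs = "Homo sapiens"),
               make_records(group = "HIS1", orgs = "Homo sapiens"),
               make_records(group = "H1;B1",
                            orgs = "Homo sapiens;Bos taurus"),
               make_records(group = "B1", orgs = "Bos taurus"))
  kept <- filter_species_unambiguous(rec, ann_fixture)
  expect_equal(kept$protein_group, c("H1", "H2", "HIS1"))
  expect_error(
    filter_species_unambiguous(make_records(group = "XX"), ann_fixture),
    "XX")
})

test_that("contaminant-class flags follow the gene-symbol rules", {
  ann <- flag_contaminant_classes(data.frame(
    gene_symbol = c("KRT10", "KRTAP1-1", "krt5", "H2BC11", "H1-4", "HIST1H2BK",
                    "TP53", "H19X"),
    stringsAsFactors = FALSE))
  expect_equal(ann$is_keratin,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(ann$is_histone,
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("keratin filter removes records with any keratin group member", {
  rec <- rbind(make_records(group = "H1"),
               make_records(group = "K1"),
               make_records(group = "H1;K1"))
  expect_equal(filter_keratins(rec, ann_fixture)$protein_group, "H1")
})

test_that("matrix construction maps intensities to log2 and flags duplicates", {
  rec <- rbind(
    make_records(run = "c1", pep = "_A_", intensity = 8),
    make_records(run = "c2", pep = "_A_", intensity = 16),
    make_records(run = "c1", pep = "_B_", intensity = 2)
  )
  m <- build_matrix(rec)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["_A_/2", "c1"], 3)
  expect_equal(sum(is.na(m)), 1L)           # _B_ unobserved in c2

  dup <- rbind(rec, make_records(run = "c1", pep = "_A_", intensity = 9))
  expect_error(build_matrix(dup), "duplicate precursor-run")
  m2 <- build_matrix(dup, on_duplicate = "max")
  expect_equal(m2["_A_/2", "c1"], log2(9))
})

test_that("cell filter drops below-threshold cells, strict boundary", {
  counts <- c(c1 = 700, c2 = 650, c3 = 499, c4 = 30, c5 = 501)
  rec <- data.frame(
    run_id = rep(names(counts), counts),
    protein_group = "P1", gene_symbols = "G1", organisms = "Homo sapiens",
    modified_sequence = sprintf("_P%04d_",
                                unlist(lapply(counts, seq_len))),
    charge = 2L, q_value = 0.005, intensity = 100, stringsAsFactors = FALSE)
  m <- build_matrix(rec)
  m2 <- filter_cells_min_precursors(m, 500)
  expect_setequal(colnames(m2), c("c1", "c2", "c5"))
  expect_setequal(attr(m2, "cells_removed"), c("c3", "c4"))
  expect_error(filter_cells_min_precursors(m, 1e9), "all cells")
  expect_equal(ncol(filter_cells_min_precursors(m, 1)), 5L)
})

test_that("coverage filter keeps the inclusive 50% boundary", {
  m <- matrix(NA_real_, 10, 10,
              dimnames = list(paste0("p", 1:10), paste0("c", 1:10)))
  cov <- c(0.2, 0.2, 0.2, 0.5, 0.5, 1, 1, 1, 1, 1)
  for (i in 1:10) m[i, seq_len(cov[i] * 10)] <- 5
  kept <- filter_precursor_coverage(m, 0.5)
  expect_equal(nrow(kept), 7L)
  expect_false(any(grepl("^p[123]$", rownames(kept))))

  m4 <- m[, 1:4]
  expect_true("p4" %in% rownames(filter_precursor_coverage(m4, 0.5)))
})

test_that("completeness profile counts precursors per coverage threshold", {
  m <- matrix(NA_real_, 8, 8)
  m[1:4, ] <- 1                              # half fully observed
  m[5:8, 1:2] <- 1                           # half at 25%
  rownames(m) <- paste0("p", 1:8); colnames(m) <- paste0("c", 1:8)
  prof <- completeness_profile(m)
  expect_equal(unname(prof$counts[["0.5"]]), 4L)
  expect_equal(unname(prof$counts[["1.0"]]), 4L)
  expect_equal(unname(prof$counts[["0.1"]]), 8L)
  expect_equal(prof$completeness, (4 * 8 + 4 * 2) / 64)
  expect_equal(unname(completeness_profile(m[0, ])$counts[["0.5"]]), 0L)
})

test_that("species and keratin filters remove exactly the truth-labelled
          contaminants on synthetic data", {
  sim <- simulate_dataset(small_truth())
  rec <- sim$report
  is_cont <- vapply(split_groups(rec$protein_group), function(accs) {
    any(sim$truth$class[match(accs, sim$truth$accession)] != "human")
  }, logical(1))
  kept <- filter_keratins(
    filter_species_unambiguous(rec, sim$annotations), sim$annotations)
  expect_setequal(
    paste(kept$modified_sequence, kept$charge, kept$run_id),
    paste(rec$modified_sequence, rec$charge, rec$run_id)[!is_cont])
})

test_that("filter report reconciles and enforces monotone counts", {
  fr <- filter_report_new()
  fr <- filter_report_add(fr, "q_value", 100, 90)
  fr <- filter_report_add(fr, "species", 90, 80)
  expect_equal(fr$stages$q_value$n_removed, 10)
  expect_error(filter_report_add(fr, "bad", 10, 20))
  expect_output(print(fr), "q_value")
})
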