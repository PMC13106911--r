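# Median centering, SVD imputation, MaxLFQ, digestion and iBAQ.

test_that("median centering is observed-only, exact and idempotent", {
  m <- rbind(a = c(4, 6, 8), b = c(4, NA, 8))
  colnames(m) <- paste0("c", 1:3)
  cm <- median_center_rows(m)
  expect_equal(cm["a", ], c(c1 = -2, c2 = 0, c3 = 2))
  expect_equal(cm["b", ], c(c1 = -2, c2 = NA, c3 = 2))
  expect_equal(median_center_rows(cm), cm)
  m_bad <- rbind(m, d = c(NA, NA, NA))
  expect_error(median_center_rows(m_bad), "no observed")
})

test_that("svd imputation recovers low-rank structure", {
  # complete matrix is untouched
  full <- rank_k_matrix(6, 5, 2, seed = 1)
  expect_equal(svd_impute(full, 2), full, ignore_attr = TRUE)

  # single missing entry in a 3x3 rank-1 matrix: closed-form u_i * v_j
  u <- c(1, 2, 3); v <- c(2, 1, 4)
  m <- outer(u, v)
  m[2, 3] <- NA
  imp <- svd_impute(m, 1, tol = 1e-12, max_iter = 500)
  expect_equal(imp[2, 3], u[2] * v[3], tolerance = 1e-8)

  # 20x10 rank-1, 10% masked, k=1: near-exact recovery
  set.seed(42)
  truth <- rank_k_matrix(20, 10, 1)
  mask <- matrix(runif(200) < 0.1, 20, 10)
  obs <- truth; obs[mask] <- NA
  imp <- svd_impute(obs, 1, tol = 1e-10, max_iter = 1000)
  expect_lt(sqrt(mean((imp[mask] - truth[mask])^2)), 1e-6)
  expect_identical(imp[!mask], truth[!mask])   # observed never modified

  # parameter errors and non-convergence warning
  expect_error(svd_impute(obs, 10), "n_components")
  expect_warning(svd_impute(obs, 1, tol = 1e-12, max_iter = 1),
                 "did not converge")
})

test_that("svd imputation beats the data SD on noisy rank-3 data", {
  set.seed(7)
  signal <- rank_k_matrix(60, 30, 3)
  signal <- signal / sd(signal)
  noisy <- signal + rnorm(1800, sd = sqrt(1 / 10))   # SNR 10 (variance ratio)
  # MNAR-light: lower values slightly more likely missing, ~20% overall
  p_miss <- plogis(-(noisy - quantile(noisy, 0.2)))
  p_miss <- p_miss * 0.2 / mean(p_miss)
  mask <- matrix(runif(1800) < p_miss, 60, 30)
  obs <- noisy; obs[mask] <- NA
  obs <- obs[rowSums(!is.na(obs)) > 0, ]
  imp <- svd_impute(obs, 3, tol = 1e-6, max_iter = 500)
  miss <- is.na(obs)
  rmse <- sqrt(mean((imp[miss] - noisy[rowSums(!is.na(obs)) > 0, ][miss])^2))
  expect_lt(rmse, sd(noisy))
})

test_that("maxlfq reproduces hand-worked and degenerate cases", {
  # single precursor: identity
  m1 <- matrix(c(10, 12), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(maxlfq(m1), c(a = 10, b = 12))

  # two complete precursors: profile (x, x+2, x+1) anchored to mean 12.5
  m2 <- rbind(c(10, 12, 11), c(13, 15, 14))
  colnames(m2) <- c("a", "b", "c")
  expect_equal(maxlfq(m2), c(a = 11.5, b = 13.5, c = 12.5))

  # disconnected components anchored independently
  m3 <- rbind(c(10, 12, NA, NA), c(NA, NA, 20, 24))
  colnames(m3) <- letters[1:4]
  w <- maxlfq(m3)
  expect_equal(w[["b"]] - w[["a"]], 2)
  expect_equal(w[["d"]] - w[["c"]], 4)
  expect_equal(mean(w[1:2]), 11)
  expect_equal(mean(w[3:4]), 22)

  # unobserved cell stays missing
  m4 <- rbind(c(10, 11, NA))
  colnames(m4) <- c("a", "b", "c")
  expect_equal(maxlfq(m4), c(a = 10, b = 11, c = NA))

  expect_error(maxlfq(matrix(numeric(0), 0, 0)), "empty")
})

test_that("maxlfq matches the dense least-squares oracle", {
  set.seed(101)
  for (i in 1:60) {
    mat <- random_connected_instance(sample(3:6, 1), sample(2:8, 1))
    colnames(mat) <- paste0("c", seq_len(ncol(mat)))
    w <- maxlfq(mat)
    o <- oracle_maxlfq(mat)
    expect_lt(max(abs(diff(w) - diff(o)), na.rm = TRUE), 1e-8)
    expect_equal(w, o, tolerance = 1e-8)
  }
})

test_that("maxlfq identities: shift equivariance and offset invariance", {
  set.seed(202)
  for (i in 1:25) {
    mat <- random_connected_instance(4, 5)
    colnames(mat) <- paste0("c", 1:4)
    w <- maxlfq(mat)
    # adding a constant shifts estimates by that constant
    expect_equal(maxlfq(mat + 3.25), w + 3.25, tolerance = 1e-10)
    # per-precursor offsets leave between-cell differences unchanged
    off <- rnorm(nrow(mat))
    w2 <- maxlfq(mat + off)
    expect_equal(diff(w2), diff(w), tolerance = 1e-10)
  }
})

test_that("protein summarization applies maxlfq per group deterministically", {
  m <- rbind(c(10, 12, 11), c(13, 15, 14), c(5, 6, 7))
  colnames(m) <- paste0("c", 1:3)
  grouping <- c("B1", "B1", "A1;A2")
  prot <- summarize_all_proteins(m, grouping)
  expect_equal(rownames(prot), c("A1;A2", "B1"))   # sorted by lead accession
  expect_equal(prot["B1", ], maxlfq(m[1:2, ]))
  expect_equal(prot["A1;A2", ], c(c1 = 5, c2 = 6, c3 = 7))
  info <- attr(prot, "protein_info")
  expect_equal(info$lead_accession, c("A1", "B1"))
  expect_equal(info$n_precursors, c(1L, 2L))

  # pre-imputation: group fully missing in one cell gives missing protein value
  m2 <- rbind(c(10, NA), c(12, NA))
  colnames(m2) <- c("c1", "c2")
  expect_true(is.na(summarize_all_proteins(m2, c("g", "g"))["g", "c2"]))

  # random multi-group instance equals per-group oracle
  set.seed(303)
  mm <- random_connected_instance(5, 15, miss_rate = 0.2)
  colnames(mm) <- paste0("c", 1:5)
  gg <- sample(paste0("P", 1:5), 15, replace = TRUE)
  prot2 <- summarize_all_proteins(mm, gg)
  for (g in unique(gg)) {
    expect_equal(prot2[g, ], oracle_maxlfq(mm[gg == g, , drop = FALSE]),
                 tolerance = 1e-8)
  }
})

test_that("tryptic peptide counting matches the worked examples", {
  expect_equal(theoretical_tryptic_peptides("MAAAAAKGGGGGGRTTTTTTK"), 3L)
  expect_equal(theoretical_tryptic_peptides("MK"), 0L)
  expect_equal(theoretical_tryptic_peptides(strrep("A", 20)), 1L)
  expect_error(theoretical_tryptic_peptides("MAB1"), "invalid residue")
  # proline rule suppresses cleavage before P
  expect_equal(theoretical_tryptic_peptides("AAAKPAAAK", proline_rule = TRUE),
               1L)
  expect_equal(theoretical_tryptic_peptides("AAAKPAAAK", proline_rule = FALSE),
               0L)   # fragments AAAK, PAAAK: 4 < 6, 5 < 6
})

test_that("tryptic peptide counting matches the brute-force oracle", {
  set.seed(404)
  for (i in 1:100) {
    s <- random_aa_sequence(sample(10:2000, 1))
    mc <- sample(0:2, 1)
    pr <- sample(c(TRUE, FALSE), 1)
    expect_equal(
      theoretical_tryptic_peptides(s, missed_cleavages = mc,
                                   proline_rule = pr),
      oracle_digest(s, missed_cleavages = mc, proline_rule = pr),
      info = sprintf("len=%d mc=%d pr=%s", nchar(s), mc, pr))
  }
})

ibaq_ann <- data.frame(
  accession = c("A1", "B1"),
  gene_symbol = c("GA1", "GB1"),
  organism = "Homo sapiens",
  sequence = c("MAAAAAKGGGGGGRTTTTTTKCCCCCCK",   # 4 observable peptides
               "MAAAAAKGGGGGGR"),                # 2 observable peptides
  stringsAsFactors = FALSE
)

test_that("iBAQ divides summed intensity by observable peptide count", {
  m <- rbind(c(100, 300))
  rownames(m) <- "_PEP_/2"; colnames(m) <- c("c1", "c2")
  res <- compute_ibaq(m, grouping = "A1", annotations = ibaq_ann)
  expect_equal(unname(res$per_cell["A1", ]), c(25, 75))
  expect_equal(res$table$theoretical_peptides, 4L)
  expect_equal(res$table$median_log10_ibaq, median(log10(c(25, 75))))

  # doubling intensities doubles iBAQ exactly
  res2 <- compute_ibaq(2 * m, grouping = "A1", annotations = ibaq_ann)
  expect_equal(res2$per_cell, 2 * res$per_cell)

  # top-N larger than the table keeps everything
  m2 <- rbind(c(100, 300), c(10, NA))
  rownames(m2) <- c("p1", "p2"); colnames(m2) <- c("c1", "c2")
  res3 <- compute_ibaq(m2, grouping = c("A1", "B1"), annotations = ibaq_ann,
                       top_n = 500, min_obs_fraction = 0)
  expect_equal(nrow(res3$table), 2L)
  expect_equal(res3$table$rank, 1:2)

  # random fixture equals the sum/divide oracle
  set.seed(505)
  mm <- matrix(exp(rnorm(40, 5)), 8, 5,
               dimnames = list(paste0("p", 1:8), paste0("c", 1:5)))
  mm[sample(40, 8)] <- NA
  gg <- rep(c("A1", "B1"), each = 4)
  res4 <- compute_ibaq(mm, grouping = gg, annotations = ibaq_ann)
  for (g in c("A1", "B1")) {
    np <- if (g == "A1") 4 else 2
    sums <- colSums(mm[gg == g, ], na.rm = TRUE)
    sums[colSums(!is.na(mm[gg == g, ])) == 0] <- NA
    expect_equal(res4$per_cell[g, ], sums / np)
  }
})
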