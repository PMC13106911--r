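# Independent oracles and shared fixtures for the test suite.

# ---- brute-force MaxLFQ oracle ---------------------------------------------
# Dense least squares on the pairwise-median ratio graph, solved by fixing
# one cell per connected component to zero (QR on the reduced design) and
# re-anchoring to the component's observed mean. Shares no code with
# scpquant::maxlfq.
oracle_maxlfq <- function(mat, min_shared = 1) {
  n <- ncol(mat)
  obs <- !is.na(mat)
  pairs <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      shared <- which(obs[, a] & obs[, b])
      if (length(shared) >= min_shared && length(shared) > 0) {
        pairs[[length(pairs) + 1]] <-
          list(a = a, b = b, r = median(mat[shared, b] - mat[shared, a]))
      }
    }
  }
  # union-find components over cells with observations
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (p in pairs) union(p$a, p$b)
  comp <- vapply(seq_len(n), find, integer(1))

  w <- rep(NA_real_, n)
  names(w) <- colnames(mat)
  active <- which(colSums(obs) > 0)
  for (cid in unique(comp[active])) {
    cells <- intersect(which(comp == cid), active)
    cp <- Filter(function(p) p$a %in% cells, pairs)
    sol <- numeric(length(cells))
    names(sol) <- as.character(cells)
    if (length(cp)) {
      free <- cells[-length(cells)]
      A <- matrix(0, length(cp), length(free))
      r <- numeric(length(cp))
      for (i in seq_along(cp)) {
        p <- cp[[i]]
        if (p$a %in% free) A[i, match(p$a, free)] <- -1
        if (p$b %in% free) A[i, match(p$b, free)] <- 1
        r[i] <- p$r
      }
      fit <- qr.solve(qr(A), r)
      sol[as.character(free)] <- fit
    }
    anchor <- mean(mat[, cells][obs[, cells]])
    w[cells] <- sol[as.character(cells)] - mean(sol) + anchor
  }
  w
}

# random MaxLFQ instance whose cell-pair graph is connected
random_connected_instance <- function(n_cells, n_prec, miss_rate = 0.3,
                                      min_shared = 1) {
  repeat {
    mat <- matrix(rnorm(n_prec * n_cells, 12, 2), n_prec, n_cells)
    mask <- matrix(runif(n_prec * n_cells) < miss_rate, n_prec, n_cells)
    mat[mask] <- NA
    if (any(colSums(!is.na(mat)) == 0)) next
    # connectivity of the shared-precursor graph
    n <- n_cells
    adj <- matrix(FALSE, n, n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (sum(!is.na(mat[, a]) & !is.na(mat[, b])) >= min_shared) {
        adj[a, b] <- adj[b, a] <- TRUE
      }
    }
    reach <- logical(n); reach[1] <- TRUE
    repeat {
      new <- reach | apply(adj[, reach, drop = FALSE], 1, any)
      if (identical(new, reach)) break
      reach <- new
    }
    if (all(reach)) return(mat)
  }
}

# ---- brute-force tryptic digest oracle -------------------------------------
# Regex-based fragmentation, explicit enumeration of missed-cleavage joins.
oracle_digest <- function(sequence, min_len = 6, max_len = 50,
                          missed_cleavages = 0, proline_rule = FALSE) {
  frags <- regmatches(sequence,
                      gregexpr("[^KR]*[KR]|[^KR]+$", sequence))[[1]]
  frags <- frags[nzchar(frags)]
  if (proline_rule) {
    merged <- character(0)
    buf <- ""
    for (i in seq_along(frags)) {
      buf <- paste0(buf, frags[i])
      nxt <- if (i < length(frags)) substr(frags[i + 1], 1, 1) else ""
      if (nxt != "P") {
        merged <- c(merged, buf)
        buf <- ""
      }
    }
    if (nzchar(buf)) merged <- c(merged, buf)
    frags <- merged
  }
  count <- 0
  for (i in seq_along(frags)) {
    for (j in i:min(length(frags), i + missed_cleavages)) {
      len <- sum(nchar(frags[i:j]))
      if (len >= min_len && len <= max_len) count <- count + 1
    }
  }
  count
}

random_aa_sequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# ---- low-rank fixtures ------------------------------------------------------
rank_k_matrix <- function(n, m, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(rnorm(n * k), n, k)
  v <- matrix(rnorm(m * k), m, k)
  u %*% t(v)
}

# ---- cached study-scale runs ------------------------------------------------
# The default-scale simulation and pipeline runs are shared across test files.
.scp_cache <- new.env(parent = emptyenv())

get_default_sim <- function(size_coefficient = 1) {
  key <- paste0("sim_s", size_coefficient)
  if (is.null(.scp_cache[[key]])) {
    .scp_cache[[key]] <- simulate_dataset(
      default_paper_scale(size_coefficient = size_coefficient))
  }
  .scp_cache[[key]]
}

get_default_run <- function(size_coefficient = 1) {
  key <- paste0("run_s", size_coefficient)
  if (is.null(.scp_cache[[key]])) {
    sim <- get_default_sim(size_coefficient)
    .scp_cache[[key]] <- run_pipeline(sim$report, sim$annotations,
                                      sim$metadata, sim$genesets)
  }
  .scp_cache[[key]]
}

# small synthetic instance for structural tests
small_truth <- function(...) {
  args <- list(n_cells = 12, n_chips = 2, n_proteins = 40,
               precursor_lambda = 1.5, n_modules = 3, n_histones = 4,
               contaminant_fraction = 0.1, seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_truth, args)
}
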