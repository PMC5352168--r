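# Fixture builders shared across test files; everything is generated in
# code at test time.

# Long count tibble from a genes x libraries matrix.
counts_from_matrix <- function(m, gene_ids = rownames(m),
                               lib_ids = colnames(m)) {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(m)))
  if (is.null(lib_ids)) lib_ids <- paste0("L", seq_len(ncol(m)))
  tibble::tibble(
    gene_id = rep(gene_ids, times = ncol(m)),
    library_id = rep(lib_ids, each = nrow(m)),
    count = as.vector(m)
  )
}

# Minimal one-species design: one stage, two temperatures.
two_lib_samples <- function(lib_low = "L26", lib_high = "L31",
                            species = "TSD", stage = 22L) {
  tibble::tibble(
    library_id = c(lib_low, lib_high),
    species = species, stage = stage,
    temperature = c("low", "high"),
    temp_label = c("26C", "31C"),
    tissue = "gonad", n_pooled = 10L
  )
}

# Write an HTSeq-count file; returns its path.
write_htseq <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# Matrix on which housekeeping anchoring is exact under the combined
# scheme: background counts identical across libraries (equal upper
# quartiles), housekeeping counts proportional to a per-library scale.
anchoring_matrix <- function(n_genes = 200, scales = c(1, 2, 4),
                             hk = c(Tfr = 100, Hprt1 = 400), seed = 1) {
  set.seed(seed)
  bg <- rpois(n_genes - length(hk), lambda = 60) + 1L
  m <- vapply(scales, function(s) c(round(hk * s), bg), numeric(n_genes))
  rownames(m) <- c(names(hk), sprintf("g%04d", seq_along(bg)))
  colnames(m) <- paste0("L", seq_along(scales))
  m
}

# Composition-skew scenario: one thermosensitive species where 30% of
# genes are strongly suppressed at the high temperature; housekeeping
# genes constant and noise-free.
skew_sim <- function(seed = 11, n_genes = 2000, depth = 2e5) {
  simulate_experiment(sim_config(
    n_genes = n_genes, depth = depth, dispersion = 0,
    species = tibble::tibble(species = "TSD", n_pooled = 10L,
                             ts_fraction = 0.3, ts_lfc = 3),
    ts_sign_balance = 0, ts_stages = c(15L, 19L, 22L), seed = seed
  ))
}

# 3x3 power grid fixture: |lfc| in {0.5, 1, 2} x base mean in {20, 60, 200},
# 80 genes per cell over a 16,000-gene background, depth 2e6.
power_grid_fixture <- function() {
  lfcs <- c(0.5, 1, 2)
  mus <- c(20, 60, 200)
  n_cell <- 80
  set.seed(606)
  bg <- rlnorm(16000, meanlog = 3, sdlog = 1.2)
  means <- c(rep(mus, each = n_cell * 3), bg)
  gene_ids <- c(sprintf("p%04d", seq_len(n_cell * 9)),
                sprintf("b%05d", seq_along(bg)))
  names(means) <- gene_ids
  lfc <- c(rep(rep(lfcs, each = n_cell), times = 3), rep(0, length(bg)))
  mu_high <- means * 2^lfc
  low <- draw_pooled_library(means, 10, 0, 2e6)
  high <- draw_pooled_library(mu_high, 10, 0, 2e6)
  counts <- tibble::tibble(
    gene_id = rep(gene_ids, 2),
    library_id = rep(c("L26", "L31"), each = length(gene_ids)),
    count = c(unname(low), unname(high)))
  de <- call_de(counts, two_lib_samples(), scheme = "UQ100")
  res <- tidy(de)
  called <- res$tier[match(gene_ids, res$gene_id)] == "stringent"
  panel <- seq_len(n_cell * 9)
  cell <- matrix(0, 3, 3)
  for (li in 1:3) for (mi in 1:3) {
    sel <- panel[(lfc[panel] == lfcs[li]) & (means[panel] == mus[mi])]
    cell[li, mi] <- mean(called[sel])
  }
  cell
}
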