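test_that("partition_counts conserves counts exactly and is seeded", {
  set.seed(77)
  m <- counts_from_matrix(matrix(rpois(500, 80), ncol = 1,
                                 dimnames = list(NULL, "L1")))
  for (k in 2:3) {
    pt <- partition_counts(m, "L1", k = k, seed = 123)
    sums <- pt$counts |>
      dplyr::summarise(total = sum(.data$count), .by = "gene_id")
    src <- m |> dplyr::summarise(total = sum(.data$count), .by = "gene_id")
    expect_equal(dplyr::arrange(sums, .data$gene_id),
                 dplyr::arrange(src, .data$gene_id))
    expect_equal(sum(pt$totals), sum(m$count))
  }
  # zero counts split to zeros
  z <- counts_from_matrix(matrix(0L, 3, 1, dimnames = list(NULL, "L1")))
  expect_true(all(partition_counts(z, "L1", 2, 1)$counts$count == 0))
  # determinism and seed sensitivity
  p1 <- partition_counts(m, "L1", 2, seed = 5)
  p2 <- partition_counts(m, "L1", 2, seed = 5)
  p3 <- partition_counts(m, "L1", 2, seed = 6)
  expect_identical(p1$counts, p2$counts)
  expect_false(identical(p1$counts, p3$counts))
  expect_error(partition_counts(m, "L1", 1, 1), "k")
  expect_error(partition_counts(m, "LX", 2, 1), "not found")
})

test_that("equal-probability split halves counts on average", {
  m <- counts_from_matrix(matrix(rep(100L, 10000), ncol = 1,
                                 dimnames = list(NULL, "L1")))
  pt <- partition_counts(m, "L1", 2, seed = 42)
  means <- pt$counts |>
    dplyr::summarise(m = mean(.data$count), .by = "subsample")
  # per-gene count ~ Binomial(100, 1/2): se of the mean over 10,000 genes
  se <- sqrt(100 * 0.25 / 10000)
  expect_true(all(abs(means$m - 50) < 3 * se))
})

test_that("conditional binomial test matches hand values and its oracle", {
  expect_equal(conditional_binomial_test(5, 5, 1e6, 1e6), 1)
  expect_equal(conditional_binomial_test(10, 0, 1e6, 1e6), 2 / 1024,
               tolerance = 1e-12)
  expect_equal(binom_oracle(10, 10, 0.5), 2 / 1024, tolerance = 1e-12)
  set.seed(11)
  x1 <- sample(0:40, 200, TRUE); x2 <- sample(0:40, 200, TRUE)
  keep <- x1 + x2 >= 1
  n1 <- 5e4; n2 <- 8e4
  p_impl <- conditional_binomial_test(x1[keep], x2[keep], n1, n2)
  p_or <- mapply(function(a, b) binom_oracle(a, a + b, n1 / (n1 + n2)),
                 x1[keep], x2[keep])
  expect_equal(p_impl, p_or, tolerance = 1e-9)
  # cross-check against stats::binom.test (same two-sided convention)
  for (i in which(keep)[1:20]) {
    expect_equal(conditional_binomial_test(x1[i], x2[i], n1, n2),
                 stats::binom.test(x1[i], x1[i] + x2[i],
                                   n1 / (n1 + n2))$p.value,
                 tolerance = 1e-7)
  }
  expect_error(conditional_binomial_test(1, 1, 0, 5), "positive")
  expect_error(conditional_binomial_test(0, 0, 5, 5), "x1 \\+ x2")
})

test_that("binomial test approaches the Fisher table test for balanced margins", {
  # when the remaining-genes margins dwarf the focal counts, conditioning
  # on the pair total makes the two tests nearly identical
  set.seed(21)
  for (i in 1:25) {
    x1 <- sample(0:30, 1); x2 <- sample(0:30, 1)
    if (x1 + x2 == 0) next
    N <- 1e6
    p_f <- fisher_two_sided_p(x1, x2, N - x1, N - x2)
    p_b <- conditional_binomial_test(x1, x2, N, N)
    expect_equal(p_f, p_b, tolerance = 1e-3)
  }
})

test_that("consensus calls intersect pairs with direction consistency", {
  sim <- simulate_experiment(sim_config(
    n_genes = 1500, depth = 2e5, dispersion = 0,
    species = tibble::tibble(species = "TSD", n_pooled = 10L,
                             ts_fraction = 0.1, ts_lfc = 3),
    stages = 22L, ts_stages = 22L, seed = 31))
  for (k in 2:3) {
    pl <- partition_counts(sim$counts, "TSD_S22_26C", k, seed = 100 + k)
    ph <- partition_counts(sim$counts, "TSD_S22_31C", k, seed = 200 + k)
    cons <- consensus_calls(pl, ph, alpha = 0.01)
    union_pairs <- unique(unlist(cons$pair_sets))
    expect_true(all(cons$consensus$gene_id %in% union_pairs))
    for (ps in cons$pair_sets) {
      expect_true(all(cons$consensus$gene_id %in% ps))
    }
    # consensus genes carry one consistent direction across all pairs
    dirs <- cons$per_pair |>
      dplyr::filter(.data$gene_id %in% cons$consensus$gene_id,
                    .data$significant) |>
      dplyr::summarise(nd = dplyr::n_distinct(.data$direction),
                       .by = "gene_id")
    expect_true(all(dirs$nd == 1))
  }
  # mismatched k errors
  pl2 <- partition_counts(sim$counts, "TSD_S22_26C", 2, seed = 1)
  ph3 <- partition_counts(sim$counts, "TSD_S22_31C", 3, seed = 2)
  expect_error(consensus_calls(pl2, ph3), "mismatched k")
})

test_that("a direction flip between pairs excludes a gene from consensus", {
  # construct two per-pair partitions by hand: gene gx strongly low-biased
  # in pair 1 but high-biased in pair 2
  mk_part <- function(c1, c2, lib) {
    structure(list(
      counts = tibble::tibble(gene_id = rep(c("gx", paste0("bg", 1:99)), 2),
                              subsample = rep(1:2, each = 100),
                              count = c(c1, c2)),
      k = 2L, seed = 0L, source_library = lib,
      totals = c(sum(c1), sum(c2))), class = "subsample_partition")
  }
  bg <- rep(50L, 99)
  low <- mk_part(c(400L, bg), c(5L, bg), "L26")
  high <- mk_part(c(5L, bg), c(400L, bg), "L31")
  cons <- consensus_calls(low, high, alpha = 0.05)
  sig <- cons$per_pair |> dplyr::filter(.data$gene_id == "gx")
  expect_setequal(sig$direction, c("low", "high"))
  expect_false("gx" %in% cons$consensus$gene_id)
})
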