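test_that("trim_top_percentile uses ceiling count and lexicographic ties", {
  m <- counts_from_matrix(matrix(1:400, nrow = 200))
  expect_length(trim_top_percentile(m, 0.01), 2)  # ceil(0.01 * 200) = 2
  expect_identical(trim_top_percentile(m, 0), character(0))
  # means (5, 5, 9): fraction 0.34 -> ceil(1.02) = 2 genes; tie at 5 broken
  # lexicographically
  tie <- counts_from_matrix(matrix(c(5, 5, 9), nrow = 3,
                                   dimnames = list(c("gb", "ga", "gc"), "L1")))
  expect_setequal(trim_top_percentile(tie, 0.34), c("gc", "ga"))
})

test_that("upper-quartile factors: equivariance, identity, interpolation", {
  a <- c(10, 20, 30, 40)
  m <- counts_from_matrix(cbind(L1 = a, L2 = 2 * a))
  f <- upper_quartile_factors(m)
  expect_equal(f$uq_factor[f$library_id == "L2"] /
                 f$uq_factor[f$library_id == "L1"], 2)
  expect_equal(exp(mean(log(f$uq_factor))), 1, tolerance = 1e-12)
  # identical libraries -> all factors exactly 1
  f2 <- upper_quartile_factors(counts_from_matrix(cbind(L1 = a, L2 = a)))
  expect_equal(f2$uq_factor, c(1, 1))
  # linear interpolation convention: quartiles 32.5 and 30 + 0.25*60 = 45
  f3 <- upper_quartile_factors(
    counts_from_matrix(cbind(L1 = c(10, 20, 30, 40), L2 = c(10, 20, 30, 90))))
  expect_equal(f3$uq_factor[1] / f3$uq_factor[2], 32.5 / 45)
  # zeros are ignored, not counted in the quantile
  f4 <- upper_quartile_factors(
    counts_from_matrix(cbind(L1 = c(0, 0, 10, 20, 30, 40),
                             L2 = c(10, 20, 30, 40, 0, 0))))
  expect_equal(f4$uq_factor, c(1, 1))
  expect_error(
    upper_quartile_factors(counts_from_matrix(cbind(L1 = c(0, 5), L2 = 0:1)),
                           exclude = "g2"),
    "no nonzero eligible counts.*L1")
})

test_that("housekeeping factors follow per-gene geometric-mean ratios", {
  m <- counts_from_matrix(matrix(c(100, 400, 200, 800), nrow = 2,
                                 dimnames = list(c("Tfr", "Hprt1"),
                                                 c("L1", "L2"))))
  f <- housekeeping_factors(m, c("Tfr", "Hprt1"))
  expect_equal(f$hk_factor[f$library_id == "L2"] /
                 f$hk_factor[f$library_id == "L1"], 2)
  # Tfr constant, Hprt1 4x -> geometric mean ratio sqrt(4) = 2
  m2 <- counts_from_matrix(matrix(c(100, 100, 100, 400), nrow = 2,
                                  dimnames = list(c("Tfr", "Hprt1"),
                                                  c("L1", "L2"))))
  f2 <- housekeeping_factors(m2, c("Tfr", "Hprt1"))
  expect_equal(f2$hk_factor[f2$library_id == "L2"] /
                 f2$hk_factor[f2$library_id == "L1"], 2)
  # single library -> factor 1
  f3 <- housekeeping_factors(counts_from_matrix(
    matrix(c(100, 400), nrow = 2,
           dimnames = list(c("Tfr", "Hprt1"), "L1"))), c("Tfr", "Hprt1"))
  expect_equal(f3$hk_factor, 1)
  expect_error(
    housekeeping_factors(m, c("Tfr", "Hprt1", "Gapdh")),
    "Gapdh")
  m_zero <- counts_from_matrix(matrix(c(100, 0, 200, 800), nrow = 2,
                                      dimnames = list(c("Tfr", "Hprt1"),
                                                      c("L1", "L2"))))
  expect_error(housekeeping_factors(m_zero, c("Tfr", "Hprt1")),
               "Hprt1@L1")
})

test_that("apply_scheme centers factors, preserves zeros, records trim", {
  set.seed(42)
  m <- matrix(rpois(400 * 4, 40), nrow = 400,
              dimnames = list(c("Tfr", "Hprt1",
                                sprintf("g%03d", 1:398)), paste0("L", 1:4)))
  m[5, ] <- 0  # an all-zero gene must stay zero after normalization
  counts <- counts_from_matrix(m)
  for (sch in c("UQ100", "UQ99", "UQHK100", "UQHK99")) {
    nm <- apply_scheme(counts, sch)
    expect_equal(exp(mean(log(nm$factors$combined_factor))), 1,
                 tolerance = 1e-12)
    expect_equal(nm$factors$combined_factor,
                 nm$factors$hk_factor * nm$factors$uq_factor,
                 tolerance = 1e-12)
    expect_true(all((nm$values$value == 0) == (nm$values$count == 0)))
    expect_true(all(nm$values$value >= 0))
    n_trim <- if (endsWith(sch, "99")) ceiling(0.01 * 400) else 0
    expect_length(nm$trimmed_genes, n_trim)
  }
  # tidiers
  td <- tidy(apply_scheme(counts, "UQHK100"))
  expect_true(all(c("scheme", "library_id", "hk_factor", "uq_factor",
                    "combined_factor") %in% names(td)))
  expect_equal(glance(apply_scheme(counts, "UQ99"))$n_trimmed, 4)
})

test_that("UQ100 equalizes the nonzero upper quartile across libraries", {
  set.seed(7)
  m <- matrix(rnbinom(300 * 3, mu = 50, size = 2), nrow = 300)
  m[, 2] <- m[, 2] * 3L
  nm <- apply_scheme(counts_from_matrix(m), "UQ100")
  uqs <- nm$values |>
    dplyr::filter(.data$value > 0) |>
    dplyr::summarise(uq = quantile(.data$value, 0.75), .by = "library_id")
  expect_lt(diff(range(uqs$uq)) / mean(uqs$uq), 1e-12)
})

test_that("housekeeping anchoring equalizes hk genes on anchorable data", {
  m <- anchoring_matrix()
  nm <- apply_scheme(counts_from_matrix(m), "UQHK100")
  hk_vals <- nm$values |> dplyr::filter(.data$gene_id %in% c("Tfr", "Hprt1"))
  spread <- hk_vals |>
    dplyr::summarise(rel = diff(range(.data$value)) / mean(.data$value),
                     .by = "gene_id")
  expect_true(all(spread$rel < 1e-9))
  # UQ100 on the same data does NOT anchor them (scales differ 4x)
  nm_uq <- apply_scheme(counts_from_matrix(m), "UQ100")
  hk_uq <- nm_uq$values |>
    dplyr::filter(.data$gene_id == "Tfr") |>
    dplyr::pull("value")
  expect_gt(diff(range(hk_uq)) / mean(hk_uq), 0.5)
})

test_that("combined-scheme application order is irrelevant", {
  # factors are estimated independently on raw counts, so dividing by the
  # housekeeping factor then the upper-quartile factor, or the reverse,
  # must give identical normalized values and identical DE calls
  sim <- skew_sim(seed = 3, n_genes = 500, depth = 5e4)
  nm <- apply_scheme(sim$counts, "UQHK100")
  v1 <- nm$values$count / nm$factors$hk_factor[
    match(nm$values$library_id, nm$factors$library_id)] /
    nm$factors$uq_factor[match(nm$values$library_id,
                               nm$factors$library_id)]
  v2 <- nm$values$count / nm$factors$uq_factor[
    match(nm$values$library_id, nm$factors$library_id)] /
    nm$factors$hk_factor[match(nm$values$library_id,
                               nm$factors$library_id)]
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(nm$values$value, v1, tolerance = 1e-12)
})
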