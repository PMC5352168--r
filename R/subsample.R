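# Pseudo-replication by library subsampling: each library's reads are
# randomly subdivided into k equal-probability subsets. At count level a
# uniform random assignment of reads is exactly a per-gene multinomial
# split with probabilities 1/k, so the partition is drawn gene-wise from a
# multinomial and conserves every count exactly. Matched subsample pairs
# across the two temperatures act as technical replicates; per-pair exact
# conditional binomial tests with BH control at 1% feed an
# all-pairs-consistent consensus call.

#' Randomly partition one library's counts into k subsamples
#'
#' Each gene's count `n` is split as a multinomial draw with equal
#' probabilities `1/k` (implemented as sequential binomial thinning, which
#' is distributionally identical and vectorizes over genes). Conservation
#' is exact: the `k` subsample counts of every gene sum to the source
#' count. Deterministic given `seed`.
#'
#' @param counts Long count tibble (`gene_id`, `library_id`, `count`).
#' @param library_id Library to partition.
#' @param k Number of subsamples (>= 2; the study used 2 and 3).
#' @param seed Integer seed, recorded in the result.
#' @return A `subsample_partition` object: list with `counts` (tibble
#'   `gene_id`, `subsample`, `count`), `k`, `seed`, `source_library`, and
#'   `totals` (per-subsample column totals).
#' @export
partition_counts <- function(counts, library_id, k, seed) {
  check_cols(counts, c("gene_id", "library_id", "count"))
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != floor(k)) {
    stop("`k` must be an integer >= 2", call. = FALSE)
  }
  src <- counts |> dplyr::filter(.data$library_id == !!library_id)
  if (nrow(src) == 0) {
    stop("library not found: ", library_id, call. = FALSE)
  }
  n <- as.numeric(src$count)
  parts <- matrix(0, nrow = length(n), ncol = k)
  with_seed(seed, {
    remaining <- n
    for (j in seq_len(k - 1)) {
      drawn <- rbinom(length(remaining), size = remaining,
                      prob = 1 / (k - j + 1))
      parts[, j] <- drawn
      remaining <- remaining - drawn
    }
    parts[, k] <- remaining
  })
  out <- tibble::tibble(
    gene_id = rep(src$gene_id, k),
    subsample = rep(seq_len(k), each = length(n)),
    count = as.integer(parts)
  )
  structure(
    list(counts = out, k = as.integer(k), seed = as.integer(seed),
         source_library = library_id,
         totals = colSums(parts)),
    class = "subsample_partition"
  )
}

#' @export
print.subsample_partition <- function(x, ...) {
  cat("<subsample_partition> library ", x$source_library, " split into k = ",
      x$k, " (seed ", x$seed, "); subsample totals: ",
      paste(x$totals, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Scalar exact conditional binomial p (no validation)
#' @noRd
.binom_p <- function(x1, n, prob) {
  d <- dbinom(0:n, n, prob)
  # guard against density underflow at extreme observations
  min(max(sum(d[d <= d[x1 + 1] * (1 + 1e-7)]), .Machine$double.xmin), 1)
}

#' Exact conditional binomial test for a pair of subsample counts
#'
#' Conditional on the total `x1 + x2`, the count `x1` in subsample 1 is
#' binomial with success probability `N1 / (N1 + N2)` under the null of
#' equal relative expression. The two-sided p-value uses the same
#' probability-mass convention as [fisher_two_sided_p()]. This is the
#' per-pair test behind [consensus_calls()]: subsamples of one library are
#' technical replicates with multinomial noise, for which this exact
#' conditional test is the natural analogue of the full-library Fisher
#' test.
#'
#' @param x1,x2 Gene counts in the two matched subsamples (vectorized;
#'   `x1 + x2 >= 1`).
#' @param N1,N2 Subsample library totals (> 0).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' conditional_binomial_test(10, 0, 1e6, 1e6)  # 2/2^10
#' @export
conditional_binomial_test <- function(x1, x2, N1, N2) {
  len <- max(length(x1), length(x2), length(N1), length(N2))
  x1 <- rep_len(as.numeric(x1), len); x2 <- rep_len(as.numeric(x2), len)
  N1 <- rep_len(as.numeric(N1), len); N2 <- rep_len(as.numeric(N2), len)
  if (any(N1 <= 0 | N2 <= 0)) {
    stop("subsample totals N1, N2 must be positive", call. = FALSE)
  }
  if (any(x1 < 0 | x2 < 0 | x1 + x2 < 1)) {
    stop("need non-negative counts with x1 + x2 >= 1", call. = FALSE)
  }
  prob <- N1 / (N1 + N2)
  vapply(seq_len(len), function(i) .binom_p(x1[i], x1[i] + x2[i], prob[i]),
         numeric(1))
}

#' Consensus differential-expression calls across matched subsample pairs
#'
#' Pairs subsample `i` of the low-temperature library with subsample `i`
#' of the high-temperature library. Within each pair every gene with at
#' least one read is tested with [conditional_binomial_test()] and
#' BH-adjusted; the consensus set contains the genes significant at
#' `alpha` with a consistent direction of temperature bias in *all* pairs.
#' As an intersection of per-pair call sets it is conservative: its
#' realized false-discovery proportion cannot exceed what any single pair
#' achieves on the same data.
#'
#' @param partition_low,partition_high `subsample_partition` objects for
#'   the two temperature libraries of one stage, with matching `k`.
#' @param alpha FDR level within each pair (default 0.01, the level used
#'   for the subsample cross-check in this design).
#' @return A list with `per_pair` (tibble `pair`, `gene_id`, `p`, `q`,
#'   `direction`, `significant`), `pair_sets` (list of per-pair significant
#'   gene-id sets) and `consensus` (tibble `gene_id`, `direction`).
#' @export
consensus_calls <- function(partition_low, partition_high, alpha = 0.01) {
  stopifnot(inherits(partition_low, "subsample_partition"),
            inherits(partition_high, "subsample_partition"))
  if (partition_low$k != partition_high$k) {
    stop("mismatched k between temperature partitions: ",
         partition_low$k, " vs ", partition_high$k, call. = FALSE)
  }
  k <- partition_low$k
  per_pair <- purrr::map(seq_len(k), function(i) {
    low <- partition_low$counts |> dplyr::filter(.data$subsample == i)
    high <- partition_high$counts |> dplyr::filter(.data$subsample == i)
    merged <- dplyr::full_join(
      low |> dplyr::select("gene_id", x1 = "count"),
      high |> dplyr::select("gene_id", x2 = "count"),
      by = "gene_id"
    ) |>
      tidyr::replace_na(list(x1 = 0L, x2 = 0L))
    n1 <- sum(merged$x1)
    n2 <- sum(merged$x2)
    testable <- merged$x1 + merged$x2 >= 1
    p <- rep(1, nrow(merged))
    p[testable] <- conditional_binomial_test(merged$x1[testable],
                                             merged$x2[testable], n1, n2)
    q <- rep(1, nrow(merged))
    q[testable] <- bh_adjust(p[testable])
    # direction relative to subsample totals: low-biased when the gene's
    # share of the low-temperature subsample exceeds its share of the high;
    # double arithmetic avoids integer overflow at library-scale totals
    lhs <- as.numeric(merged$x1) * n2
    rhs <- as.numeric(merged$x2) * n1
    direction <- dplyr::case_when(
      lhs > rhs ~ "low",
      lhs < rhs ~ "high",
      .default = "none"
    )
    tibble::tibble(pair = i, gene_id = merged$gene_id, p = p, q = q,
                   direction = direction,
                   significant = testable & q <= alpha & direction != "none")
  }) |> dplyr::bind_rows()

  pair_sets <- per_pair |>
    dplyr::filter(.data$significant) |>
    (\(d) split(d$gene_id, d$pair))()
  pair_sets <- purrr::map(as.character(seq_len(k)),
                          ~ pair_sets[[.x]] %||% character(0))
  names(pair_sets) <- paste0("pair", seq_len(k))

  consensus <- per_pair |>
    dplyr::filter(.data$significant) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     n_dir = dplyr::n_distinct(.data$direction),
                     direction = .data$direction[1],
                     .by = "gene_id") |>
    dplyr::filter(.data$n_pairs == k, .data$n_dir == 1) |>
    dplyr::select("gene_id", "direction")

  list(per_pair = per_pair, pair_sets = pair_sets, consensus = consensus)
}
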