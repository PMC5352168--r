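# Synthetic pooled-embryo RNA-seq generator mirroring the study design:
# two species (one temperature-sensitive, one not) x five developmental
# stages x two incubation temperatures, one pooled library per cell. The
# noise hierarchy is gamma (among-embryo biological variation) summed over
# the pool, followed by a multinomial sequencing draw of the configured
# depth, so library column totals are exact and the only randomness at
# dispersion 0 is multinomial sampling.

#' Configuration of a synthetic two-species temperature-contrast experiment
#'
#' Defaults emulate the study design: stages 9/12/15/19/22; a
#' thermosensitive (TSD) species with pools of 10 embryos whose
#' temperature-responsive genes change expression during the
#' thermosensitive period (stages 15, 19, 22), and a genotypic (GSD)
#' species with pools of 5 embryos and no temperature response, serving as
#' negative control. Library depth defaults to 2e6 reads, a desk-scale
#' stand-in for the tens of millions of read pairs per library in a real
#' experiment.
#'
#' @param n_genes Number of genes.
#' @param stages Ordered developmental stage set.
#' @param species A tibble with one row per species: `species`, `n_pooled`,
#'   `ts_fraction` (fraction of genes that respond to temperature) and
#'   `ts_lfc` (absolute log2 fold-change of responsive genes during their
#'   active stages). Defaults: TSD species, pool 10, fraction 0.05, lfc 2;
#'   GSD species, pool 5, fraction 0, lfc 0.
#' @param ts_stages Stages at which thermosensitive effects are active
#'   (default `c(15, 19, 22)`, the thermosensitive period).
#' @param depth Expected (and exact) reads per library.
#' @param hk_genes Ids of housekeeping genes, simulated with zero
#'   fold-change and zero dispersion at a high constant base mean.
#' @param ncrna_fraction Fraction of genes given low base abundance,
#'   mimicking ncRNA-like transcripts.
#' @param dispersion Negative-binomial dispersion of among-embryo
#'   biological variation within a pool (gamma shape `1/dispersion`);
#'   0 gives pure multinomial sequencing noise.
#' @param ts_mean_multiplier Multiplier applied to the base means of
#'   thermosensitive genes; values well above 1 create the
#'   library-composition skew that separates the normalization schemes.
#' @param ts_sign_balance Fraction of thermosensitive genes whose
#'   expression is higher at the high temperature (default 0.5, balanced).
#'   Values near 0 or 1 make the response one-directional, creating the
#'   composition skew that biases upper-quartile scale estimation while
#'   leaving housekeeping anchoring intact.
#' @param base_meanlog,base_sdlog Log-normal parameters of the base-mean
#'   distribution (relative abundance scale).
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(n_genes = 8000,
                       stages = c(9L, 12L, 15L, 19L, 22L),
                       species = NULL,
                       ts_stages = c(15L, 19L, 22L),
                       depth = 2e6,
                       hk_genes = c("Tfr", "Hprt1"),
                       ncrna_fraction = 0.05,
                       dispersion = 0.05,
                       ts_mean_multiplier = 1,
                       ts_sign_balance = 0.5,
                       base_meanlog = 3,
                       base_sdlog = 1.5,
                       seed = 1L) {
  if (is.null(species)) {
    species <- tibble::tibble(
      species = c("TSD", "GSD"),
      n_pooled = c(10L, 5L),
      ts_fraction = c(0.05, 0),
      ts_lfc = c(2, 0)
    )
  }
  check_cols(species, c("species", "n_pooled", "ts_fraction", "ts_lfc"))
  if (missing(ts_stages)) {
    ts_stages <- intersect(ts_stages, stages)
  }
  stopifnot(n_genes >= length(hk_genes) + 1, depth > 0, dispersion >= 0,
            all(species$ts_fraction >= 0 & species$ts_fraction <= 1),
            ncrna_fraction >= 0 && ncrna_fraction <= 1,
            all(species$n_pooled >= 1),
            length(stages) >= 1, ts_mean_multiplier > 0,
            ts_sign_balance >= 0 && ts_sign_balance <= 1)
  if (!all(ts_stages %in% stages)) {
    stop("`ts_stages` must be a subset of `stages`", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), stages = as.integer(stages),
         species = species, ts_stages = as.integer(ts_stages),
         depth = depth, hk_genes = hk_genes,
         ncrna_fraction = ncrna_fraction, dispersion = dispersion,
         ts_mean_multiplier = ts_mean_multiplier,
         ts_sign_balance = ts_sign_balance,
         base_meanlog = base_meanlog, base_sdlog = base_sdlog,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Draw one pooled sequencing library
#'
#' Mechanistic core of the generator: each of `n_pooled` embryos
#' contributes gamma-distributed expression around the per-gene mean
#' (`shape = 1/dispersion`, so the embryo-level coefficient of variation is
#' `sqrt(dispersion)`); the pool is the sum of contributions, and
#' sequencing draws exactly `depth` reads from the pooled proportions via
#' a single multinomial. With `dispersion = 0` the pooled proportions are
#' deterministic. Housekeeping-style genes can be exempted from biological
#' noise via `zero_dispersion_genes`.
#'
#' @param means Named (or plain) numeric vector of per-gene expected
#'   expression on an arbitrary relative scale; at least one positive
#'   entry.
#' @param n_pooled Number of embryos pooled.
#' @param dispersion Among-embryo NB dispersion (>= 0).
#' @param depth Total reads to draw; the returned counts sum to `depth`
#'   exactly.
#' @param zero_dispersion_genes Indices (or names) of genes drawn without
#'   biological noise.
#' @return Integer count vector, same length/names as `means`.
#' @export
draw_pooled_library <- function(means, n_pooled, dispersion, depth,
                                zero_dispersion_genes = integer()) {
  stopifnot(all(is.finite(means)), all(means >= 0), n_pooled >= 1,
            dispersion >= 0, depth > 0)
  if (all(means == 0)) {
    stop("all base means are zero; nothing to sequence", call. = FALSE)
  }
  if (dispersion == 0) {
    pooled <- means * n_pooled
  } else {
    shape <- n_pooled / dispersion
    pooled <- ifelse(means > 0,
                     rgamma(length(means), shape = shape,
                            scale = means * dispersion),
                     0)
    if (length(zero_dispersion_genes) > 0) {
      pooled[zero_dispersion_genes] <- means[zero_dispersion_genes] * n_pooled
    }
  }
  counts <- as.integer(rmultinom(1, size = depth, prob = pooled / sum(pooled)))
  names(counts) <- names(means)
  counts
}

#' Simulate the full two-species temperature-contrast experiment
#'
#' Generates one pooled library per species x stage x temperature cell
#' (20 libraries under the default five-stage two-species design) together
#' with a per-gene ground-truth table for power and FDR evaluation.
#' Gene base means are log-normal; a configured fraction of genes per
#' species is thermosensitive, with log2 fold-change `+/- ts_lfc`
#' (sign alternating, so half are higher at 31 degrees C) active during
#' `ts_stages`; housekeeping genes are constant, high-abundance and
#' noise-free; an `ncrna_fraction` of genes is shifted to low abundance.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (long tibble `gene_id`, `library_id`,
#'   `count`), `samples` (sample sheet tibble, see [read_sample_sheet()])
#'   and `truth` (tibble `gene_id`, `species`, `stage`, `lfc`, `de`,
#'   `category`, `base_mean`); `lfc` is log2(high/low), positive meaning
#'   31-degree-biased.
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 500, depth = 1e5,
#'                                       seed = 42))
#' dplyr::count(sim$truth, species, de = lfc != 0)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_hk <- length(config$hk_genes)
    n_bg <- config$n_genes - n_hk
    gene_ids <- c(config$hk_genes,
                  sprintf("g%05d", seq_len(n_bg)))
    base_mean <- rlnorm(n_bg, meanlog = config$base_meanlog,
                        sdlog = config$base_sdlog)
    # ncRNA-like genes: a low-abundance tail
    n_nc <- round(config$ncrna_fraction * n_bg)
    nc_idx <- if (n_nc > 0) sample.int(n_bg, n_nc) else integer()
    base_mean[nc_idx] <- base_mean[nc_idx] * 0.05
    # housekeeping genes: constant and high (80th percentile of background)
    hk_mean <- rep(quantile(base_mean, 0.8, names = FALSE), n_hk)
    means <- c(hk_mean, base_mean)
    names(means) <- gene_ids
    category <- rep("background", config$n_genes)
    category[seq_len(n_hk)] <- "housekeeping"
    category[n_hk + nc_idx] <- "ncRNA-like"

    per_species <- purrr::map(seq_len(nrow(config$species)), function(si) {
      sp <- config$species[si, ]
      eligible <- which(category != "housekeeping")
      n_ts <- round(sp$ts_fraction * config$n_genes)
      ts_idx <- if (n_ts > 0) sample(eligible, min(n_ts, length(eligible)))
                else integer()
      # sign split: first n_up responsive genes higher at high temperature
      n_up <- round(config$ts_sign_balance * length(ts_idx))
      sign <- rep(c(1, -1), c(n_up, length(ts_idx) - n_up))
      lfc <- numeric(config$n_genes)
      lfc[ts_idx] <- sign * sp$ts_lfc
      sp_means <- means
      sp_means[ts_idx] <- sp_means[ts_idx] * config$ts_mean_multiplier
      sp_category <- category
      sp_category[ts_idx] <- "thermosensitive"

      libs <- tidyr::expand_grid(stage = config$stages,
                                 temperature = c("low", "high"))
      lib_rows <- purrr::pmap(libs, function(stage, temperature) {
        active <- stage %in% config$ts_stages
        mu <- sp_means
        if (active && temperature == "high") {
          mu <- mu * 2^lfc
        }
        cnt <- draw_pooled_library(
          mu, n_pooled = sp$n_pooled, dispersion = config$dispersion,
          depth = config$depth,
          zero_dispersion_genes = seq_len(n_hk)
        )
        lib_id <- paste0(sp$species, "_S", stage, "_",
                         ifelse(temperature == "low", "26C", "31C"))
        list(
          counts = tibble::tibble(gene_id = gene_ids, library_id = lib_id,
                                  count = unname(cnt)),
          sample = tibble::tibble(
            library_id = lib_id, species = sp$species,
            stage = as.integer(stage), temperature = temperature,
            temp_label = ifelse(temperature == "low", "26C", "31C"),
            tissue = dplyr::case_when(stage == 9 ~ "trunk",
                                      stage %in% c(12, 15) ~ "AKG",
                                      .default = "gonad"),
            n_pooled = sp$n_pooled
          )
        )
      })
      truth <- tidyr::expand_grid(gene_id = gene_ids,
                                  stage = config$stages) |>
        dplyr::mutate(
          species = sp$species,
          lfc = ifelse(.data$stage %in% config$ts_stages,
                       rep(lfc, each = length(config$stages)), 0),
          de = .data$lfc != 0,
          category = rep(sp_category, each = length(config$stages)),
          base_mean = rep(unname(sp_means), each = length(config$stages))
        ) |>
        dplyr::select("gene_id", "species", "stage", "lfc", "de",
                      "category", "base_mean")
      list(counts = purrr::map(lib_rows, "counts") |> dplyr::bind_rows(),
           samples = purrr::map(lib_rows, "sample") |> dplyr::bind_rows(),
           truth = truth)
    })

    list(counts = purrr::map(per_species, "counts") |> dplyr::bind_rows(),
         samples = purrr::map(per_species, "samples") |> dplyr::bind_rows(),
         truth = purrr::map(per_species, "truth") |> dplyr::bind_rows(),
         config = config)
  })
}

#' Evaluate DE calls against synthetic ground truth
#'
#' Per species x stage: true/false positives, false negatives, realized
#' false-discovery proportion and power at the requested tier, plus a
#' stratified power table over bins of |log2 fold-change| and base mean.
#'
#' @param results A `thermode_de` object or its [tidy()] tibble.
#' @param truth Truth tibble from [simulate_experiment()].
#' @param tier `"stringent"` or `"suggestive"` (suggestive includes
#'   stringent calls).
#' @param lfc_bins,mean_bins Cut points for the stratified power table.
#' @return A list with `summary` (tibble per species x stage: `n_true_de`,
#'   `tp`, `fp`, `fn`, `fdr`, `power`; `fdr` is `NaN` when nothing is
#'   called) and `strata` (power by |lfc| bin x base-mean bin).
#' @export
evaluate_calls <- function(results, truth,
                           tier = c("stringent", "suggestive"),
                           lfc_bins = c(0, 1, 2, Inf),
                           mean_bins = c(0, 20, 100, Inf)) {
  tier <- match.arg(tier)
  res <- if (inherits(results, "thermode_de")) results$results else results
  check_cols(res, c("gene_id", "species", "stage", "tier"))
  check_cols(truth, c("gene_id", "species", "stage", "lfc", "de"))
  if (!setequal(unique(res$gene_id),
                unique(truth$gene_id[truth$species %in% res$species &
                                       truth$stage %in% res$stage]))) {
    stop("results and truth do not share the same gene universe",
         call. = FALSE)
  }
  strict <- tier == "stringent"
  joined <- res |>
    dplyr::inner_join(truth, by = c("gene_id", "species", "stage")) |>
    dplyr::mutate(called = if (strict) .data$tier == "stringent"
                  else .data$tier != "ns")
  summary <- joined |>
    dplyr::summarise(
      n_true_de = sum(.data$de),
      tp = sum(.data$called & .data$de),
      fp = sum(.data$called & !.data$de),
      fn = sum(!.data$called & .data$de),
      fdr = sum(.data$called & !.data$de) / sum(.data$called),
      power = dplyr::if_else(sum(.data$de) == 0, NA_real_,
                             sum(.data$called & .data$de) / sum(.data$de)),
      .by = c("species", "stage")
    )
  strata <- joined |>
    dplyr::filter(.data$de) |>
    dplyr::mutate(
      lfc_bin = cut(abs(.data$lfc), lfc_bins, include.lowest = TRUE),
      mean_bin = cut(.data$base_mean, mean_bins, include.lowest = TRUE)
    ) |>
    dplyr::summarise(n = dplyr::n(), power = mean(.data$called),
                     .by = c("species", "lfc_bin", "mean_bin"))
  list(summary = summary, strata = strata)
}
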