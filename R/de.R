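# Per-gene differential-expression calling: one Fisher exact test per gene
# per species x stage temperature contrast, BH correction within each
# species x stage family, and tier assignment against the stringent
# (default 1e-10) and suggestive (default 0.05) FDR cutoffs.

#' Differential-expression configuration
#'
#' @param stringent_alpha FDR cutoff for the stringent tier. The default
#'   1e-10 is deliberately extreme: with pooled unreplicated libraries the
#'   Fisher test sees only sequencing (multinomial) noise, so biological
#'   variation among embryo pools inflates nominal significance and a very
#'   conservative tier is needed for headline calls.
#' @param suggestive_alpha FDR cutoff for the suggestive tier (default
#'   0.05).
#' @param input_values `"normalized"` (default): tests run on
#'   scheme-normalized values rounded half-up to integers; `"raw"`: tests
#'   run on raw counts.
#' @return A `de_config` object (list).
#' @export
de_config <- function(stringent_alpha = 1e-10, suggestive_alpha = 0.05,
                      input_values = c("normalized", "raw")) {
  input_values <- match.arg(input_values)
  if (!(stringent_alpha > 0 && stringent_alpha <= suggestive_alpha &&
        suggestive_alpha <= 1)) {
    stop("need 0 < stringent_alpha <= suggestive_alpha <= 1", call. = FALSE)
  }
  structure(list(stringent_alpha = stringent_alpha,
                 suggestive_alpha = suggestive_alpha,
                 fdr_method = "BH",
                 input_values = input_values),
            class = "de_config")
}

#' Round half-up to integer
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Build the gene-vs-remaining 2x2 contingency table for one gene
#'
#' Cell `n11` is the focal gene's (rounded) value in the low-temperature
#' library, `n12` in the high-temperature library; `n21`/`n22` are the
#' summed values of all other genes in the tested universe. For a
#' `thermode_norm` input the values are the normalized ones rounded
#' half-up, and genes trimmed by the scheme are outside the tested
#' universe.
#'
#' @param x A `thermode_norm` object from [apply_scheme()], or a long count
#'   tibble (`gene_id`, `library_id`, `count`).
#' @param gene Focal gene id.
#' @param lib_low,lib_high Library ids of the low- and high-temperature
#'   libraries being contrasted.
#' @return A one-row tibble `gene_id`, `n11`, `n12`, `n21`, `n22`, `N`.
#' @export
build_contingency <- function(x, gene, lib_low, lib_high) {
  if (inherits(x, "thermode_norm")) {
    values <- x$values |>
      dplyr::filter(!.data$gene_id %in% x$trimmed_genes)
    if (gene %in% x$trimmed_genes) {
      stop("gene not in tested universe (trimmed by scheme ",
           x$scheme$name, "): ", gene, call. = FALSE)
    }
    values <- values |> dplyr::mutate(v = round_half_up(.data$value))
  } else {
    check_cols(x, c("gene_id", "library_id", "count"))
    values <- x |> dplyr::mutate(v = as.numeric(.data$count))
  }
  if (!gene %in% values$gene_id) {
    stop("gene not in tested universe: ", gene, call. = FALSE)
  }
  pick <- function(lib) {
    col <- values |> dplyr::filter(.data$library_id == lib)
    if (nrow(col) == 0) {
      stop("library not found: ", lib, call. = FALSE)
    }
    c(gene = sum(col$v[col$gene_id == gene]), total = sum(col$v))
  }
  lowv <- pick(lib_low)
  highv <- pick(lib_high)
  tibble::tibble(gene_id = gene,
                 n11 = lowv[["gene"]], n12 = highv[["gene"]],
                 n21 = lowv[["total"]] - lowv[["gene"]],
                 n22 = highv[["total"]] - highv[["gene"]],
                 N = lowv[["total"]] + highv[["total"]])
}

#' Call differentially expressed genes across a study design
#'
#' For each species the counts are normalized under `scheme` across that
#' species' libraries (independently per species), then for each
#' developmental stage every eligible gene is tested with the two-sided
#' Fisher exact test on its gene-vs-remaining contingency table
#' contrasting the two temperatures. p-values are BH-adjusted within each
#' species x stage family, and each gene is assigned a tier
#' (`"stringent"`, `"suggestive"`, `"ns"`) and a direction of temperature
#' bias (`"low"` = higher at 26 degrees C, `"high"` = higher at 31).
#'
#' Genes with zero (rounded) values at both temperatures are untestable:
#' they are reported with `p = q = 1`, tier `"ns"`, direction `"none"` and
#' are excluded from the BH family so they do not dilute the correction.
#'
#' @param counts Long count tibble (`gene_id`, `library_id`, `count`).
#' @param samples Sample sheet tibble with one library per
#'   (species, stage, temperature); see [read_sample_sheet()].
#' @param scheme A [norm_scheme()] (or name). Ignored when
#'   `config$input_values == "raw"`.
#' @param config A [de_config()].
#' @return A `thermode_de` object. `tidy()` returns the per-gene result
#'   table (`gene_id`, `species`, `stage`, `mean_low`, `mean_high`,
#'   `log2fc`, `p`, `q`, `tier`, `direction`); `glance()` a per-family
#'   summary. `log2fc` is `log2((mean_high + 0.5) / (mean_low + 0.5))`, so
#'   positive values are high-temperature (31 degrees C) biased.
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 300, depth = 5e4,
#'                                       stages = c(15, 22), seed = 1))
#' de <- call_de(sim$counts, sim$samples, scheme = "UQHK100")
#' glance(de)
#' @export
call_de <- function(counts, samples, scheme = norm_scheme("UQHK100"),
                    config = de_config()) {
  check_cols(counts, c("gene_id", "library_id", "count"))
  check_cols(samples, c("library_id", "species", "stage", "temperature"))
  if (is.character(scheme)) scheme <- norm_scheme(scheme)
  stopifnot(inherits(config, "de_config"))
  samples <- samples |>
    dplyr::filter(.data$library_id %in% unique(counts$library_id))
  cells <- samples |>
    dplyr::count(.data$species, .data$stage, .data$temperature)
  if (any(cells$n != 1)) {
    bad <- cells[cells$n != 1, ][1, ]
    stop("design requires exactly one library per cell; offending cell: (",
         bad$species, ", stage ", bad$stage, ", ", bad$temperature, ")",
         call. = FALSE)
  }
  incomplete <- cells |>
    dplyr::count(.data$species, .data$stage, name = "n_temp") |>
    dplyr::filter(.data$n_temp != 2)
  if (nrow(incomplete) > 0) {
    stop("missing temperature library for (", incomplete$species[1],
         ", stage ", incomplete$stage[1], ")", call. = FALSE)
  }

  norm_list <- list()
  results <- purrr::map(unique(samples$species), function(sp) {
    sp_samples <- samples |> dplyr::filter(.data$species == sp)
    sp_counts <- counts |>
      dplyr::filter(.data$library_id %in% sp_samples$library_id)
    if (config$input_values == "normalized") {
      nm <- apply_scheme(sp_counts, scheme)
      norm_list[[sp]] <<- nm
      vals <- nm$values |>
        dplyr::filter(!.data$gene_id %in% nm$trimmed_genes) |>
        dplyr::mutate(v = round_half_up(.data$value))
    } else {
      trimmed <- trim_top_percentile(sp_counts, scheme$trim_fraction)
      vals <- sp_counts |>
        dplyr::filter(!.data$gene_id %in% trimmed) |>
        dplyr::mutate(v = as.numeric(.data$count))
    }
    purrr::map(sort(unique(sp_samples$stage)), function(st) {
      lib_low <- sp_samples$library_id[sp_samples$stage == st &
                                         sp_samples$temperature == "low"]
      lib_high <- sp_samples$library_id[sp_samples$stage == st &
                                          sp_samples$temperature == "high"]
      wide <- vals |>
        dplyr::filter(.data$library_id %in% c(lib_low, lib_high)) |>
        dplyr::select("gene_id", "library_id", "v") |>
        tidyr::pivot_wider(names_from = "library_id", values_from = "v",
                           values_fill = 0)
      vlow <- wide[[lib_low]]
      vhigh <- wide[[lib_high]]
      t_low <- sum(vlow)
      t_high <- sum(vhigh)
      n11 <- vlow; n12 <- vhigh
      n21 <- t_low - vlow; n22 <- t_high - vhigh
      testable <- (n11 + n12) > 0
      p <- rep(1, length(vlow))
      p[testable] <- fisher_two_sided_p(n11[testable], n12[testable],
                                        n21[testable], n22[testable])
      q <- rep(1, length(vlow))
      q[testable] <- bh_adjust(p[testable])
      direction <- rep("none", length(vlow))
      direction[testable] <- classify_direction(n11[testable], n12[testable],
                                                n21[testable], n22[testable])
      tier <- dplyr::case_when(
        testable & q <= config$stringent_alpha ~ "stringent",
        testable & q <= config$suggestive_alpha ~ "suggestive",
        .default = "ns"
      )
      tibble::tibble(
        gene_id = wide$gene_id, species = sp, stage = st,
        mean_low = vlow, mean_high = vhigh,
        log2fc = log2((vhigh + 0.5) / (vlow + 0.5)),
        p = p, q = q, tier = tier, direction = direction
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(
    list(results = results, config = config, scheme = scheme,
         normalization = norm_list),
    class = "thermode_de"
  )
}

#' @export
print.thermode_de <- function(x, ...) {
  cat("<thermode_de> scheme ", x$scheme$name, ", ",
      if (x$config$input_values == "raw") "raw counts" else "normalized values",
      "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @describeIn call_de Per-gene result tibble.
#' @param x A `thermode_de` object.
#' @param ... Unused.
#' @method tidy thermode_de
#' @export
tidy.thermode_de <- function(x, ...) {
  x$results
}

#' @describeIn call_de Per species x stage summary: genes tested and DE
#'   counts at each tier.
#' @method glance thermode_de
#' @export
glance.thermode_de <- function(x, ...) {
  x$results |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_tested = sum(.data$mean_low + .data$mean_high > 0),
      n_stringent = sum(.data$tier == "stringent"),
      n_suggestive = sum(.data$tier == "suggestive"),
      .by = c("species", "stage")
    )
}

#' Gene ids called differentially expressed at a tier
#'
#' @param de A `thermode_de` object.
#' @param tier `"stringent"` (default) or `"suggestive"`; the suggestive
#'   tier includes stringent calls.
#' @param species,stage Optional filters.
#' @return Character vector of gene ids.
#' @export
de_genes <- function(de, tier = c("stringent", "suggestive"),
                     species = NULL, stage = NULL) {
  tier <- match.arg(tier)
  stopifnot(inherits(de, "thermode_de"))
  res <- de$results
  if (!is.null(species)) res <- res[res$species %in% species, ]
  if (!is.null(stage)) res <- res[res$stage %in% stage, ]
  ok <- if (tier == "stringent") res$tier == "stringent" else res$tier != "ns"
  unique(res$gene_id[ok])
}
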