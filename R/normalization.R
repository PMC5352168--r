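# The four normalization schemes compared in the study: upper-quartile
# scaling alone (UQ100), after trimming the top 1 percentile of transcripts
# (UQ99), and both combined with housekeeping-gene anchoring (UQHK100,
# UQHK99). Factors are centered to geometric mean 1 so normalized values
# stay near the raw count scale.

#' Define a normalization scheme
#'
#' The four named schemes differ on two axes: whether libraries are
#' anchored to constitutively expressed housekeeping genes before
#' upper-quartile scaling, and whether the top 1 percent most-expressed
#' transcripts are eliminated (from factor estimation and from downstream
#' testing) first.
#'
#' @param name One of `"UQ100"`, `"UQ99"`, `"UQHK100"`, `"UQHK99"`.
#' @param hk_genes Housekeeping gene ids used by the UQHK schemes. The
#'   defaults are the transferrin receptor and hypoxanthine
#'   phosphoribosyltransferase 1 genes, constitutively expressed across
#'   stages in both study species.
#' @param trim_fraction Fraction of top-expressed genes to eliminate;
#'   defaults to 0 for the `*100` schemes and 0.01 for the `*99` schemes.
#' @return An object of class `norm_scheme`.
#' @examples
#' norm_scheme("UQHK100")
#' norm_scheme("UQ99")
#' @export
norm_scheme <- function(name = c("UQHK100", "UQ100", "UQ99", "UQHK99"),
                        hk_genes = c("Tfr", "Hprt1"),
                        trim_fraction = NULL) {
  name <- match.arg(name)
  use_hk <- grepl("HK", name, fixed = TRUE)
  if (is.null(trim_fraction)) {
    trim_fraction <- if (endsWith(name, "99")) 0.01 else 0
  }
  if (trim_fraction < 0 || trim_fraction >= 1) {
    stop("`trim_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (use_hk && length(hk_genes) == 0) {
    stop("housekeeping scheme requires a non-empty `hk_genes` set",
         call. = FALSE)
  }
  structure(
    list(name = name, use_housekeeping = use_hk,
         trim_fraction = trim_fraction,
         hk_genes = if (use_hk) hk_genes else character()),
    class = "norm_scheme"
  )
}

#' @export
print.norm_scheme <- function(x, ...) {
  cat("<norm_scheme> ", x$name,
      if (x$use_housekeeping) {
        paste0(" (housekeeping: ", paste(x$hk_genes, collapse = ", "), ")")
      } else {
        ""
      },
      "\n  trim fraction: ", x$trim_fraction, "\n", sep = "")
  invisible(x)
}

#' Genes eliminated by top-percentile trimming
#'
#' Ranks genes by mean raw count across the libraries in `counts` and
#' returns the `ceiling(fraction * n_genes)` most-expressed ones. Boundary
#' ties are broken by lexicographic gene id so the set is deterministic.
#'
#' @param counts Long count tibble (`gene_id`, `library_id`, `count`).
#' @param fraction Fraction of genes to eliminate, in `[0, 1)`.
#' @return Character vector of trimmed gene ids (empty for `fraction = 0`).
#' @export
trim_top_percentile <- function(counts, fraction) {
  check_cols(counts, c("gene_id", "library_id", "count"))
  if (fraction < 0 || fraction >= 1) {
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  }
  if (fraction == 0) {
    return(character(0))
  }
  means <- counts |>
    dplyr::summarise(mean_count = mean(.data$count), .by = "gene_id")
  # small slack so e.g. 0.01 * 200 (stored as 2 + 4e-16) still trims 2 genes
  n_trim <- ceiling(fraction * nrow(means) - 1e-8)
  means |>
    dplyr::arrange(dplyr::desc(.data$mean_count), .data$gene_id) |>
    dplyr::slice_head(n = n_trim) |>
    dplyr::pull("gene_id")
}

#' Upper-quartile scale factors
#'
#' Per library, the factor is proportional to the 75th percentile (linear
#' interpolation between order statistics) of that library's nonzero
#' values among non-excluded genes; factors are rescaled to geometric
#' mean 1 across libraries.
#'
#' @param counts Long tibble with columns `gene_id`, `library_id` and a
#'   value column (`count` or `value`).
#' @param exclude Gene ids excluded from factor estimation (e.g. a trimmed
#'   set).
#' @param value_col Name of the value column, default `"count"`.
#' @return Tibble `library_id`, `uq_factor`.
#' @export
upper_quartile_factors <- function(counts, exclude = character(),
                                   value_col = "count") {
  check_cols(counts, c("gene_id", "library_id", value_col))
  eligible <- counts |>
    dplyr::filter(!.data$gene_id %in% exclude, .data[[value_col]] > 0)
  empty <- setdiff(unique(counts$library_id), unique(eligible$library_id))
  if (length(empty) > 0) {
    stop("no nonzero eligible counts in library: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  uq <- eligible |>
    dplyr::summarise(uq = quantile(.data[[value_col]], 0.75, type = 7,
                                   names = FALSE),
                     .by = "library_id")
  uq |>
    dplyr::mutate(uq_factor = .data$uq / gmean(.data$uq)) |>
    dplyr::select("library_id", "uq_factor")
}

#' Housekeeping-gene scale factors
#'
#' Per library, the factor is the geometric mean over housekeeping genes of
#' the ratio of the gene's value in that library to the gene's geometric
#' mean across libraries, rescaled to geometric mean 1. Robust to a single
#' outlying housekeeping gene and symmetric in libraries.
#'
#' @param counts Long tibble with `gene_id`, `library_id` and a value
#'   column.
#' @param hk_genes Housekeeping gene ids; each must be present with a
#'   nonzero value in every library.
#' @param value_col Name of the value column, default `"count"`.
#' @return Tibble `library_id`, `hk_factor`.
#' @export
housekeeping_factors <- function(counts, hk_genes, value_col = "count") {
  check_cols(counts, c("gene_id", "library_id", value_col))
  stopifnot(length(hk_genes) > 0)
  libs <- unique(counts$library_id)
  hk <- counts |> dplyr::filter(.data$gene_id %in% hk_genes)
  offenders <- tidyr::expand_grid(gene_id = hk_genes, library_id = libs) |>
    dplyr::left_join(hk, by = c("gene_id", "library_id")) |>
    dplyr::filter(is.na(.data[[value_col]]) | .data[[value_col]] <= 0)
  if (nrow(offenders) > 0) {
    stop("housekeeping gene(s) missing or zero: ",
         paste(paste0(offenders$gene_id, "@", offenders$library_id),
               collapse = ", "), call. = FALSE)
  }
  hk |>
    dplyr::mutate(ratio = .data[[value_col]] / gmean(.data[[value_col]]),
                  .by = "gene_id") |>
    dplyr::summarise(hk_factor = gmean(.data$ratio), .by = "library_id") |>
    dplyr::mutate(hk_factor = .data$hk_factor / gmean(.data$hk_factor)) |>
    dplyr::select("library_id", "hk_factor")
}

#' Normalize a count matrix under a scheme
#'
#' The trimmed gene set (for `*99` schemes) is computed first and excluded
#' from upper-quartile factor estimation; trimmed genes still receive
#' normalized values but are excluded from downstream testing.
#'
#' Housekeeping and upper-quartile factors are both estimated on the raw
#' counts and multiplied: `combined = hk_factor * uq_factor`, recentered to
#' geometric mean 1. Independent estimation is what makes the mixed scheme
#' meaningful: the upper quartile is scale-equivariant, so re-estimating it
#' on housekeeping-adjusted values would cancel the anchoring exactly and
#' reduce every UQHK scheme to its UQ counterpart. It also makes the two
#' application orders (anchor first or scale first) coincide identically,
#' since scalar factors commute. Housekeeping factors are always estimated
#' from the housekeeping genes themselves, whether or not those genes fall
#' in a trimmed set. Normalization never turns a zero count into a nonzero
#' value.
#'
#' @param counts Long count tibble (`gene_id`, `library_id`, `count`).
#' @param scheme A [norm_scheme()] object (or scheme name).
#' @return A `thermode_norm` object: list with `values` (long tibble
#'   `gene_id`, `library_id`, `count`, `value`), `factors` (per-library
#'   `hk_factor`, `uq_factor`, `combined_factor`), `scheme`, and
#'   `trimmed_genes`.
#' @examples
#' counts <- tidyr::expand_grid(gene_id = c("Tfr", "Hprt1", "g1", "g2"),
#'                              library_id = c("L1", "L2"))
#' counts$count <- c(100L, 200L, 40L, 80L, 10L, 20L, 5L, 10L)
#' nm <- apply_scheme(counts, norm_scheme("UQHK100"))
#' tidy(nm)           # per-library factors
#' nm$values          # normalized values: L2 = 2 x L1 raw, so values match
#' @export
apply_scheme <- function(counts, scheme = norm_scheme("UQHK100")) {
  if (is.character(scheme)) scheme <- norm_scheme(scheme)
  stopifnot(inherits(scheme, "norm_scheme"))
  check_cols(counts, c("gene_id", "library_id", "count"))
  trimmed <- trim_top_percentile(counts, scheme$trim_fraction)
  uq <- upper_quartile_factors(counts, exclude = trimmed)
  if (scheme$use_housekeeping) {
    hk <- housekeeping_factors(counts, scheme$hk_genes)
    factors <- dplyr::left_join(hk, uq, by = "library_id")
  } else {
    factors <- uq |> dplyr::mutate(hk_factor = 1, .before = "uq_factor")
  }
  factors <- factors |>
    dplyr::mutate(combined_factor = .data$hk_factor * .data$uq_factor)
  # recenter the combined factor exactly (absorb residual into uq_factor)
  g <- gmean(factors$combined_factor)
  factors <- factors |>
    dplyr::mutate(uq_factor = .data$uq_factor / g,
                  combined_factor = .data$combined_factor / g)
  values <- counts |>
    dplyr::left_join(factors |> dplyr::select("library_id", "combined_factor"),
                     by = "library_id") |>
    dplyr::mutate(value = .data$count / .data$combined_factor) |>
    dplyr::select("gene_id", "library_id", "count", "value")
  structure(
    list(values = values, factors = factors, scheme = scheme,
         trimmed_genes = trimmed),
    class = "thermode_norm"
  )
}

#' @export
print.thermode_norm <- function(x, ...) {
  cat("<thermode_norm> scheme ", x$scheme$name, ": ",
      length(unique(x$values$gene_id)), " genes x ",
      nrow(x$factors), " libraries",
      if (length(x$trimmed_genes) > 0) {
        paste0(" (", length(x$trimmed_genes), " genes trimmed)")
      } else {
        ""
      }, "\n", sep = "")
  print(x$factors)
  invisible(x)
}

#' @describeIn apply_scheme Per-library normalization factors as a tibble.
#' @param x A `thermode_norm` object.
#' @param ... Unused.
#' @method tidy thermode_norm
#' @export
tidy.thermode_norm <- function(x, ...) {
  x$factors |> dplyr::mutate(scheme = x$scheme$name, .before = 1)
}

#' @describeIn apply_scheme One-row summary (scheme, dimensions, trim count).
#' @method glance thermode_norm
#' @export
glance.thermode_norm <- function(x, ...) {
  tibble::tibble(scheme = x$scheme$name,
                 n_genes = length(unique(x$values$gene_id)),
                 n_libraries = nrow(x$factors),
                 n_trimmed = length(x$trimmed_genes))
}

#' Compare normalization schemes by their differential-expression yield
#'
#' Runs the Fisher differential-expression pipeline once per scheme on a
#' single stage's temperature contrast within one species and reports DE
#' gene counts per scheme plus all pairwise overlaps — the
#' scheme-comparison analysis used to justify the conservative combined
#' scheme (housekeeping anchoring yields fewer calls than upper-quartile
#' alone on composition-skewed data).
#'
#' @param counts Long count tibble for one species.
#' @param samples Sample sheet tibble covering `counts` (see
#'   [read_sample_sheet()]).
#' @param schemes List of [norm_scheme()] objects or scheme names.
#' @param species,stage The contrast to test.
#' @param config A [de_config()].
#' @param tier Tier whose gene sets are compared: `"stringent"` (default)
#'   or `"suggestive"`.
#' @return A list with `summary` (tibble: scheme, n_de), `sets` (named list
#'   of DE gene-id sets) and `overlap` (an [overlap_sets()] report when 2-4
#'   schemes are given).
#' @export
compare_schemes <- function(counts, samples,
                            schemes = list("UQ100", "UQ99", "UQHK100", "UQHK99"),
                            species, stage, config = de_config(),
                            tier = c("stringent", "suggestive")) {
  tier <- match.arg(tier)
  stopifnot(length(schemes) >= 2)
  schemes <- purrr::map(schemes, ~ if (is.character(.x)) norm_scheme(.x) else .x)
  labels <- purrr::map_chr(schemes, "name")
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  sub_samples <- samples |>
    dplyr::filter(.data$species == !!species, .data$stage == !!stage)
  sets <- purrr::map(schemes, function(sc) {
    de <- call_de(counts, sub_samples, scheme = sc, config = config)
    res <- tidy(de)
    ok <- if (tier == "stringent") res$tier == "stringent" else res$tier != "ns"
    res$gene_id[ok]
  })
  names(sets) <- labels
  summary <- tibble::tibble(scheme = labels,
                            n_de = lengths(sets))
  overlap <- if (length(sets) <= 4) overlap_sets(sets) else NULL
  list(summary = summary, sets = sets, overlap = overlap)
}
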