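# Set-level downstream analyses: overlap of DE gene sets across schemes,
# stages and species (Venn decomposition + Jaccard), per-gene direction
# profiles across development, direction concordance against external
# reference profiles (e.g. qPCR), gene-category tagging, and cross-species
# concordance over a caller-supplied shared gene universe.

#' Overlap report for 2-4 labeled gene sets
#'
#' Exact Venn-region counts (every non-empty combination of membership)
#' and pairwise Jaccard indices.
#'
#' @param sets Named list of 2-4 character vectors of gene ids.
#' @return An `overlap_report` object: list with `sizes` (tibble `set`,
#'   `size`), `regions` (tibble `region`, `size`; region labels like
#'   `"A&B"` use set names, and region counts sum to the union size) and
#'   `jaccard` (tibble `set1`, `set2`, `jaccard`).
#' @examples
#' overlap_sets(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
#'                   C = "g3"))
#' @export
overlap_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 4) {
    stop("`sets` must be a named list of 2-4 gene-id sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  sets <- purrr::map(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- purrr::map(sets, ~ universe %in% .x)
  key <- do.call(paste0, purrr::map(membership, ~ as.integer(.x)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                 drop = FALSE]
  regions <- purrr::map_df(seq_len(nrow(combos)), function(i) {
    inc <- unlist(combos[i, ])
    label <- paste(names(sets)[inc], collapse = "&")
    want <- paste(as.integer(inc), collapse = "")
    tibble::tibble(region = label, size = sum(key == want))
  })
  pairs <- utils::combn(names(sets), 2)
  jaccard <- purrr::map_df(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1, j]]]
    b <- sets[[pairs[2, j]]]
    u <- length(union(a, b))
    tibble::tibble(set1 = pairs[1, j], set2 = pairs[2, j],
                   jaccard = if (u == 0) NA_real_ else
                     length(intersect(a, b)) / u)
  })
  structure(
    list(sizes = tibble::tibble(set = names(sets), size = lengths(sets)),
         regions = regions, jaccard = jaccard),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> ", nrow(x$sizes), " sets, union size ",
      sum(x$regions$size), "\n", sep = "")
  print(dplyr::left_join(x$sizes, x$jaccard, by = c(set = "set1")))
  invisible(x)
}

#' @describeIn overlap_sets Venn-region sizes as a tibble.
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  x$regions
}

#' Jaccard index of two gene sets
#' @param a,b Character vectors.
#' @return A number in `[0, 1]`, `NA` when both sets are empty.
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(unique(a), unique(b)))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Per-stage direction profile of one gene
#'
#' The direction of temperature bias at each stage, reported only when the
#' gene reaches at least the suggestive tier there; otherwise `"ns"`.
#'
#' @param results A `thermode_de` object or its [tidy()] tibble.
#' @param gene Gene id.
#' @param species Species label.
#' @param stages Ordered stage set; defaults to the stages present for the
#'   species.
#' @return A tibble `gene_id`, `species`, `stage`, `direction` with one row
#'   per stage (direction in `c("low", "high", "ns")`).
#' @export
direction_profile <- function(results, gene, species, stages = NULL) {
  res <- if (inherits(results, "thermode_de")) results$results else results
  check_cols(res, c("gene_id", "species", "stage", "tier", "direction"))
  res <- res |> dplyr::filter(.data$species == !!species)
  if (is.null(stages)) stages <- sort(unique(res$stage))
  if (!gene %in% res$gene_id) {
    stop("unknown gene for species ", species, ": ", gene, call. = FALSE)
  }
  res |>
    dplyr::filter(.data$gene_id == gene) |>
    dplyr::right_join(tibble::tibble(stage = stages), by = "stage") |>
    dplyr::transmute(
      gene_id = gene, species = !!species, stage = .data$stage,
      direction = dplyr::if_else(
        !is.na(.data$tier) & .data$tier != "ns" & .data$direction != "none",
        .data$direction, "ns")
    ) |>
    dplyr::arrange(match(.data$stage, stages))
}

#' Direction concordance between two per-stage profiles
#'
#' A reproducible surrogate for the qualitative visual comparison of
#' expression profiles over development used to validate this kind of
#' transcriptome against qPCR: per stage, the two profiles match when both
#' report the same direction of temperature bias. Stages where either side
#' is `"ns"` (or tied) are not comparable and are excluded from the
#' denominator by default — agreeing on "no signal" is not evidence of
#' concordant direction.
#'
#' @param profile,reference Tibbles with columns `stage`, `direction`
#'   (values in `c("low", "high", "ns", "none")`), covering the same stage
#'   set.
#' @param include_ns Count stages where both sides are `ns`/`none` as
#'   matches (default `FALSE`).
#' @return A list with `per_stage` (tibble `stage`, `direction`,
#'   `reference`, `comparable`, `match`) and `concordance`
#'   (matches / comparable stages; `NA` when no stage is comparable).
#' @export
direction_concordance <- function(profile, reference, include_ns = FALSE) {
  check_cols(profile, c("stage", "direction"))
  check_cols(reference, c("stage", "direction"))
  if (!setequal(profile$stage, reference$stage) ||
      nrow(profile) != nrow(reference)) {
    stop("profiles cover different stage sets", call. = FALSE)
  }
  merged <- dplyr::inner_join(
    profile |> dplyr::select("stage", "direction"),
    reference |> dplyr::select("stage", reference = "direction"),
    by = "stage"
  )
  is_ns <- function(d) d %in% c("ns", "none")
  merged <- merged |>
    dplyr::mutate(
      comparable = if (include_ns) {
        TRUE
      } else {
        !is_ns(.data$direction) & !is_ns(.data$reference)
      },
      match = .data$comparable & (.data$direction == .data$reference |
        (include_ns & is_ns(.data$direction) & is_ns(.data$reference)))
    )
  n_comp <- sum(merged$comparable)
  list(per_stage = merged,
       concordance = if (n_comp == 0) NA_real_ else
         sum(merged$match) / n_comp)
}

#' Tag differential-expression results with gene categories
#'
#' Counts DE genes per category x species x stage, split by tier and
#' direction. A gene belonging to several categories is counted in each
#' (multi-membership); genes absent from the catalog are tallied under
#' `"uncategorized"`.
#'
#' @param results A `thermode_de` object or its [tidy()] tibble.
#' @param catalog Gene-set tibble from [read_gene_sets()] (`set_name`,
#'   `gene_id`).
#' @return A tibble `set_name`, `species`, `stage`, `tier`, `direction`,
#'   `n`, restricted to DE genes (tier != `"ns"`).
#' @export
tag_gene_sets <- function(results, catalog) {
  res <- if (inherits(results, "thermode_de")) results$results else results
  check_cols(res, c("gene_id", "species", "stage", "tier", "direction"))
  check_cols(catalog, c("set_name", "gene_id"))
  if (nrow(catalog) == 0) {
    stop("`catalog` is empty", call. = FALSE)
  }
  de <- res |> dplyr::filter(.data$tier != "ns")
  tagged <- de |>
    dplyr::left_join(catalog |> dplyr::select("set_name", "gene_id"),
                     by = "gene_id", relationship = "many-to-many") |>
    dplyr::mutate(set_name = dplyr::coalesce(.data$set_name,
                                             "uncategorized"))
  tagged |>
    dplyr::count(.data$set_name, .data$species, .data$stage, .data$tier,
                 .data$direction, name = "n")
}

#' Cross-species concordance of differential expression
#'
#' Compares DE calls between two species over a caller-supplied shared
#' gene universe (orthology mapping is an input, never inferred). Per
#' shared gene and stage, directions are compared where both species reach
#' at least the suggestive tier; a gene is concordant when it has at least
#' one comparable stage and all comparable stages agree.
#'
#' @param results_a,results_b `thermode_de` objects or tidy result tibbles,
#'   one species each.
#' @param shared Either a character vector of gene ids shared verbatim, or
#'   a two-column data frame (`gene_a`, `gene_b`) mapping ids of species A
#'   to species B.
#' @return A list with `per_gene` (tibble `gene_a`, `gene_b`,
#'   `n_comparable`, `n_match`, `status` in concordant / discordant /
#'   not-comparable) and `summary` (tibble of status counts).
#' @export
cross_species_concordance <- function(results_a, results_b, shared) {
  res_a <- if (inherits(results_a, "thermode_de")) results_a$results else results_a
  res_b <- if (inherits(results_b, "thermode_de")) results_b$results else results_b
  if (is.character(shared)) {
    shared <- tibble::tibble(gene_a = shared, gene_b = shared)
  }
  check_cols(shared, c("gene_a", "gene_b"))
  if (nrow(shared) == 0) {
    stop("empty shared gene universe", call. = FALSE)
  }
  dir_of <- function(res, ids, id_col) {
    out <- res |>
      dplyr::filter(.data$gene_id %in% ids) |>
      dplyr::transmute(gene_id = .data$gene_id, stage = .data$stage,
                       dir = dplyr::if_else(.data$tier != "ns" &
                                              .data$direction != "none",
                                            .data$direction, "ns"))
    names(out)[1] <- id_col
    out
  }
  a <- dir_of(res_a, shared$gene_a, "gene_a")
  b <- dir_of(res_b, shared$gene_b, "gene_b")
  per_gene <- shared |>
    dplyr::inner_join(a, by = "gene_a", relationship = "many-to-many") |>
    dplyr::inner_join(b, by = c("gene_b", "stage"), suffix = c("_a", "_b")) |>
    dplyr::mutate(comparable = .data$dir_a != "ns" & .data$dir_b != "ns") |>
    dplyr::summarise(
      n_comparable = sum(.data$comparable),
      n_match = sum(.data$comparable & .data$dir_a == .data$dir_b),
      .by = c("gene_a", "gene_b")
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_comparable == 0 ~ "not-comparable",
      .data$n_match == .data$n_comparable ~ "concordant",
      .default = "discordant"
    ))
  list(per_gene = per_gene,
       summary = per_gene |> dplyr::count(.data$status, name = "n"))
}
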