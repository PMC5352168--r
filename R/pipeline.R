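# End-to-end pipeline: normalize -> per-stage Fisher tests -> FDR tiers ->
# subsample consensus cross-check -> overlap and direction summaries, all
# written to a run directory with a machine-readable manifest. Re-running
# the same configuration reproduces byte-identical outputs: every source of
# randomness flows from seeds recorded in the manifest, and no timestamps
# are written.

#' Pipeline configuration
#'
#' Either point `counts_dir` + `sample_sheet` at HTSeq-count output, or set
#' `simulate` to a [sim_config()] to run on generated data.
#'
#' @param counts_dir Directory of HTSeq-count files named
#'   `<library_id>.txt` (one per library in the sample sheet).
#' @param sample_sheet Path to the sample sheet (see [read_sample_sheet()]).
#' @param simulate Optional [sim_config()]; when given, `counts_dir` and
#'   `sample_sheet` are ignored.
#' @param gene_sets Optional path to a GMT file for category tagging.
#' @param scheme Normalization scheme name or [norm_scheme()].
#' @param stringent_alpha,suggestive_alpha FDR tiers (see [de_config()]).
#' @param subsample_k Integer vector of subsample counts (default
#'   `c(2, 3)`).
#' @param subsample_alpha Per-pair FDR level for consensus calls (default
#'   0.01).
#' @param compare_stage Stage used for the scheme-comparison report
#'   (default: last stage, where temperature responses are strongest in
#'   this design).
#' @param seed Global seed; subsample seeds are derived from it.
#' @return A `pipeline_config` object (list).
#' @export
pipeline_config <- function(counts_dir = NULL, sample_sheet = NULL,
                            simulate = NULL, gene_sets = NULL,
                            scheme = "UQHK100",
                            stringent_alpha = 1e-10,
                            suggestive_alpha = 0.05,
                            subsample_k = c(2L, 3L),
                            subsample_alpha = 0.01,
                            compare_stage = NULL,
                            seed = 1L) {
  if (is.null(simulate) && (is.null(counts_dir) || is.null(sample_sheet))) {
    stop("provide either `simulate` or both `counts_dir` and `sample_sheet`",
         call. = FALSE)
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(
    list(counts_dir = counts_dir, sample_sheet = sample_sheet,
         simulate = simulate, gene_sets = gene_sets,
         scheme = if (is.character(scheme)) norm_scheme(scheme) else scheme,
         de = de_config(stringent_alpha, suggestive_alpha),
         subsample_k = as.integer(subsample_k),
         subsample_alpha = subsample_alpha,
         compare_stage = compare_stage,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load the configured inputs (counts + samples [+ truth])
#' @noRd
load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    return(simulate_experiment(config$simulate))
  }
  samples <- read_sample_sheet(config$sample_sheet)
  tables <- purrr::map2(
    file.path(config$counts_dir, paste0(samples$library_id, ".txt")),
    samples$library_id, read_htseq_counts
  )
  counts <- if (length(tables) > 1) merge_counts(tables) else tables[[1]]
  list(counts = counts, samples = samples, truth = NULL)
}

#' Run the full analysis pipeline into a run directory
#'
#' Stages: load (or simulate) counts; per-species normalization under the
#' configured scheme; per species x stage Fisher differential-expression
#' tests with tiered BH control; subsample consensus calls per
#' species x stage for each configured `k`; scheme comparison at
#' `compare_stage`; cross-stage overlap of stringent calls per species;
#' direction profiles of all suggestive-or-better genes; optional
#' gene-category tagging; and a JSON manifest recording seeds, the
#' configuration hash and package version.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must not already contain a
#'   manifest).
#' @return `out_dir`, invisibly. Artifacts: `factors.tsv`,
#'   `de_results.tsv`, `de_summary.tsv`, `subsample_consensus.tsv`,
#'   `scheme_comparison.tsv`, `overlap_<species>.tsv`,
#'   `direction_profiles.tsv`, optional `category_summary.tsv`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- load_pipeline_inputs(config)
  counts <- inputs$counts
  samples <- inputs$samples

  de <- call_de(counts, samples, scheme = config$scheme, config = config$de)
  factors <- purrr::imap(de$normalization,
                         ~ tidy(.x) |> dplyr::mutate(species = .y,
                                                     .before = 1)) |>
    dplyr::bind_rows()
  write_results(factors, file.path(out_dir, "factors.tsv"))
  write_results(de$results, file.path(out_dir, "de_results.tsv"))
  de_summary <- glance(de) |>
    dplyr::left_join(
      de$results |>
        dplyr::filter(.data$tier == "stringent") |>
        dplyr::count(.data$species, .data$stage, .data$direction) |>
        tidyr::pivot_wider(names_from = "direction", values_from = "n",
                           names_prefix = "stringent_",
                           values_fill = 0L),
      by = c("species", "stage")
    )
  write_results(de_summary, file.path(out_dir, "de_summary.tsv"))

  # subsample consensus cross-check per species x stage x k
  consensus_rows <- purrr::pmap(
    samples |> dplyr::distinct(.data$species, .data$stage),
    function(species, stage) {
      lib_low <- samples$library_id[samples$species == species &
                                      samples$stage == stage &
                                      samples$temperature == "low"]
      lib_high <- samples$library_id[samples$species == species &
                                       samples$stage == stage &
                                       samples$temperature == "high"]
      purrr::map(config$subsample_k, function(k) {
        seed_low <- config$seed + 1000L * k +
          2L * which(samples$library_id == lib_low)
        seed_high <- config$seed + 1000L * k +
          2L * which(samples$library_id == lib_high) + 1L
        cons <- consensus_calls(
          partition_counts(counts, lib_low, k, seed_low),
          partition_counts(counts, lib_high, k, seed_high),
          alpha = config$subsample_alpha
        )
        full_set <- de_genes(de, "stringent", species = species,
                             stage = stage)
        tibble::tibble(
          species = species, stage = stage, k = k,
          seed_low = seed_low, seed_high = seed_high,
          n_consensus = nrow(cons$consensus),
          n_full_stringent = length(full_set),
          jaccard_vs_full = jaccard_index(cons$consensus$gene_id, full_set),
          consensus_genes = paste(sort(cons$consensus$gene_id),
                                  collapse = ",")
        )
      }) |> dplyr::bind_rows()
    }
  ) |> dplyr::bind_rows()
  write_results(consensus_rows, file.path(out_dir, "subsample_consensus.tsv"))

  # scheme comparison on one stage of the first species
  sp1 <- samples$species[1]
  cmp_stage <- config$compare_stage %||% max(samples$stage)
  cmp <- compare_schemes(counts, samples,
                         schemes = list("UQ100", "UQ99", "UQHK100", "UQHK99"),
                         species = sp1, stage = cmp_stage,
                         config = config$de)
  cmp_tbl <- cmp$summary |>
    dplyr::mutate(species = sp1, stage = cmp_stage, .before = 1)
  write_results(cmp_tbl, file.path(out_dir, "scheme_comparison.tsv"))
  write_results(cmp$overlap$jaccard,
                file.path(out_dir, "scheme_overlap_jaccard.tsv"))

  # cross-stage overlap of stringent calls per species
  for (sp in unique(samples$species)) {
    stages <- sort(unique(samples$stage[samples$species == sp]))
    sets <- purrr::map(stages, ~ de_genes(de, "stringent", species = sp,
                                          stage = .x))
    names(sets) <- paste0("stage", stages)
    nonempty <- sets[lengths(sets) > 0]
    if (length(nonempty) >= 2) {
      ov <- overlap_sets(nonempty[seq_len(min(4, length(nonempty)))])
      write_results(tidy(ov),
                    file.path(out_dir, paste0("overlap_", sp, ".tsv")))
    } else {
      write_results(tibble::tibble(region = character(), size = integer()),
                    file.path(out_dir, paste0("overlap_", sp, ".tsv")))
    }
  }

  # direction profiles for every gene reaching the suggestive tier anywhere
  profiles <- de$results |>
    dplyr::mutate(direction = dplyr::if_else(
      .data$tier != "ns" & .data$direction != "none",
      .data$direction, "ns")) |>
    dplyr::select("gene_id", "species", "stage", "direction") |>
    dplyr::filter(any(.data$direction != "ns"),
                  .by = c("gene_id", "species")) |>
    dplyr::arrange(.data$species, .data$gene_id, .data$stage)
  write_results(profiles, file.path(out_dir, "direction_profiles.tsv"))

  if (!is.null(config$gene_sets)) {
    catalog <- read_gene_sets(config$gene_sets)
    write_results(tag_gene_sets(de, catalog),
                  file.path(out_dir, "category_summary.tsv"))
  }

  manifest <- list(
    package = "thermode",
    version = as.character(utils::packageVersion("thermode")),
    seed = config$seed,
    subsample_k = config$subsample_k,
    subsample_alpha = config$subsample_alpha,
    scheme = config$scheme$name,
    stringent_alpha = config$de$stringent_alpha,
    suggestive_alpha = config$de$suggestive_alpha,
    compare_stage = cmp_stage,
    simulated = !is.null(config$simulate),
    config_hash = rlang::hash(config),
    n_genes = length(unique(counts$gene_id)),
    n_libraries = length(unique(counts$library_id))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(inputs$truth)) {
    write_results(inputs$truth, file.path(out_dir, "truth.tsv"))
  }
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts written by [run_pipeline()] and assembles a summary:
#' per-stage DE counts by direction, the scheme-comparison table, subsample
#' concordance, optional category summaries, and the manifest (seeds and
#' configuration hash verbatim).
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return A list of tibbles plus the manifest, of class `thermode_report`.
#' @export
make_report <- function(run_dir) {
  required <- c("manifest.json", "de_summary.tsv", "scheme_comparison.tsv",
                "subsample_consensus.tsv", "de_results.tsv")
  missing <- required[!file.exists(file.path(run_dir, required))]
  if (length(missing) > 0) {
    stop("incomplete run; missing artifact(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cat_path <- file.path(run_dir, "category_summary.tsv")
  structure(
    list(
      de_summary = read_results(file.path(run_dir, "de_summary.tsv")),
      scheme_comparison = read_results(file.path(run_dir,
                                                 "scheme_comparison.tsv")),
      subsample_consensus = read_results(
        file.path(run_dir, "subsample_consensus.tsv"),
        col_types = readr::cols(consensus_genes = readr::col_character(),
                                .default = readr::col_guess())
      ),
      category_summary = if (file.exists(cat_path)) read_results(cat_path),
      manifest = manifest
    ),
    class = "thermode_report"
  )
}

#' @export
print.thermode_report <- function(x, ...) {
  cat("<thermode_report> scheme ", x$manifest$scheme, ", seed ",
      x$manifest$seed, ", config hash ", x$manifest$config_hash, "\n",
      "DE summary:\n", sep = "")
  print(x$de_summary)
  cat("Scheme comparison (stage ", x$manifest$compare_stage, "):\n", sep = "")
  print(x$scheme_comparison)
  invisible(x)
}
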