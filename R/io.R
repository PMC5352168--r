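# Readers and writers for the pipeline's external formats: HTSeq-count
# two-column tables, sample sheets, GMT gene sets and TSV result tables.

#' Read one HTSeq-count output file
#'
#' Parses the two-column `gene_id TAB count` text format written by
#' `htseq-count`. Summary rows whose gene id starts with `"__"`
#' (`__no_feature`, `__ambiguous`, ...) are excluded from the gene universe
#' but kept as QC metadata in the `htseq_summary` attribute.
#'
#' @param path Path to a two-column tab-delimited count file.
#' @param library_id Identifier assigned to this library; stored in the
#'   `library_id` column.
#' @return A tibble with columns `gene_id`, `library_id`, `count`
#'   (non-negative integer), one row per gene, with attribute
#'   `htseq_summary` (a tibble of the `"__"` QC rows, possibly empty).
#' @examples
#' f <- tempfile()
#' writeLines(c("g1\t5", "g2\t0", "__no_feature\t100"), f)
#' counts <- read_htseq_counts(f, "lib1")
#' counts
#' attr(counts, "htseq_summary")
#' @seealso [merge_counts()] to combine libraries, [read_sample_sheet()]
#' @export
read_htseq_counts <- function(path, library_id) {
  stopifnot(is.character(library_id), length(library_id) == 1)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop("no gene rows in ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_ncol <- which(lengths(parts) != 2)
  if (length(bad_ncol) > 0) {
    stop("malformed line ", bad_ncol[1], " in ", path,
         ": expected 2 tab-separated columns", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  raw <- vapply(parts, `[[`, character(1), 2)
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) | num < 0 | num != floor(num))
  if (length(bad) > 0) {
    stop("malformed line ", bad[1], " in ", path,
         ": count ", raw[bad[1]], " is not a non-negative integer",
         call. = FALSE)
  }
  is_summary <- startsWith(ids, "__")
  summary_tbl <- tibble::tibble(field = ids[is_summary],
                                value = as.integer(num[is_summary]))
  ids <- ids[!is_summary]
  num <- num[!is_summary]
  if (length(ids) == 0) {
    stop("no gene rows in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate gene_id in ", path, ": ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(gene_id = ids, library_id = library_id,
                        count = as.integer(num))
  attr(out, "htseq_summary") <- summary_tbl
  attr(out, "source") <- path
  out
}

#' Merge single-library count tables into one long count table
#'
#' The merged gene universe is the union of gene ids; genes absent from a
#' library are filled with count 0, so per-library column totals are
#' conserved exactly.
#'
#' @param tables A list of count tibbles as returned by
#'   [read_htseq_counts()] (columns `gene_id`, `library_id`, `count`).
#' @return A long tibble `gene_id`, `library_id`, `count` covering the full
#'   gene x library grid, genes sorted, libraries in input order.
#' @export
merge_counts <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  purrr::walk(tables, check_cols, cols = c("gene_id", "library_id", "count"),
              what = "each count table")
  lib_ids <- purrr::map_chr(tables, ~ unique(.x$library_id))
  if (anyDuplicated(lib_ids)) {
    stop("duplicate library_id across tables: ",
         paste(unique(lib_ids[duplicated(lib_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_rows(tables) |>
    dplyr::mutate(library_id = factor(.data$library_id, levels = lib_ids)) |>
    tidyr::complete(.data$gene_id, .data$library_id,
                    fill = list(count = 0L)) |>
    dplyr::mutate(library_id = as.character(.data$library_id)) |>
    dplyr::arrange(.data$gene_id) |>
    dplyr::select("gene_id", "library_id", "count")
}

#' Read a sample sheet describing the library design
#'
#' Expects a delimited text file (tab or comma, detected from the header
#' line) with columns `library_id`, `species`, `stage`, `temperature`,
#' `tissue`, `n_pooled`. Temperature labels are mapped to the internal
#' ordered levels `"low"`/`"high"` via `temperature_map`; the original
#' label is kept in `temp_label`.
#'
#' A valid unreplicated design has exactly one library per
#' (species, stage, temperature); duplicated cells raise a warning (both
#' rows are retained, downstream tests will refuse the design).
#'
#' @param path Path to the sample sheet.
#' @param temperature_map Named character vector mapping sheet labels to
#'   `"low"`/`"high"`. Default maps 26 degree labels to `low` and 31 degree
#'   labels to `high`, the incubation temperatures of this study design.
#' @param stages Integer vector of permitted developmental stages.
#' @return A tibble of library descriptors, one row per library.
#' @export
read_sample_sheet <- function(path,
                              temperature_map = c("26" = "low", "26C" = "low",
                                                  "31" = "high", "31C" = "high"),
                              stages = c(9L, 12L, 15L, 19L, 22L)) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  sheet <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                             progress = FALSE, show_col_types = FALSE)
  required <- c("library_id", "species", "stage", "temperature", "tissue",
                "n_pooled")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$library_id)) {
    stop("duplicate library_id in sample sheet: ",
         paste(unique(sheet$library_id[duplicated(sheet$library_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_stage <- setdiff(unique(sheet$stage), stages)
  if (length(bad_stage) > 0) {
    stop("stage(s) outside the declared set {",
         paste(stages, collapse = ","), "}: ",
         paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  labels <- as.character(sheet$temperature)
  unknown <- setdiff(unique(labels), names(temperature_map))
  if (length(unknown) > 0) {
    stop("unknown temperature label(s): ", paste(unknown, collapse = ", "),
         "; extend `temperature_map`", call. = FALSE)
  }
  out <- sheet |>
    dplyr::transmute(
      library_id = as.character(.data$library_id),
      species = as.character(.data$species),
      stage = as.integer(.data$stage),
      temperature = unname(temperature_map[labels]),
      temp_label = labels,
      tissue = as.character(.data$tissue),
      n_pooled = as.integer(.data$n_pooled)
    )
  if (any(out$n_pooled <= 0)) {
    stop("n_pooled must be a positive integer", call. = FALSE)
  }
  dup_cell <- out |>
    dplyr::count(.data$species, .data$stage, .data$temperature) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_cell) > 0) {
    warning("design violation: more than one library per ",
            "(species, stage, temperature) cell; both retained",
            call. = FALSE)
  }
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A long tibble `set_name`, `description`, `gene_id` (one row per
#'   set membership). Empty sets contribute no rows but raise a warning.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::imap(parts, function(p, i) {
    if (length(p) < 2 || !nzchar(p[1])) {
      stop("GMT line ", i, ": blank set name or missing description field",
           call. = FALSE)
    }
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning("GMT set '", p[1], "' has no members", call. = FALSE)
      return(tibble::tibble(set_name = character(), description = character(),
                            gene_id = character()))
    }
    tibble::tibble(set_name = p[1], description = p[2], gene_id = members)
  })
  catalog <- dplyr::bind_rows(rows)
  sets <- unique(purrr::map_chr(parts, 1))
  if (anyDuplicated(sets)) {
    stop("duplicate set name(s) in GMT: ",
         paste(unique(sets[duplicated(sets)]), collapse = ", "),
         call. = FALSE)
  }
  catalog
}

#' Write a result table as TSV
#'
#' Tab-separated, UTF-8, Unix newlines, full floating-point precision
#' (small q-values fall into scientific notation). An empty table writes a
#' header-only file. Together with [read_results()] integer and string
#' columns round-trip losslessly.
#'
#' @param results A data frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || ncol(results) == 0) {
    stop("`results` must be a data frame with at least one column",
         call. = FALSE)
  }
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to a TSV result table.
#' @param col_types Optional readr column specification; guessed otherwise.
#' @return A tibble.
#' @export
read_results <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}
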