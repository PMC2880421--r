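#' Read a long-form CpG methylation table
#'
#' The canonical input is a tidy TSV with one row per quantified CpG:
#' columns `sample_id`, `gene`, `cpg_index` (1-based position ordinal within
#' the assayed target region) and `methylation_percent` in \[0, 100\].
#' Missing measurements are the literal `NA` (an empty cell is also accepted).
#' Validation is total: the file either yields a fully valid table or an
#' error; nothing is partially loaded.
#'
#' @param path Path to a TSV (or CSV with `delim = ","`) file with a header.
#' @param panel Gene panel the rows must belong to (see [gene_panel()]).
#' @param delim Field delimiter, tab by default.
#' @return Tibble with columns `sample_id`, `gene`, `cpg_index`,
#'   `methylation_percent`.
#' @seealso [write_cpg_table()], [join_cohort()]
#' @export
read_cpg_table <- function(path, panel = gene_panel(), delim = "\t") {
  x <- read_checked(path, delim,
                    cols = c(sample_id = "c", gene = "c",
                             cpg_index = "i", methylation_percent = "d"))
  validate_cpg_table(x, panel)
}

#' Write a long-form CpG methylation table
#'
#' @param x Tibble as returned by [read_cpg_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(x, path) {
  readr::write_tsv(x[, c("sample_id", "gene", "cpg_index",
                         "methylation_percent")], path, na = "NA")
  invisible(path)
}

validate_cpg_table <- function(x, panel) {
  if (any(is.na(x$sample_id)) || any(is.na(x$gene)) || any(is.na(x$cpg_index))) {
    abort("sample_id, gene and cpg_index may not be missing",
          class = "methcall_validation_error")
  }
  bad_gene <- setdiff(unique(x$gene), panel$gene)
  if (length(bad_gene)) {
    abort(paste0("genes not in the panel: ", paste(bad_gene, collapse = ", ")),
          class = "methcall_validation_error")
  }
  out <- x$methylation_percent
  bad <- which(!is.na(out) & (out < 0 | out > 100))
  if (length(bad)) {
    abort(paste0("methylation_percent outside [0, 100] in row(s): ",
                 paste(head(bad, 5L), collapse = ", ")),
          class = "methcall_validation_error")
  }
  key <- paste(x$sample_id, x$gene, x$cpg_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE]
    abort(paste0("duplicate (sample_id, gene, cpg_index) key, e.g. ",
                 dup$sample_id[1], "/", dup$gene[1], "/", dup$cpg_index[1]),
          class = "methcall_validation_error")
  }
  if (any(x$cpg_index < 1L)) {
    abort("cpg_index is 1-based and must be >= 1",
          class = "methcall_validation_error")
  }
  tibble::as_tibble(x)
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `diagnosis` (normal, DCIS, invasive or mixed)
#' and the clinicopathological factors `er`, `pr`, `tp53`, `ki67` (two-level)
#' and `grade` (three-level). Empty factor cells map to `unknown`; `diagnosis`
#' must never be missing, and normal samples must have `grade = unknown`.
#'
#' @inheritParams read_cpg_table
#' @return Tibble with one validated row per sample.
#' @export
read_metadata <- function(path, delim = "\t") {
  x <- read_checked(path, delim,
                    cols = c(sample_id = "c", diagnosis = "c", er = "c",
                             pr = "c", tp53 = "c", ki67 = "c", grade = "c"))
  validate_metadata(x)
}

#' Write a sample metadata table
#' @param x Metadata tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  readr::write_tsv(x[, c("sample_id", "diagnosis", "er", "pr", "tp53",
                         "ki67", "grade")], path, na = "NA")
  invisible(path)
}

validate_metadata <- function(x) {
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("duplicated sample_id: ",
                 paste(unique(x$sample_id[duplicated(x$sample_id)]),
                       collapse = ", ")),
          class = "methcall_validation_error")
  }
  if (any(is.na(x$diagnosis))) {
    abort("diagnosis may not be missing", class = "methcall_validation_error")
  }
  bad <- setdiff(unique(x$diagnosis), diagnosis_levels())
  if (length(bad)) {
    abort(paste0("unrecognised diagnosis level(s): ",
                 paste(bad, collapse = ", "), "; allowed: ",
                 paste(diagnosis_levels(), collapse = ", ")),
          class = "methcall_validation_error")
  }
  lv <- factor_levels()
  for (f in names(lv)) {
    v <- x[[f]]
    v[is.na(v) | v == ""] <- "unknown"
    bad <- setdiff(unique(v), c(lv[[f]], "unknown"))
    if (length(bad)) {
      abort(paste0("unrecognised ", f, " level(s): ",
                   paste(bad, collapse = ", "), "; allowed: ",
                   paste(c(lv[[f]], "unknown"), collapse = ", ")),
            class = "methcall_validation_error")
    }
    x[[f]] <- v
  }
  if (any(x$diagnosis == "normal" & x$grade != "unknown")) {
    abort("normal samples must have grade = unknown",
          class = "methcall_validation_error")
  }
  tibble::as_tibble(x)
}

#' Read a technical-control measurement table
#'
#' Controls (commercial unmethylated DNA and mixed lymphocyte DNA run in
#' parallel with the samples) define the technical background of the
#' pyrosequencing assays. They are recorded and reported; an optional mode
#' subtracts the unmethylated-control mean per gene (see
#' [subtract_background()]).
#'
#' @inheritParams read_cpg_table
#' @return Tibble with columns `control_type`, `gene`, `cpg_index`,
#'   `methylation_percent`.
#' @export
read_control_table <- function(path, panel = gene_panel(), delim = "\t") {
  x <- read_checked(path, delim,
                    cols = c(control_type = "c", gene = "c",
                             cpg_index = "i", methylation_percent = "d"))
  bad <- setdiff(unique(x$control_type), c("unmethylated_dna", "lymphocyte_dna"))
  if (length(bad)) {
    abort(paste0("unrecognised control_type: ", paste(bad, collapse = ", ")),
          class = "methcall_validation_error")
  }
  v <- x$methylation_percent
  if (any(!is.na(v) & (v < 0 | v > 100))) {
    abort("control methylation_percent outside [0, 100]",
          class = "methcall_validation_error")
  }
  bad_gene <- setdiff(unique(x$gene), panel$gene)
  if (length(bad_gene)) {
    abort(paste0("control genes not in the panel: ",
                 paste(bad_gene, collapse = ", ")),
          class = "methcall_validation_error")
  }
  tibble::as_tibble(x)
}

# Shared reader: enforces the header, fails on malformed rows with the
# offending line number, accepts "" and "NA" as missing.
read_checked <- function(path, delim, cols) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "methcall_io_error")
  }
  spec <- do.call(readr::cols, as.list(cols))
  x <- suppressWarnings(
    readr::read_delim(path, delim = delim, col_types = spec,
                      na = c("", "NA"), progress = FALSE,
                      show_col_types = FALSE)
  )
  missing_cols <- setdiff(names(cols), names(x))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "methcall_validation_error")
  }
  pr <- readr::problems(x)
  if (nrow(pr)) {
    abort(paste0("malformed value at line ", pr$row[1], ", column '",
                 names(x)[pr$col[1]], "' of ", path),
          class = "methcall_parse_error")
  }
  x[names(cols)]
}

#' Assemble a cohort from measurements and metadata
#'
#' Joins a validated CpG table to sample metadata. Every measurement's
#' `sample_id` must appear in the metadata; orphans are an error listing the
#' offending ids. The cohort keeps the long measurement table, the metadata
#' and the panel together and is the unit every downstream stage consumes.
#'
#' @param measurements Tibble from [read_cpg_table()].
#' @param metadata Tibble from [read_metadata()].
#' @param panel Gene panel.
#' @return A `meth_cohort` object.
#' @examples
#' cfg <- default_simulation_config(seed = 1)
#' sim <- simulate_cohort(cfg)
#' cohort <- join_cohort(sim$measurements, sim$metadata)
#' cohort
#' @export
join_cohort <- function(measurements, metadata, panel = gene_panel()) {
  measurements <- validate_cpg_table(measurements, panel)
  metadata <- validate_metadata(metadata)
  orphans <- setdiff(unique(measurements$sample_id), metadata$sample_id)
  if (length(orphans)) {
    abort(paste0("measurements for sample(s) absent from metadata: ",
                 paste(head(orphans, 10L), collapse = ", ")),
          class = "methcall_validation_error")
  }
  structure(
    list(measurements = measurements, metadata = metadata, panel = panel),
    class = "meth_cohort"
  )
}

#' @export
print.meth_cohort <- function(x, ...) {
  counts <- table(factor(x$metadata$diagnosis, levels = diagnosis_levels()))
  cat("<meth_cohort> ", nrow(x$metadata), " samples (",
      paste(paste0(names(counts), "=", counts), collapse = ", "), "), ",
      nrow(x$panel), " genes, ", nrow(x$measurements),
      " CpG measurements\n", sep = "")
  invisible(x)
}

#' Per-gene sample-by-CpG view of a cohort
#'
#' @param cohort A `meth_cohort`.
#' @param gene Gene symbol.
#' @return Wide tibble, one row per sample with that gene measured, one
#'   column per CpG (`cpg_1`, `cpg_2`, ...).
#' @export
gene_matrix <- function(cohort, gene) {
  stopifnot(inherits(cohort, "meth_cohort"))
  m <- dplyr::filter(cohort$measurements, .data$gene == !!gene)
  tidyr::pivot_wider(m[, c("sample_id", "cpg_index", "methylation_percent")],
                     names_from = "cpg_index",
                     values_from = "methylation_percent",
                     names_prefix = "cpg_", names_sort = TRUE)
}
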