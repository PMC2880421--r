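#' Gene-level average methylation per sample
#'
#' Collapses per-CpG methylation to one value per sample and gene: the
#' arithmetic mean over the non-missing CpGs of the assayed target region.
#' A sample whose assay failed entirely (no valid CpGs) gets a missing
#' average with `n_cpgs_used = 0`.
#'
#' @param x A `meth_cohort` or a long measurement tibble.
#' @return Tibble with columns `sample_id`, `gene`, `avg_methylation`,
#'   `n_cpgs_used`.
#' @examples
#' m <- tibble::tibble(sample_id = "s1", gene = "FOXC1", cpg_index = 1:3,
#'                     methylation_percent = c(10, NA, 30))
#' gene_sample_averages(m)  # avg 20, n_cpgs_used 2
#' @export
gene_sample_averages <- function(x) {
  m <- if (inherits(x, "meth_cohort")) x$measurements else x
  out <- dplyr::summarise(
    dplyr::group_by(m, .data$sample_id, .data$gene),
    avg_methylation = mean(.data$methylation_percent, na.rm = TRUE),
    n_cpgs_used = sum(!is.na(.data$methylation_percent)),
    .groups = "drop"
  )
  out$avg_methylation[out$n_cpgs_used == 0L] <- NA_real_
  out
}

#' Average methylation of one sample-gene assay
#'
#' Vector form of the averaging rule: mean over non-missing CpGs, missing
#' when every CpG is missing.
#'
#' @param values Numeric vector of per-CpG methylation percentages (may
#'   contain `NA`).
#' @return List with `avg_methylation` and `n_cpgs_used`.
#' @export
average_methylation <- function(values) {
  n <- sum(!is.na(values))
  list(avg_methylation = if (n == 0L) NA_real_ else mean(values, na.rm = TRUE),
       n_cpgs_used = n)
}

#' Calibrate the normal-tissue reference for one gene
#'
#' The reference is the mean and standard deviation of the gene-level
#' averages of the normal-control samples; a tumour sample is later called
#' hypermethylated when its average exceeds `mu + k * sigma` (strictly) and
#' hypomethylated below `mu - k * sigma` (strictly), with `k = 2` by default.
#'
#' @param values Normal-sample gene averages (percent); missing dropped.
#' @param gene Gene symbol carried along in the result.
#' @param k Threshold multiplier on the standard deviation (default 2).
#' @param sd_denominator `"n-1"` (sample SD, the default) or `"n"`
#'   (population SD). With only a handful of normal controls the choice is
#'   material, so it is exposed.
#' @return One-row tibble: `gene`, `n_normals`, `mu`, `sigma`, `lower`,
#'   `upper`.
#' @examples
#' fit_normal_reference(c(4, 5, 6), gene = "FOXC1")  # mu 5, sigma 1, (3, 7)
#' @export
fit_normal_reference <- function(values, gene = NA_character_, k = 2,
                                 sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2L) {
    abort(paste0("reference calibration for ", gene, " needs >= 2 normal ",
                 "averages, got ", n),
          class = "methcall_calibration_error")
  }
  mu <- mean(v)
  sigma <- if (sd_denominator == "n-1") sd(v) else sqrt(mean((v - mu)^2))
  if (sigma == 0) {
    warn(paste0("degenerate reference for ", gene,
                ": all normal averages identical (sigma = 0)"))
  }
  tibble::tibble(gene = gene, n_normals = n, mu = mu, sigma = sigma,
                 lower = mu - k * sigma, upper = mu + k * sigma)
}

#' Calibrate normal references for every gene of a cohort
#'
#' Uses the diagnosis = normal samples measured for each gene; genes differ
#' in how many normals were assayed (assay failures, or panels extended with
#' additional normal tissue for a subset of genes), so each gene's reference
#' uses all normals actually measured for it.
#'
#' @param cohort A `meth_cohort`.
#' @inheritParams fit_normal_reference
#' @return Tibble with one reference row per calibratable gene. Genes with
#'   fewer than two normal averages are dropped with a warning naming them;
#'   downstream calling then fails only for those genes.
#' @export
fit_normal_references <- function(cohort, k = 2,
                                  sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  avg <- gene_sample_averages(cohort)
  normals <- cohort$metadata$sample_id[cohort$metadata$diagnosis == "normal"]
  avg <- avg[avg$sample_id %in% normals & !is.na(avg$avg_methylation), ]
  refs <- list()
  failed <- character()
  for (g in cohort$panel$gene) {
    v <- avg$avg_methylation[avg$gene == g]
    if (length(v) < 2L) {
      failed <- c(failed, g)
      next
    }
    refs[[g]] <- fit_normal_reference(v, gene = g, k = k,
                                      sd_denominator = sd_denominator)
  }
  if (length(failed)) {
    warn(paste0("no reference calibrated (fewer than 2 normal averages) for: ",
                paste(failed, collapse = ", ")))
  }
  dplyr::bind_rows(refs)
}

#' Call one gene average against its normal reference
#'
#' @param avg Gene-level average methylation (percent) or `NA`.
#' @param ref One-row reference tibble from [fit_normal_reference()].
#' @param gene Optional gene symbol; if given it must match `ref$gene`.
#' @return One of `"hyper"`, `"in_range"`, `"hypo"`, `"missing"`. Boundary
#'   values (exactly at a threshold) are `in_range`: the thresholds are
#'   strict.
#' @examples
#' ref <- fit_normal_reference(c(4, 5, 6), gene = "FOXC1")
#' call_sample(8.0, ref)  # "hyper": 8 > 7
#' call_sample(7.0, ref)  # "in_range": boundary is strict
#' @export
call_sample <- function(avg, ref, gene = NULL) {
  if (!is.null(gene) && !is.na(ref$gene) && !identical(gene, ref$gene)) {
    abort(paste0("reference is for ", ref$gene, ", not ", gene),
          class = "methcall_validation_error")
  }
  if (is.na(avg)) return("missing")
  if (avg > ref$upper) return("hyper")
  if (avg < ref$lower) return("hypo")
  "in_range"
}

#' Call every tumour sample of a cohort
#'
#' Applies the strict mean +/- k*SD rule per gene to all non-normal samples.
#' Normal samples are the calibration set and receive no call. Hypo states
#' are computed for every gene; default reports show hypermethylation only
#' for non-imprinted genes and both aberrant states for imprinted genes
#' (see [frequency_table()]).
#'
#' @param cohort A `meth_cohort`.
#' @param refs Reference tibble from [fit_normal_references()]. Computed
#'   from the cohort when `NULL`.
#' @inheritParams fit_normal_reference
#' @return Tibble: `sample_id`, `gene`, `avg_methylation`, `n_cpgs_used`,
#'   `state`. Genes without a calibrated reference are omitted with a
#'   warning; other genes proceed.
#' @export
call_cohort <- function(cohort, refs = NULL, k = 2,
                        sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (is.null(refs)) {
    refs <- fit_normal_references(cohort, k = k,
                                  sd_denominator = sd_denominator)
  }
  missing_ref <- setdiff(cohort$panel$gene, refs$gene)
  if (length(missing_ref)) {
    warn(paste0("no calls for gene(s) without a reference: ",
                paste(missing_ref, collapse = ", ")))
  }
  tumours <- cohort$metadata$sample_id[cohort$metadata$diagnosis != "normal"]
  avg <- gene_sample_averages(cohort)
  avg <- avg[avg$sample_id %in% tumours & avg$gene %in% refs$gene, ]
  # Assays never attempted produce no measurement rows at all; materialise
  # them as explicit missing calls so denominators are auditable.
  full <- tidyr::expand_grid(sample_id = tumours,
                             gene = intersect(cohort$panel$gene, refs$gene))
  avg <- dplyr::left_join(full, avg, by = c("sample_id", "gene"))
  avg$n_cpgs_used[is.na(avg$n_cpgs_used)] <- 0L
  avg <- dplyr::left_join(avg, refs[, c("gene", "lower", "upper")], by = "gene")
  state <- rep("in_range", nrow(avg))
  state[!is.na(avg$avg_methylation) & avg$avg_methylation > avg$upper] <- "hyper"
  state[!is.na(avg$avg_methylation) & avg$avg_methylation < avg$lower] <- "hypo"
  state[is.na(avg$avg_methylation)] <- "missing"
  out <- avg[, c("sample_id", "gene", "avg_methylation", "n_cpgs_used")]
  out$state <- state
  tibble::as_tibble(out)
}

# Round half away from zero, the convention of the printed frequency tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aberrant-methylation frequency per gene and diagnosis group
#'
#' For every gene, diagnosis group and call state, counts calls and reports
#' the percentage over the samples with a non-missing call for that gene
#' (samples whose assay failed are excluded from the denominator, and
#' `n_valid` is printed next to every frequency so denominators are
#' auditable). Frequencies are rounded half-up to one decimal.
#'
#' @param calls Call tibble from [call_cohort()].
#' @param metadata Sample metadata.
#' @return Tibble: `gene`, `group`, `state`, `n_called`, `n_valid`,
#'   `frequency` (percent; `NA` for an empty group).
#' @export
frequency_table <- function(calls, metadata) {
  x <- dplyr::left_join(calls,
                        metadata[, c("sample_id", "diagnosis")],
                        by = "sample_id")
  groups <- intersect(tumour_groups(), unique(x$diagnosis))
  states <- c("hyper", "in_range", "hypo", "missing")
  grid <- tidyr::expand_grid(gene = unique(calls$gene),
                             group = groups, state = states)
  counts <- dplyr::count(x, gene = .data$gene, group = .data$diagnosis,
                         state = .data$state, name = "n_called")
  out <- dplyr::left_join(grid, counts, by = c("gene", "group", "state"))
  out$n_called[is.na(out$n_called)] <- 0L
  valid <- dplyr::summarise(
    dplyr::group_by(x, gene = .data$gene, group = .data$diagnosis),
    n_valid = sum(.data$state != "missing"), .groups = "drop"
  )
  out <- dplyr::left_join(out, valid, by = c("gene", "group"))
  out$n_valid[is.na(out$n_valid)] <- 0L
  out$frequency <- ifelse(out$n_valid > 0 & out$state != "missing",
                          round_half_up(100 * out$n_called / out$n_valid, 1L),
                          NA_real_)
  tibble::as_tibble(out)
}

#' Default report view of a frequency table
#'
#' Mirrors the usual presentation: hypermethylation frequencies for
#' non-imprinted genes; both hyper- and hypomethylation for imprinted genes,
#' whose allele-specific methylation makes deviation in either direction
#' aberrant.
#'
#' @param freq Output of [frequency_table()].
#' @param panel Gene panel with the `imprinted` flag.
#' @return Filtered frequency tibble.
#' @export
report_frequencies <- function(freq, panel = gene_panel()) {
  imprinted <- panel$gene[panel$imprinted]
  keep <- freq$state == "hyper" |
    (freq$gene %in% imprinted & freq$state == "hypo")
  freq[keep, , drop = FALSE]
}

#' Number of aberrantly methylated genes per sample
#'
#' Counts, per sample, the genes called hypermethylated; for imprinted genes
#' both aberrant directions count. With `count_hypo = TRUE` hypomethylation
#' counts for every gene.
#'
#' @param calls Call tibble from [call_cohort()].
#' @param panel Gene panel.
#' @param count_hypo Count hypomethylated non-imprinted genes too.
#' @return Tibble `sample_id`, `n_methylated`.
#' @export
methylated_gene_count <- function(calls, panel = gene_panel(),
                                  count_hypo = FALSE) {
  imprinted <- panel$gene[panel$imprinted]
  calls$.hit <- calls$state == "hyper" |
    (calls$state == "hypo" & (count_hypo | calls$gene %in% imprinted))
  dplyr::summarise(dplyr::group_by(calls, .data$sample_id),
                   n_methylated = sum(.data$.hit), .groups = "drop")
}

#' Subtract the technical background from measurements
#'
#' Optional adjustment: subtracts each gene's mean unmethylated-control
#' signal from every measurement of that gene, flooring at 0. By default
#' the pipeline records controls without subtracting them.
#'
#' @param measurements Long CpG tibble.
#' @param controls Control tibble from [read_control_table()].
#' @return Adjusted measurement tibble.
#' @export
subtract_background <- function(measurements, controls) {
  bg <- dplyr::summarise(
    dplyr::group_by(controls[controls$control_type == "unmethylated_dna", ],
                    .data$gene),
    background = mean(.data$methylation_percent, na.rm = TRUE),
    .groups = "drop"
  )
  x <- dplyr::left_join(measurements, bg, by = "gene")
  x$background[is.na(x$background)] <- 0
  x$methylation_percent <- pmax(0, x$methylation_percent - x$background)
  x$background <- NULL
  x
}

#' Write a call matrix
#'
#' Samples-by-genes overview with states encoded `H` (hyper), `N`
#' (in range), `L` (hypo) and `NA` (assay missing).
#'
#' @param calls Call tibble from [call_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(calls, path) {
  code <- c(hyper = "H", in_range = "N", hypo = "L", missing = NA_character_)
  x <- calls[, c("sample_id", "gene", "state")]
  x$state <- unname(code[x$state])
  wide <- tidyr::pivot_wider(x, names_from = "gene", values_from = "state")
  wide <- wide[order(wide$sample_id), , drop = FALSE]
  readr::write_tsv(wide, path, na = "NA")
  invisible(path)
}
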