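#' Read a qRT-PCR Ct triplicate table
#'
#' Expects columns `sample_id`, `gene`, `rep1`, `rep2`, `rep3` (cycle
#' thresholds). Replicates are aggregated by their mean, with the replicate
#' standard deviation kept for quality control.
#'
#' @inheritParams read_cpg_table
#' @return Tibble: `sample_id`, `gene`, `rep1..rep3`, `ct_mean`, `ct_sd`.
#' @export
read_ct_table <- function(path, delim = "\t") {
  x <- read_checked(path, delim,
                    cols = c(sample_id = "c", gene = "c", rep1 = "d",
                             rep2 = "d", rep3 = "d"))
  reps <- as.matrix(x[, c("rep1", "rep2", "rep3")])
  if (any(!is.na(reps) & (reps <= 0 | !is.finite(reps)))) {
    abort("Ct values must be positive and finite",
          class = "methcall_validation_error")
  }
  if (anyDuplicated(paste(x$sample_id, x$gene, sep = "\r"))) {
    abort("duplicate (sample_id, gene) in Ct table",
          class = "methcall_validation_error")
  }
  x$ct_mean <- rowMeans(reps, na.rm = TRUE)
  x$ct_sd <- apply(reps, 1L, sd, na.rm = TRUE)
  tibble::as_tibble(x)
}

#' Read a standard-curve dilution series table
#'
#' Expects columns `gene`, `quantity` (relative input amount of the dilution
#' series, any consistent units) and `ct`.
#'
#' @inheritParams read_cpg_table
#' @return Tibble: `gene`, `quantity`, `ct`.
#' @export
read_standard_table <- function(path, delim = "\t") {
  x <- read_checked(path, delim, cols = c(gene = "c", quantity = "d", ct = "d"))
  if (any(is.na(x$quantity) | x$quantity <= 0)) {
    abort("standard quantities must be positive",
          class = "methcall_validation_error")
  }
  tibble::as_tibble(x)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 input quantity over a dilution
#' series. The amplification efficiency is `10^(-1/slope) - 1`; a perfect
#' doubling per cycle gives slope -3.3219 and efficiency 1 (100%).
#'
#' @param quantity Input quantities of the dilution points (positive).
#' @param ct Measured Ct of each point.
#' @param gene Optional gene symbol carried in the result.
#' @return Object of class `standard_curve`: list with `gene`, `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n_points`.
#' @examples
#' q <- 10^seq(0, -4)
#' sc <- fit_standard_curve(q, 20 - log2(10) * log10(q))
#' sc$efficiency  # 1 (within floating point)
#' @export
fit_standard_curve <- function(quantity, ct, gene = NA_character_) {
  keep <- !is.na(quantity) & !is.na(ct)
  quantity <- quantity[keep]
  ct <- ct[keep]
  if (length(quantity) < 3L) {
    abort("a standard curve needs >= 3 dilution points",
          class = "methcall_curve_error")
  }
  if (any(quantity <= 0)) {
    abort("standard quantities must be positive",
          class = "methcall_curve_error")
  }
  lq <- log10(quantity)
  if (diff(range(lq)) < 2) {
    warn(paste0("standard curve for ", gene, " spans < 2 log10 units"))
  }
  fit <- lm(ct ~ lq)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    abort(paste0("invalid standard curve for ", gene,
                 ": slope must be negative (Ct falls with input)"),
          class = "methcall_curve_error")
  }
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(list(gene = gene, slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 n_points = length(quantity)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve %s> slope %.4f, intercept %.3f, R2 %.4f, efficiency %.1f%% (%d points)\n",
              x$gene, x$slope, x$intercept, x$r_squared,
              100 * x$efficiency, x$n_points))
  invisible(x)
}

#' Map a Ct to a relative quantity on a standard curve
#'
#' @param ct Cycle threshold(s).
#' @param curve A `standard_curve`.
#' @return Relative quantity `10^((ct - intercept) / slope)`, strictly
#'   decreasing in Ct.
#' @export
quantity_from_ct <- function(ct, curve) {
  if (!inherits(curve, "standard_curve") || curve$slope >= 0) {
    abort("need a valid standard_curve with negative slope",
          class = "methcall_curve_error")
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Relative expression by the standard-curve method
#'
#' For each sample, interpolates the target and reference Ct means on their
#' per-gene standard curves and reports the ratio of quantities
#' (target / reference). Samples with a replicate SD above `sd_threshold`
#' cycles on either gene are flagged (`qc_flag`), not removed.
#'
#' @param ct_table Ct tibble from [read_ct_table()] (or with `ct_mean`,
#'   `ct_sd` columns).
#' @param curves Named list of `standard_curve` objects, one per gene.
#' @param target,reference Gene symbols of the target and the normalisation
#'   reference.
#' @param sd_threshold Replicate-SD QC threshold in cycles (default 0.5).
#' @return Tibble: `sample_id`, `target_ct`, `reference_ct`,
#'   `target_quantity`, `reference_quantity`, `relative_level`, `qc_flag`.
#' @export
relative_expression <- function(ct_table, curves, target, reference,
                                sd_threshold = 0.5) {
  for (g in c(target, reference)) {
    if (is.null(curves[[g]])) {
      abort(paste0("no standard curve for ", g),
            class = "methcall_curve_error")
    }
  }
  t_rows <- ct_table[ct_table$gene == target, ]
  r_rows <- ct_table[ct_table$gene == reference, ]
  x <- dplyr::inner_join(
    t_rows[, c("sample_id", "ct_mean", "ct_sd")],
    r_rows[, c("sample_id", "ct_mean", "ct_sd")],
    by = "sample_id", suffix = c("_target", "_reference")
  )
  only_target <- setdiff(t_rows$sample_id, r_rows$sample_id)
  if (length(only_target)) {
    abort(paste0("missing reference (", reference, ") measurement for: ",
                 paste(head(only_target, 10L), collapse = ", ")),
          class = "methcall_validation_error")
  }
  tibble::tibble(
    sample_id = x$sample_id,
    target_ct = x$ct_mean_target,
    reference_ct = x$ct_mean_reference,
    target_quantity = quantity_from_ct(x$ct_mean_target, curves[[target]]),
    reference_quantity = quantity_from_ct(x$ct_mean_reference,
                                          curves[[reference]]),
    relative_level = quantity_from_ct(x$ct_mean_target, curves[[target]]) /
      quantity_from_ct(x$ct_mean_reference, curves[[reference]]),
    qc_flag = (!is.na(x$ct_sd_target) & x$ct_sd_target > sd_threshold) |
      (!is.na(x$ct_sd_reference) & x$ct_sd_reference > sd_threshold)
  )
}

#' Compare expression across normal / methylated / unmethylated groups
#'
#' Joins relative expression to methylation calls and diagnosis, splits the
#' samples into normal tissue, tumours called hypermethylated for `gene`,
#' and tumours not called hypermethylated, then runs pairwise permutation
#' Mann-Whitney tests on the relative expression levels and reports group
#' medians.
#'
#' @param expression Tibble from [relative_expression()].
#' @param calls Call tibble from [call_cohort()].
#' @param metadata Sample metadata.
#' @param gene Gene whose methylation call defines the tumour split.
#' @inheritParams association_screen
#' @return List with `groups` (per-sample group assignment), `medians`
#'   (per group: n and median relative level) and `tests` (pairwise results
#'   with BH q-values).
#' @export
expression_by_methylation_group <- function(expression, calls, metadata,
                                            gene, n_perm = 1e5, seed = 1,
                                            exact_cap = 10000) {
  gcalls <- calls[calls$gene == gene, c("sample_id", "state")]
  x <- dplyr::left_join(expression, metadata[, c("sample_id", "diagnosis")],
                        by = "sample_id")
  x <- dplyr::left_join(x, gcalls, by = "sample_id")
  grp <- rep(NA_character_, nrow(x))
  grp[x$diagnosis == "normal"] <- "normal"
  grp[x$diagnosis != "normal" & x$state == "hyper"] <- "methylated"
  grp[x$diagnosis != "normal" & !is.na(x$state) &
        x$state %in% c("in_range", "hypo")] <- "unmethylated"
  x$group <- grp
  x <- x[!is.na(x$group), , drop = FALSE]
  medians <- dplyr::summarise(
    dplyr::group_by(x, .data$group),
    n = dplyr::n(),
    median_relative_level = median(.data$relative_level),
    .groups = "drop"
  )
  prs <- combn(intersect(c("normal", "methylated", "unmethylated"),
                         unique(x$group)), 2L, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    va <- x$relative_level[x$group == pr[1]]
    vb <- x$relative_level[x$group == pr[2]]
    s <- derive_seed(seed, paste0("expr:", gene, ":", pr[1], ":", pr[2]))
    res <- tryCatch(
      mann_whitney_perm(va, vb, n_perm = n_perm, seed = s,
                        exact_cap = exact_cap),
      methcall_untestable_error = function(e) NULL
    )
    tibble::tibble(
      gene = gene, group_a = pr[1], group_b = pr[2],
      n_a = length(va), n_b = length(vb),
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p_perm = if (is.null(res)) NA_real_ else res$p_perm,
      n_perm = if (is.null(res)) NA_integer_ else res$n_perm,
      exact = if (is.null(res)) NA else res$exact
    )
  })
  tests <- dplyr::bind_rows(rows)
  tests$q_value <- bh_adjust(tests$p_perm)
  list(groups = x[, c("sample_id", "group", "relative_level")],
       medians = medians, tests = tests)
}
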