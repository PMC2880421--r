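#' Screen gene methylation levels against clinicopathological factors
#'
#' For every gene and factor, tests whether gene-level average methylation
#' differs across factor levels: permutation Mann-Whitney for two-level
#' factors (ER, PR, TP53, Ki-67) and permutation Kruskal-Wallis for the
#' three-level grade. All tumour diagnosis groups are combined; samples with
#' an `unknown` factor level are dropped per test, not imputed. q-values are
#' Benjamini-Hochberg adjusted over the family of all tests the screen could
#' run (untestable gene-factor cells are reported with missing p and are not
#' part of the family).
#'
#' @param averages Gene-level averages from [gene_sample_averages()].
#' @param metadata Sample metadata.
#' @param factors Named list mapping factor column to its levels; defaults
#'   to [factor_levels()].
#' @param n_perm Sampled permutations per test (exact enumeration is used
#'   automatically for small groups).
#' @param seed Root seed; each test's seed is derived from it and the test
#'   label via [derive_seed()].
#' @param exact_cap Passed to the permutation tests.
#' @param alpha FDR level defining the `significant` flag (default 0.05).
#' @return Tibble with one row per gene and factor: statistic, `p_perm`,
#'   `n_perm`, `exact`, `seed`, `q_value`, `significant`.
#' @export
association_screen <- function(averages, metadata, factors = factor_levels(),
                               n_perm = 1e5, seed = 1, exact_cap = 10000,
                               alpha = 0.05) {
  tum <- metadata[metadata$diagnosis != "normal", , drop = FALSE]
  x <- dplyr::inner_join(averages, tum, by = "sample_id")
  genes <- sort(unique(x$gene))
  rows <- list()
  for (g in genes) {
    xg <- x[x$gene == g & !is.na(x$avg_methylation), , drop = FALSE]
    for (f in names(factors)) {
      lv <- factors[[f]]
      v <- xg$avg_methylation[xg[[f]] %in% lv]
      grp <- xg[[f]][xg[[f]] %in% lv]
      res <- run_guarded(g, f, function() {
        s <- derive_seed(seed, paste0(g, ":", f))
        if (length(lv) == 2L) {
          mann_whitney_perm(v[grp == lv[1]], v[grp == lv[2]],
                            n_perm = n_perm, seed = s, exact_cap = exact_cap)
        } else {
          kruskal_wallis_perm(v, grp, n_perm = n_perm, seed = s,
                              exact_cap = exact_cap)
        }
      })
      rows[[paste0(g, ":", f)]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$p_perm)
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  out
}

# Run one screen test, converting an untestable cell into an NA row instead
# of aborting the whole screen.
run_guarded <- function(gene, factor_name, fn) {
  res <- tryCatch(fn(), methcall_untestable_error = function(e) NULL)
  if (is.null(res)) {
    return(tibble::tibble(gene = gene, factor = factor_name,
                          statistic_kind = NA_character_,
                          statistic = NA_real_, p_perm = NA_real_,
                          n_perm = NA_integer_, exact = NA, seed = NA_integer_))
  }
  tibble::tibble(gene = gene, factor = factor_name,
                 statistic_kind = res$statistic_kind,
                 statistic = res$statistic, p_perm = res$p_perm,
                 n_perm = res$n_perm, exact = res$exact, seed = res$seed)
}

#' Pairwise diagnosis-group comparisons of methylation level for one gene
#'
#' Permutation Mann-Whitney tests of gene-level average methylation between
#' pairs of diagnosis groups (normal, DCIS, invasive, mixed), the per-gene
#' level comparison behind "does methylation level rise with progression".
#'
#' @inheritParams association_screen
#' @param gene Gene symbol to compare.
#' @param pairs List of 2-element character vectors; defaults to all pairs
#'   of diagnosis groups present in the data for this gene.
#' @return Tibble with one row per pair: `group_a`, `group_b`, medians,
#'   statistic, `p_perm`, `q_value` over the requested pairs.
#' @export
diagnosis_level_comparison <- function(averages, metadata, gene,
                                       pairs = NULL, n_perm = 1e5, seed = 1,
                                       exact_cap = 10000) {
  x <- dplyr::inner_join(averages[averages$gene == gene, ], metadata,
                         by = "sample_id")
  x <- x[!is.na(x$avg_methylation), , drop = FALSE]
  present <- intersect(diagnosis_levels(), unique(x$diagnosis))
  if (is.null(pairs)) {
    pairs <- combn(present, 2L, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    va <- x$avg_methylation[x$diagnosis == pr[1]]
    vb <- x$avg_methylation[x$diagnosis == pr[2]]
    s <- derive_seed(seed, paste0(gene, ":", pr[1], ":", pr[2]))
    res <- tryCatch(
      mann_whitney_perm(va, vb, n_perm = n_perm, seed = s,
                        exact_cap = exact_cap),
      methcall_untestable_error = function(e) NULL
    )
    tibble::tibble(
      gene = gene, group_a = pr[1], group_b = pr[2],
      n_a = length(va), n_b = length(vb),
      median_a = if (length(va)) median(va) else NA_real_,
      median_b = if (length(vb)) median(vb) else NA_real_,
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p_perm = if (is.null(res)) NA_real_ else res$p_perm,
      n_perm = if (is.null(res)) NA_integer_ else res$n_perm,
      exact = if (is.null(res)) NA else res$exact
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$p_perm)
  out
}

#' Co-methylation between gene pairs
#'
#' Permutation Spearman correlation of gene-level average methylation for
#' every pair of panel genes, over the samples with both genes measured.
#' Reports rho and rho squared, with BH adjustment over all pairs.
#'
#' @inheritParams association_screen
#' @param genes Genes to correlate; defaults to all genes present.
#' @return Tibble with one row per unordered pair: `gene_a`, `gene_b`, `n`,
#'   `rho`, `rho_squared`, `p_perm`, `q_value`.
#' @export
comethylation <- function(averages, genes = NULL, n_perm = 1e5, seed = 1) {
  if (is.null(genes)) genes <- sort(unique(averages$gene))
  wide <- tidyr::pivot_wider(
    averages[averages$gene %in% genes, c("sample_id", "gene", "avg_methylation")],
    names_from = "gene", values_from = "avg_methylation"
  )
  prs <- combn(sort(intersect(genes, names(wide))), 2L, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    xa <- wide[[pr[1]]]
    xb <- wide[[pr[2]]]
    s <- derive_seed(seed, paste0(pr[1], ":", pr[2]))
    res <- tryCatch(
      spearman_perm(xa, xb, n_perm = n_perm, seed = s),
      methcall_untestable_error = function(e) NULL
    )
    tibble::tibble(
      gene_a = pr[1], gene_b = pr[2],
      n = sum(!is.na(xa) & !is.na(xb)),
      rho = if (is.null(res)) NA_real_ else res$rho,
      rho_squared = if (is.null(res)) NA_real_ else res$rho_squared,
      p_perm = if (is.null(res)) NA_real_ else res$p_perm,
      n_perm = if (is.null(res)) NA_integer_ else res$n_perm
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$p_perm)
  out
}
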