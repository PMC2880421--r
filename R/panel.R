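#' The candidate gene panel
#'
#' A gene panel is an ordered table of gene symbols with an `imprinted` flag.
#' Imprinted genes (here *IGF2*) carry allele-specific methylation in normal
#' tissue, so deviations in either direction are aberrant and default reports
#' show both hyper- and hypomethylation for them; non-imprinted genes are
#' reported as hypermethylated only.
#'
#' The default panel is the eleven-gene breast cancer progression panel:
#' ABCB1, CDKN2A, ESR1, FOXC1, GSTP1, IGF2, MGMT, MLH1, PPP2R2B, PTEN,
#' RASSF1A, with IGF2 the single imprinted member.
#'
#' @param genes Character vector of unique gene symbols.
#' @param imprinted Logical vector the same length as `genes`.
#' @return A tibble with columns `gene` and `imprinted`.
#' @examples
#' gene_panel()
#' gene_panel(c("GENE1", "GENE2"), imprinted = c(FALSE, TRUE))
#' @export
gene_panel <- function(genes = NULL, imprinted = NULL) {
  if (is.null(genes)) {
    genes <- c("ABCB1", "CDKN2A", "ESR1", "FOXC1", "GSTP1", "IGF2",
               "MGMT", "MLH1", "PPP2R2B", "PTEN", "RASSF1A")
    imprinted <- genes == "IGF2"
  }
  if (is.null(imprinted)) imprinted <- rep(FALSE, length(genes))
  if (anyDuplicated(genes)) {
    abort("gene symbols in a panel must be unique",
          class = "methcall_validation_error")
  }
  if (length(imprinted) != length(genes) || !is.logical(imprinted)) {
    abort("`imprinted` must be a logical vector matching `genes`",
          class = "methcall_validation_error")
  }
  tibble::tibble(gene = as.character(genes), imprinted = imprinted)
}

#' Factor levels used by clinicopathological screens
#'
#' Declares the levels of each metadata factor: two-level factors are tested
#' with Mann-Whitney, the three-level grade with Kruskal-Wallis. `unknown`
#' is always accepted in metadata and dropped per test.
#'
#' @return Named list mapping factor column name to its non-missing levels.
#' @export
factor_levels <- function() {
  list(
    er    = c("positive", "negative"),
    pr    = c("positive", "negative"),
    tp53  = c("wildtype", "mutant"),
    ki67  = c("positive", "negative"),
    grade = c("A_I", "B_II", "C_III")
  )
}

diagnosis_levels <- function() c("normal", "DCIS", "invasive", "mixed")
tumour_groups    <- function() c("DCIS", "invasive", "mixed")
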