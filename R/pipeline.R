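#' Build a pipeline run configuration
#'
#' A run is driven by one configuration object: either paths to input tables
#' (`inputs`) or a simulation config (`simulate`), plus the calling and
#' statistics options. Constants mirror the analysis defaults: SD multiplier
#' 2 and FDR level 0.05.
#'
#' @param inputs Named list of paths: `cpg`, `metadata`, optional
#'   `controls`, `ct`, `standards`. Ignored when `simulate` is given.
#' @param simulate Optional `simulation_config`; the cohort (and expression
#'   data) are generated instead of read.
#' @param panel Gene panel.
#' @param seed Root seed for every permutation stream.
#' @param n_perm Sampled permutations per test.
#' @param alpha FDR significance level.
#' @param k SD multiplier of the calling rule.
#' @param sd_denominator `"n-1"` or `"n"` for the reference SD.
#' @param exact_cap Exact-enumeration cap of the permutation tests.
#' @param subtract_background Subtract the unmethylated-control mean per
#'   gene before averaging (off by default; controls are reported either
#'   way).
#' @param expression_target,expression_reference Target and reference gene
#'   of the expression comparison (defaults follow the simulation config
#'   when simulating).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            panel = gene_panel(), seed = 1, n_perm = 1e5,
                            alpha = 0.05, k = 2,
                            sd_denominator = c("n-1", "n"),
                            exact_cap = 10000, subtract_background = FALSE,
                            expression_target = NULL,
                            expression_reference = NULL) {
  sd_denominator <- match.arg(sd_denominator)
  if (is.null(inputs) && is.null(simulate)) {
    abort("either `inputs` or `simulate` must be given",
          class = "methcall_config_error")
  }
  stopifnot(k > 0, alpha > 0, alpha < 1)
  if (!is.null(simulate)) {
    validate_simulation_config(simulate)
    if (is.null(expression_target)) expression_target <- simulate$expression$target
    if (is.null(expression_reference)) {
      expression_reference <- simulate$expression$reference
    }
  }
  if (is.null(expression_target)) expression_target <- "FOXC1"
  if (is.null(expression_reference)) expression_reference <- "PGK1"
  structure(list(inputs = inputs, simulate = simulate, panel = panel,
                 seed = as.integer(seed), n_perm = n_perm, alpha = alpha,
                 k = k, sd_denominator = sd_denominator,
                 exact_cap = exact_cap,
                 subtract_background = subtract_background,
                 expression_target = expression_target,
                 expression_reference = expression_reference),
            class = "run_config")
}

config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                     digits = 15, force = TRUE, null = "null"))
  sprintf("%08x", string_hash31(s))
}

#' Run the end-to-end methylation analysis
#'
#' Executes every stage on one cohort and writes the report bundle to
#' `out_dir`: `frequency_table.tsv`, `call_matrix.tsv`,
#' `diagnosis_comparisons.tsv`, `comethylation.tsv`,
#' `association_screen.tsv`, `expression_comparison.tsv` (when expression
#' inputs are present) and a machine-readable `manifest.json` recording the
#' package version, seed and a config hash. Deterministic given config +
#' seed: two runs produce byte-identical bundles. Any stage error aborts
#' with the stage named and removes files already written.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and the file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path, na = "NA")
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "methcall_stage_error")
    })
  }

  panel <- config$panel
  has_expression <- FALSE
  ct_table <- standards <- NULL
  cohort <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate)
      if (!is.null(config$expression_target)) {
        ex <- simulate_expression(config$simulate, sim$metadata)
        ct_table <- ex$ct_table
        standards <- ex$standards
        has_expression <- TRUE
      }
      join_cohort(sim$measurements, sim$metadata, panel)
    } else {
      meas <- read_cpg_table(config$inputs$cpg, panel)
      meta <- read_metadata(config$inputs$metadata)
      if (!is.null(config$inputs$controls) && config$subtract_background) {
        ctrl <- read_control_table(config$inputs$controls, panel)
        meas <- subtract_background(meas, ctrl)
      }
      if (!is.null(config$inputs$ct) && !is.null(config$inputs$standards)) {
        ct_table <- read_ct_table(config$inputs$ct)
        standards <- read_standard_table(config$inputs$standards)
        has_expression <- TRUE
      }
      join_cohort(meas, meta, panel)
    }
  })

  calls <- NULL
  freq <- NULL
  stage("calling", {
    refs <- fit_normal_references(cohort, k = config$k,
                                  sd_denominator = config$sd_denominator)
    calls <- call_cohort(cohort, refs)
    freq <- frequency_table(calls, cohort$metadata)
    emit(freq, "frequency_table.tsv")
    matrix_path <- file.path(out_dir, "call_matrix.tsv")
    write_call_matrix(calls, matrix_path)
    written <- c(written, matrix_path)
  })

  averages <- gene_sample_averages(cohort)
  diag_cmp <- stage("diagnosis_comparisons", {
    out <- dplyr::bind_rows(lapply(sort(unique(calls$gene)), function(g) {
      diagnosis_level_comparison(averages, cohort$metadata, g,
                                 n_perm = config$n_perm, seed = config$seed,
                                 exact_cap = config$exact_cap)
    }))
    emit(out, "diagnosis_comparisons.tsv")
    out
  })

  cometh <- stage("comethylation", {
    tum <- cohort$metadata$sample_id[cohort$metadata$diagnosis != "normal"]
    out <- comethylation(averages[averages$sample_id %in% tum, ],
                         n_perm = config$n_perm, seed = config$seed)
    emit(out, "comethylation.tsv")
    out
  })

  screen <- stage("association_screen", {
    out <- association_screen(averages, cohort$metadata,
                              n_perm = config$n_perm, seed = config$seed,
                              exact_cap = config$exact_cap,
                              alpha = config$alpha)
    emit(out, "association_screen.tsv")
    out
  })

  expr_cmp <- NULL
  if (has_expression) {
    expr_cmp <- stage("expression", {
      curves <- lapply(split(standards, standards$gene), function(s) {
        fit_standard_curve(s$quantity, s$ct, gene = s$gene[1])
      })
      rel <- relative_expression(ct_table, curves,
                                 target = config$expression_target,
                                 reference = config$expression_reference)
      cmp <- expression_by_methylation_group(
        rel, calls, cohort$metadata, gene = config$expression_target,
        n_perm = config$n_perm, seed = config$seed,
        exact_cap = config$exact_cap
      )
      emit(cmp$tests, "expression_comparison.tsv")
      cmp
    })
  }

  manifest <- list(
    package = "methcall",
    version = as.character(utils::packageVersion("methcall")),
    seed = config$seed,
    n_perm = config$n_perm,
    alpha = config$alpha,
    config_hash = config_hash(config),
    files = basename(written)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(cohort = cohort, calls = calls, frequency = freq,
                 diagnosis_comparisons = diag_cmp, comethylation = cometh,
                 association_screen = screen, expression = expr_cmp,
                 files = c(written, manifest_path), out_dir = out_dir))
}

#' Summarise a report bundle
#'
#' Regenerates a per-gene one-line summary from the files of a completed
#' run: hypermethylation frequency per diagnosis group and the factors
#' significantly associated at the run's FDR level.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Character vector of summary lines (one per gene, plus a header),
#'   printed when called interactively.
#' @export
summarize_run <- function(out_dir) {
  freq <- readr::read_tsv(file.path(out_dir, "frequency_table.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  screen <- readr::read_tsv(file.path(out_dir, "association_screen.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  genes <- sort(unique(freq$gene))
  lines <- vapply(genes, function(g) {
    f <- freq[freq$gene == g & freq$state == "hyper", ]
    f <- f[match(tumour_groups(), f$group), ]
    sig <- screen$factor[screen$gene == g & !is.na(screen$significant) &
                           screen$significant]
    paste0(g, ": hyper ",
           paste(sprintf("%s %.1f%% (n=%d)", f$group, f$frequency,
                         f$n_valid), collapse = ", "),
           if (length(sig)) paste0("; associated with: ",
                                   paste(sig, collapse = ", "))
           else "; no significant factor associations")
  }, character(1))
  c(paste0("Summary of ", length(genes), " genes"), unname(lines))
}
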