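#' Default synthetic-cohort configuration
#'
#' Builds the configuration of the synthetic breast-lesion cohort generator.
#' Group sizes default to 27 DCIS, 28 invasive, 34 mixed tumours and 28
#' normal tissues; most genes are calibrated against 5 normals, with
#' FOXC1, ABCB1, PPP2R2B and PTEN measured in all 28 (the remaining normals
#' carry no assay for the other genes). Gene-level methylation follows a
#' two-component latent model: a tightly low unmethylated baseline
#' (means 6-8%, SD 1.5-2.5%) plus a hypermethylated subpopulation shifted by
#' +30 to +40 points, with per-gene hyper fractions per diagnosis group
#' chosen to emulate the qualitative published pattern (RASSF1A-like high
#' everywhere, FOXC1-like rising from DCIS to invasive, CDKN2A-like near
#' zero). The imprinted IGF2 sits at a 50% baseline with both hyper- and
#' hypomethylated subpopulations. Per-CpG values add Gaussian jitter and are
#' clipped to \[0, 100\]; missingness drops whole assays (all CpGs of a gene
#' for a sample), the way pyrosequencing assays fail.
#'
#' `factor_effects` is empty by default (clinicopathological factors carry
#' no programmed methylation signal); screen power tests inject effects
#' explicitly.
#'
#' @param seed Integer seed stored in the config; all generator randomness
#'   derives from it.
#' @param group_sizes Named integer vector with entries `normal`, `DCIS`,
#'   `invasive`, `mixed`.
#' @return A `simulation_config` list.
#' @export
default_simulation_config <- function(seed = 1,
                                      group_sizes = c(normal = 28, DCIS = 27,
                                                      invasive = 28,
                                                      mixed = 34)) {
  gene_model <- function(baseline_mean, baseline_sd, n_cpgs, hyper_shift,
                         hyper_fraction, hypo_shift = 0,
                         hypo_fraction = c(DCIS = 0, invasive = 0, mixed = 0),
                         cpg_jitter_sd = 1.5, missing_rate = 0.03,
                         normals_measured = 5L) {
    list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         n_cpgs = n_cpgs, cpg_jitter_sd = cpg_jitter_sd,
         hyper_shift = hyper_shift, hypo_shift = hypo_shift,
         hyper_fraction = hyper_fraction, hypo_fraction = hypo_fraction,
         missing_rate = missing_rate, normals_measured = normals_measured)
  }
  hf <- function(d, i, m) c(DCIS = d, invasive = i, mixed = m)
  genes <- list(
    ABCB1   = gene_model(6, 2.0, 5, 30, hf(0.41, 0.39, 0.44),
                         normals_measured = 28L),
    CDKN2A  = gene_model(6, 1.5, 7, 35, hf(0.00, 0.107, 0.059)),
    ESR1    = gene_model(7, 2.0, 5, 30, hf(0, 0, 0)),
    FOXC1   = gene_model(6, 1.5, 8, 35, hf(0.222, 0.536, 0.676),
                         normals_measured = 28L),
    GSTP1   = gene_model(6, 1.5, 5, 40, hf(0.222, 0.143, 0.265)),
    IGF2    = gene_model(50, 4.0, 4, 25, hf(0.037, 0.107, 0.294),
                         hypo_shift = -30,
                         hypo_fraction = hf(0.370, 0.393, 0.147)),
    MGMT    = gene_model(6, 2.0, 6, 30, hf(0.037, 0.036, 0.059)),
    MLH1    = gene_model(6, 1.5, 5, 30, hf(0.074, 0.036, 0.029)),
    PPP2R2B = gene_model(7, 2.0, 6, 35, hf(0.55, 0.786, 0.706),
                         missing_rate = 0.15, normals_measured = 28L),
    PTEN    = gene_model(7, 2.0, 4, 30, hf(0.185, 0.143, 0.235),
                         normals_measured = 28L),
    RASSF1A = gene_model(8, 2.5, 7, 40, hf(0.852, 0.821, 0.853))
  )
  factors <- list(
    er    = list(levels = c("positive", "negative", "unknown"),
                 prob = c(0.74, 0.23, 0.03)),
    pr    = list(levels = c("positive", "negative", "unknown"),
                 prob = c(0.69, 0.28, 0.03)),
    tp53  = list(levels = c("wildtype", "mutant", "unknown"),
                 prob = c(0.78, 0.19, 0.03)),
    ki67  = list(levels = c("positive", "negative", "unknown"),
                 prob = c(0.29, 0.70, 0.01)),
    grade = list(levels = c("A_I", "B_II", "C_III", "unknown"),
                 prob = c(0.25, 0.40, 0.33, 0.02))
  )
  expression <- list(
    target = "FOXC1", reference = "PGK1",
    diagnoses = c("normal", "DCIS", "invasive"),
    normal_quantity = 1.0, tumour_multiplier = 0.5,
    log2_sd = 0.75, reference_log2_sd = 0.25, ct_noise_sd = 0.1,
    standards_quantities = 10^seq(0, -4),
    curves = list(FOXC1 = list(slope = -3.3219, intercept = 36),
                  PGK1 = list(slope = -3.3219, intercept = 30))
  )
  cfg <- list(seed = as.integer(seed), group_sizes = group_sizes,
              genes = genes, factors = factors,
              factor_effects = list(), expression = expression)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks sizes, fractions, probabilities and per-gene model fields before
#' any output is generated.
#'
#' @param config A `simulation_config` list.
#' @return The config, invisibly usable, or an error.
#' @export
validate_simulation_config <- function(config) {
  gs <- config$group_sizes
  if (!all(c("normal", "DCIS", "invasive", "mixed") %in% names(gs)) ||
      any(gs < 0)) {
    abort("group_sizes must name normal/DCIS/invasive/mixed, all >= 0",
          class = "methcall_config_error")
  }
  for (g in names(config$genes)) {
    m <- config$genes[[g]]
    hf <- m$hyper_fraction[tumour_groups()]
    lf <- m$hypo_fraction[tumour_groups()]
    if (anyNA(hf) || anyNA(lf)) {
      abort(paste0("hyper/hypo fractions for ", g,
                   " must be named for DCIS, invasive and mixed"),
            class = "methcall_config_error")
    }
    if (any(hf < 0 | hf > 1) || any(lf < 0 | lf > 1) || any(hf + lf > 1)) {
      abort(paste0("fractions for ", g, " must lie in [0,1] with ",
                   "hyper + hypo <= 1"),
            class = "methcall_config_error")
    }
    if (m$missing_rate < 0 || m$missing_rate > 1 || m$n_cpgs < 1 ||
        m$baseline_sd < 0 || m$cpg_jitter_sd < 0) {
      abort(paste0("invalid model fields for ", g),
            class = "methcall_config_error")
    }
  }
  for (f in names(config$factors)) {
    p <- config$factors[[f]]$prob
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      abort(paste0("level probabilities for ", f, " must sum to 1"),
            class = "methcall_config_error")
    }
  }
  for (eff in config$factor_effects) {
    if (!all(c("factor", "level", "genes", "shift") %in% names(eff)) ||
        !eff$factor %in% names(config$factors)) {
      abort("each factor effect needs factor/level/genes/shift",
            class = "methcall_config_error")
    }
  }
  invisible(config)
}

#' Simulate a methylation cohort
#'
#' Draws metadata, per-sample latent gene methylation from the
#' two-component model, per-CpG measurements with jitter, and returns the
#' ground truth alongside. Fully deterministic given `config$seed`: the same
#' config yields byte-identical tables.
#'
#' @param config A `simulation_config` (see [default_simulation_config()]).
#' @return List with `measurements` (long CpG tibble), `metadata`, `truth`
#'   (one row per sample x gene: `component` = baseline/hyper/hypo and the
#'   latent value before jitter and clipping), and `clipped_fraction` (share
#'   of emitted CpG values clipped into \[0, 100\]).
#' @examples
#' sim <- simulate_cohort(default_simulation_config(seed = 42))
#' dplyr::count(sim$metadata, diagnosis)
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  gs <- config$group_sizes[c("normal", "DCIS", "invasive", "mixed")]
  n_total <- sum(gs)
  diagnosis <- rep(names(gs), times = gs)
  sample_id <- sprintf("%s%03d",
                       c(normal = "N", DCIS = "D", invasive = "I",
                         mixed = "M")[diagnosis],
                       unlist(lapply(gs, seq_len)))
  metadata <- tibble::tibble(sample_id = sample_id, diagnosis = diagnosis)
  is_tumour <- diagnosis != "normal"
  for (f in names(config$factors)) {
    spec <- config$factors[[f]]
    v <- rep("unknown", n_total)
    v[is_tumour] <- sample(spec$levels, sum(is_tumour), replace = TRUE,
                           prob = spec$prob)
    metadata[[f]] <- v
  }
  metadata$grade[!is_tumour] <- "unknown"

  genes <- names(config$genes)
  normal_ids <- metadata$sample_id[!is_tumour]
  truth_rows <- vector("list", length(genes))
  meas_rows <- vector("list", length(genes))
  clipped <- 0L
  emitted <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    m <- config$genes[[g]]
    # Latent component per sample: normals are always baseline.
    comp <- rep("baseline", n_total)
    for (grp in tumour_groups()) {
      idx <- which(diagnosis == grp)
      u <- runif(length(idx))
      comp[idx][u < m$hyper_fraction[[grp]]] <- "hyper"
      comp[idx][u >= m$hyper_fraction[[grp]] &
                  u < m$hyper_fraction[[grp]] + m$hypo_fraction[[grp]]] <- "hypo"
    }
    shift <- c(baseline = 0, hyper = m$hyper_shift, hypo = m$hypo_shift)[comp]
    latent_mean <- m$baseline_mean + shift
    for (eff in config$factor_effects) {
      if (g %in% eff$genes) {
        latent_mean <- latent_mean +
          ifelse(metadata[[eff$factor]] == eff$level, eff$shift, 0)
      }
    }
    latent <- rnorm(n_total, latent_mean, m$baseline_sd)
    truth_rows[[gi]] <- tibble::tibble(sample_id = metadata$sample_id,
                                       gene = g, component = comp,
                                       latent = latent)
    # Which samples carry a measured assay for this gene: the first
    # `normals_measured` normals, and tumours minus whole-assay failures.
    measured_normals <- head(normal_ids, m$normals_measured)
    tum_ids <- metadata$sample_id[is_tumour]
    failed <- runif(length(tum_ids)) < m$missing_rate
    measured <- c(measured_normals, tum_ids[!failed])
    keep <- metadata$sample_id %in% measured
    n_meas <- sum(keep)
    vals <- rep(latent[keep], each = m$n_cpgs) +
      rnorm(n_meas * m$n_cpgs, 0, m$cpg_jitter_sd)
    clipped <- clipped + sum(vals < 0 | vals > 100)
    emitted <- emitted + length(vals)
    vals <- pmin(100, pmax(0, vals))
    meas_rows[[gi]] <- tibble::tibble(
      sample_id = rep(metadata$sample_id[keep], each = m$n_cpgs),
      gene = g,
      cpg_index = rep(seq_len(m$n_cpgs), times = n_meas),
      methylation_percent = vals
    )
  }
  list(
    measurements = dplyr::bind_rows(meas_rows),
    metadata = metadata,
    truth = dplyr::bind_rows(truth_rows),
    clipped_fraction = if (emitted) clipped / emitted else 0
  )
}

#' Simulate qRT-PCR expression data for a cohort
#'
#' Generates Ct triplicates for the target and reference genes of the
#' samples in the configured expression diagnoses, plus standard-curve
#' dilution series for both genes. Normal tissue is given higher target
#' expression than tumours irrespective of each tumour's methylation call,
#' reproducing the observed early-silencing pattern. Randomness derives a
#' dedicated seed from `config$seed`, so cohort and expression draws never
#' interleave.
#'
#' @param config A `simulation_config`.
#' @param metadata Cohort metadata from [simulate_cohort()].
#' @return List with `ct_table` (sample_id, gene, rep1..rep3, ct_mean,
#'   ct_sd), `standards` (gene, quantity, ct) and `expression_truth`
#'   (programmed relative level per sample).
#' @export
simulate_expression <- function(config, metadata) {
  e <- config$expression
  set.seed(derive_seed(config$seed, "expression"))
  keep <- metadata$diagnosis %in% e$diagnoses
  ids <- metadata$sample_id[keep]
  diag <- metadata$diagnosis[keep]
  n <- length(ids)
  base_q <- e$normal_quantity *
    ifelse(diag == "normal", 1, e$tumour_multiplier)
  target_q <- base_q * 2^rnorm(n, 0, e$log2_sd)
  ref_q <- 2^rnorm(n, 0, e$reference_log2_sd)
  ct_of <- function(q, gene) {
    cv <- e$curves[[gene]]
    cv$intercept + cv$slope * log10(q)
  }
  make_rows <- function(gene, q) {
    ct0 <- ct_of(q, gene)
    reps <- matrix(rnorm(3L * n, 0, e$ct_noise_sd), ncol = 3L) + ct0
    tibble::tibble(sample_id = ids, gene = gene,
                   rep1 = reps[, 1], rep2 = reps[, 2], rep3 = reps[, 3],
                   ct_mean = rowMeans(reps),
                   ct_sd = apply(reps, 1L, sd))
  }
  ct_table <- dplyr::bind_rows(make_rows(e$target, target_q),
                               make_rows(e$reference, ref_q))
  standards <- dplyr::bind_rows(lapply(c(e$target, e$reference), function(g) {
    q <- e$standards_quantities
    tibble::tibble(gene = g, quantity = q,
                   ct = ct_of(q, g) + rnorm(length(q), 0, e$ct_noise_sd))
  }))
  list(ct_table = ct_table, standards = standards,
       expression_truth = tibble::tibble(sample_id = ids, diagnosis = diag,
                                         relative_level = target_q / ref_q))
}

#' Write / read the simulation ground truth
#'
#' The truth table (one row per sample x gene with the latent component)
#' is the oracle for calling-accuracy tests; missingness affects
#' measurements, never the truth.
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param path TSV path.
#' @return `path` invisibly (write) or the truth tibble (read).
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(truth[, c("sample_id", "gene", "component", "latent")],
                   path, na = "NA")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read_checked(path, "\t", cols = c(sample_id = "c", gene = "c",
                                    component = "c", latent = "d"))
}

#' Write / read a simulation config as YAML
#'
#' @param config A `simulation_config`.
#' @param path YAML path.
#' @return `path` invisibly (write); a validated `simulation_config` (read).
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  x$group_sizes <- as.list(x$group_sizes)
  x$genes <- lapply(x$genes, function(m) {
    m$hyper_fraction <- as.list(m$hyper_fraction)
    m$hypo_fraction <- as.list(m$hypo_fraction)
    m
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$group_sizes <- unlist(x$group_sizes)
  x$genes <- lapply(x$genes, function(m) {
    m$hyper_fraction <- unlist(m$hyper_fraction)
    m$hypo_fraction <- unlist(m$hypo_fraction)
    m$normals_measured <- as.integer(m$normals_measured)
    m$n_cpgs <- as.integer(m$n_cpgs)
    m
  })
  x$seed <- as.integer(x$seed)
  x$expression$standards_quantities <- unlist(x$expression$standards_quantities)
  if (is.null(x$factor_effects)) x$factor_effects <- list()
  class(x) <- "simulation_config"
  validate_simulation_config(x)
}
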