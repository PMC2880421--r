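test_that("gene-level averaging skips missing CpGs and records the count", {
  expect_equal(average_methylation(c(10, 20, 30)),
               list(avg_methylation = 20, n_cpgs_used = 3L))
  expect_equal(average_methylation(5.0),
               list(avg_methylation = 5, n_cpgs_used = 1L))
  expect_equal(average_methylation(c(10, NA, 30)),
               list(avg_methylation = 20, n_cpgs_used = 2L))
  expect_equal(average_methylation(c(NA_real_, NA_real_)),
               list(avg_methylation = NA_real_, n_cpgs_used = 0L))

  avg <- gene_sample_averages(tiny_cohort())
  t3 <- avg[avg$sample_id == "T3", ]
  expect_equal(t3$avg_methylation[t3$gene == "GENE1"], 3)
  expect_identical(t3$n_cpgs_used[t3$gene == "GENE1"], 2L)
  expect_true(is.na(t3$avg_methylation[t3$gene == "GENE2"]))
  expect_identical(t3$n_cpgs_used[t3$gene == "GENE2"], 0L)
})

test_that("normal reference: closed form, degenerate SD, too few normals", {
  ref <- fit_normal_reference(c(4, 5, 6), gene = "G")
  expect_equal(ref$mu, 5)
  expect_equal(ref$sigma, 1)
  expect_equal(c(ref$lower, ref$upper), c(3, 7))

  expect_warning(degen <- fit_normal_reference(c(5, 5, 5), gene = "G"),
                 "degenerate")
  expect_equal(c(degen$lower, degen$upper), c(5, 5))

  expect_error(fit_normal_reference(5, gene = "G"),
               class = "methcall_calibration_error")

  # SD denominator choice is material at small n
  r1 <- fit_normal_reference(c(4, 5, 6), gene = "G", sd_denominator = "n-1")
  r2 <- fit_normal_reference(c(4, 5, 6), gene = "G", sd_denominator = "n")
  expect_equal(r2$sigma, sqrt(2 / 3))
  expect_true(r2$upper < r1$upper)
})

test_that("calling is strict at the thresholds and propagates missingness", {
  ref <- fit_normal_reference(c(4, 5, 6), gene = "G")
  expect_identical(call_sample(8.0, ref), "hyper")
  expect_identical(call_sample(7.0, ref), "in_range")  # boundary is strict
  expect_identical(call_sample(3.0, ref), "in_range")
  expect_identical(call_sample(2.9, ref), "hypo")
  expect_identical(call_sample(NA_real_, ref), "missing")
  expect_error(call_sample(5, ref, gene = "OTHER"),
               class = "methcall_validation_error")
})

test_that("cohort calling matches expectations on the tiny fixture", {
  calls <- call_cohort(tiny_cohort())
  get <- function(s, g) calls$state[calls$sample_id == s & calls$gene == g]
  expect_identical(get("T1", "GENE1"), "hyper")     # 40 vs (3, 7)
  expect_identical(get("T2", "GENE1"), "in_range")  # equals normal mean
  expect_identical(get("T4", "GENE1"), "in_range")  # exactly upper bound 7
  expect_identical(get("T3", "GENE2"), "missing")
  expect_identical(get("T2", "GENE2"), "hypo")      # 1 vs lower 10 - 2*sd
  # normals receive no calls
  expect_false(any(grepl("^N", calls$sample_id)))
})

test_that("tumours drawn at the normal mean are all in range", {
  set.seed(402)
  n_norm <- 20
  meas <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("N%02d", 1:n_norm), gene = "GENE1",
                   cpg_index = 1L, methylation_percent = rnorm(n_norm, 10, 1)),
    tibble::tibble(sample_id = sprintf("T%02d", 1:5), gene = "GENE1",
                   cpg_index = 1L, methylation_percent = 10)
  )
  meta <- tibble::tibble(
    sample_id = c(sprintf("N%02d", 1:n_norm), sprintf("T%02d", 1:5)),
    diagnosis = rep(c("normal", "DCIS"), c(n_norm, 5)),
    er = "unknown", pr = "unknown", tp53 = "unknown", ki67 = "unknown",
    grade = "unknown"
  )
  meta$grade[meta$diagnosis == "DCIS"] <- "B_II"
  cohort <- join_cohort(meas, meta, gene_panel("GENE1"))
  refs <- fit_normal_references(cohort)
  # the tumour value equals the empirical normal mean only approximately;
  # it must sit inside mean +/- 2 SD regardless
  calls <- call_cohort(cohort, refs)
  expect_true(all(calls$state == "in_range"))
})

test_that("programmed hyper fraction is recovered within binomial error", {
  # single-gene cohort, 200 tumours at 80% programmed hyper fraction
  cfg <- default_simulation_config(
    seed = 71, group_sizes = c(normal = 60, DCIS = 100, invasive = 100,
                               mixed = 0)
  )
  cfg$genes <- cfg$genes["GSTP1"]
  cfg$genes$GSTP1$hyper_fraction <- c(DCIS = 0.8, invasive = 0.8, mixed = 0.8)
  cfg$genes$GSTP1$normals_measured <- 60L
  cfg$genes$GSTP1$missing_rate <- 0
  sim <- simulate_cohort(cfg)
  cohort <- join_cohort(sim$measurements, sim$metadata, gene_panel("GSTP1"))
  calls <- call_cohort(cohort)
  obs <- mean(calls$state == "hyper")
  expect_lt(abs(obs - 0.8), 2 * sqrt(0.8 * 0.2 / 200))
})

test_that("loss of imprinting produces hypomethylation calls", {
  cfg <- default_simulation_config(seed = 72)
  sim <- simulate_cohort(cfg)
  cohort <- join_cohort(sim$measurements, sim$metadata, gene_panel())
  calls <- call_cohort(cohort)
  igf2 <- calls[calls$gene == "IGF2", ]
  expect_gt(sum(igf2$state == "hypo"), 0)
  expect_gt(sum(igf2$state == "hyper"), 0)
  truth <- sim$truth[sim$truth$gene == "IGF2", ]
  joined <- dplyr::inner_join(igf2, truth, by = c("sample_id", "gene"))
  # programmed hypo samples are overwhelmingly called hypo (shift -30 >> SD)
  expect_gt(mean(joined$state[joined$component == "hypo"] == "hypo"), 0.9)
})

test_that("frequency table reproduces printed-style ratios and conserves counts", {
  make_calls <- function(n_hyper, n_valid, n_group, gene = "G1") {
    n_missing <- n_group - n_valid
    tibble::tibble(
      sample_id = sprintf("T%03d", seq_len(n_group)), gene = gene,
      avg_methylation = 1, n_cpgs_used = 1L,
      state = c(rep("hyper", n_hyper), rep("in_range", n_valid - n_hyper),
                rep("missing", n_missing))
    )
  }
  meta_for <- function(calls) {
    tibble::tibble(sample_id = unique(calls$sample_id), diagnosis = "DCIS",
                   er = "unknown", pr = "unknown", tp53 = "unknown",
                   ki67 = "unknown", grade = "B_II")
  }
  f1 <- frequency_table(make_calls(6, 27, 27), meta_for(make_calls(6, 27, 27)))
  expect_equal(f1$frequency[f1$state == "hyper"], 22.2)
  f2 <- frequency_table(make_calls(0, 27, 27), meta_for(make_calls(0, 27, 27)))
  expect_equal(f2$frequency[f2$state == "hyper"], 0)
  # 55.0% is reachable only once missing assays shrink the denominator
  f3 <- frequency_table(make_calls(11, 20, 27), meta_for(make_calls(11, 20, 27)))
  expect_equal(f3$frequency[f3$state == "hyper"], 55.0)
  expect_identical(f3$n_valid[f3$state == "hyper"], 20L)
  # no k/27 rounds to 55.0
  expect_false(any(vapply(0:27, function(k) {
    abs(round(100 * k / 27, 1) - 55.0) < 1e-9
  }, logical(1))))
  # conservation: states sum to group size
  expect_identical(sum(f3$n_called), 27L)
})

test_that("frequencies across a simulated cohort conserve group sizes", {
  cfg <- default_simulation_config(seed = 73)
  sim <- simulate_cohort(cfg)
  cohort <- join_cohort(sim$measurements, sim$metadata)
  freq <- frequency_table(call_cohort(cohort), cohort$metadata)
  sizes <- c(DCIS = 27L, invasive = 28L, mixed = 34L)
  tot <- dplyr::summarise(dplyr::group_by(freq, gene, group),
                          n = sum(n_called), .groups = "drop")
  expect_true(all(tot$n == sizes[tot$group]))
  expect_true(all(freq$n_called <= freq$n_valid |
                    freq$state == "missing"))
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 100, na.rm = TRUE))
})

test_that("calls are invariant to CpG and sample order, monotone in average", {
  cohort <- tiny_cohort()
  calls <- call_cohort(cohort)
  shuffled <- tiny_measurements()[sample(nrow(tiny_measurements())), ]
  cohort2 <- join_cohort(shuffled, tiny_metadata()[sample(7), ], tiny_panel())
  calls2 <- call_cohort(cohort2)
  key <- function(x) x[order(x$sample_id, x$gene), ]
  expect_equal(key(as.data.frame(calls)), key(as.data.frame(calls2)),
               ignore_attr = TRUE)

  # monotonicity: raising an average never moves the state downward
  ref <- fit_normal_reference(c(4, 5, 6), gene = "G")
  states <- vapply(seq(0, 12, by = 0.1), call_sample, character(1), ref = ref)
  rank_of <- c(hypo = 1L, in_range = 2L, hyper = 3L)
  expect_true(all(diff(rank_of[states]) >= 0))
})

test_that("methylated gene counts follow the reporting policy", {
  calls <- tibble::tibble(
    sample_id = "T1",
    gene = c("A", "B", "C", "D", "IMP"),
    avg_methylation = 1, n_cpgs_used = 1L,
    state = c("hyper", "hyper", "hyper", "hypo", "hypo")
  )
  panel <- gene_panel(c("A", "B", "C", "D", "IMP"),
                      imprinted = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(methylated_gene_count(calls, panel)$n_methylated, 4L)
  expect_identical(methylated_gene_count(calls, panel,
                                         count_hypo = TRUE)$n_methylated, 5L)
  all_in_range <- dplyr::mutate(calls, state = "in_range")
  expect_identical(methylated_gene_count(all_in_range, panel)$n_methylated, 0L)
  # permutation of gene order leaves the count unchanged
  expect_identical(methylated_gene_count(calls[5:1, ], panel)$n_methylated, 4L)
})

test_that("background subtraction floors at zero and shifts only listed genes", {
  controls <- tibble::tibble(control_type = "unmethylated_dna", gene = "GENE1",
                             cpg_index = c(1L, 2L),
                             methylation_percent = c(2, 4))
  m <- tibble::tibble(sample_id = "s", gene = c("GENE1", "GENE2"),
                      cpg_index = 1L, methylation_percent = c(2, 50))
  out <- subtract_background(m, controls)
  expect_equal(out$methylation_percent, c(0, 50))  # 2 - 3 floored at 0
})
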