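# Screen-level behaviour on simulated cohorts. Permutation counts are kept
# moderate; the p-value floor 1/(n_perm+1) must stay well below alpha/m for
# BH to be able to reject at all.

screen_cohort <- function(cfg) {
  sim <- simulate_cohort(cfg)
  cohort <- join_cohort(sim$measurements, sim$metadata,
                        gene_panel(names(cfg$genes),
                                   imprinted = names(cfg$genes) == "IGF2"))
  list(averages = gene_sample_averages(cohort), metadata = cohort$metadata)
}

test_that("a programmed ER shift is flagged at q < 0.05 and nulls are not", {
  hits <- 0L
  false_genes <- character(0)
  n_rep <- 15L
  for (i in seq_len(n_rep)) {
    cfg <- null_simulation_config(seed = 5000 + i)
    # 2-SD-of-baseline shift on one gene for ER-negative tumours
    cfg$factor_effects <- list(list(
      factor = "er", level = "negative", genes = "ESR1",
      shift = -2 * cfg$genes$ESR1$baseline_sd
    ))
    sc <- screen_cohort(cfg)
    res <- association_screen(sc$averages, sc$metadata, n_perm = 1999,
                              seed = 100 + i)
    hit <- res$significant[res$gene == "ESR1" & res$factor == "er"]
    hits <- hits + as.integer(hit)
    false_genes <- c(false_genes,
                     res$gene[res$significant &
                                !(res$gene == "ESR1" & res$factor == "er")])
  }
  expect_gte(hits / n_rep, 0.9)
  # false flags across 15 replicates x 54 null tests stay rare under FDR 5%
  expect_lte(length(false_genes), 15)
})

test_that("null screens produce approximately uniform p-values", {
  ps <- c()
  for (i in 1:30) {
    sc <- screen_cohort(null_simulation_config(seed = 6000 + i))
    res <- association_screen(sc$averages, sc$metadata, n_perm = 199,
                              seed = 200 + i)
    ps <- c(ps, res$p_perm[!is.na(res$p_perm)])
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("screen output is a complete gene-by-factor grid with BH family", {
  sc <- screen_cohort(default_simulation_config(seed = 61))
  res <- association_screen(sc$averages, sc$metadata, n_perm = 99, seed = 3)
  expect_identical(nrow(res), 11L * 5L)
  expect_setequal(unique(res$factor), names(factor_levels()))
  expect_identical(res$statistic_kind[res$factor == "grade"][1],
                   "kruskal_wallis_H")
  expect_identical(res$statistic_kind[res$factor == "er"][1],
                   "mann_whitney_U")
  ok <- !is.na(res$p_perm)
  expect_equal(res$q_value[ok], oracle_bh(res$p_perm[ok]), tolerance = 1e-12)
})

test_that("untestable cells become NA rows excluded from the BH family", {
  sc <- screen_cohort(default_simulation_config(seed = 62))
  md <- sc$metadata
  md$er[md$diagnosis != "normal"] <- "positive"  # one-armed factor
  res <- association_screen(sc$averages, md, n_perm = 99, seed = 3)
  er_rows <- res[res$factor == "er", ]
  expect_true(all(is.na(er_rows$p_perm)))
  expect_true(all(is.na(er_rows$q_value)))
  other <- res[res$factor != "er" & !is.na(res$p_perm), ]
  expect_equal(other$q_value, oracle_bh(other$p_perm), tolerance = 1e-12)
})

test_that("adding a test never perturbs the others (seed derivation)", {
  sc <- screen_cohort(default_simulation_config(seed = 63))
  full <- association_screen(sc$averages, sc$metadata, n_perm = 299, seed = 11)
  two <- association_screen(sc$averages, sc$metadata,
                            factors = factor_levels()[c("er", "grade")],
                            n_perm = 299, seed = 11)
  joined <- dplyr::inner_join(
    two[, c("gene", "factor", "p_perm")],
    full[, c("gene", "factor", "p_perm")],
    by = c("gene", "factor"), suffix = c("_two", "_full")
  )
  expect_equal(joined$p_perm_two, joined$p_perm_full)

  # sample order is irrelevant given the same seed handling
  perm <- sample(nrow(sc$averages))
  res2 <- association_screen(sc$averages[perm, ], sc$metadata,
                             n_perm = 299, seed = 11)
  cmp <- dplyr::inner_join(full[, c("gene", "factor", "statistic")],
                           res2[, c("gene", "factor", "statistic")],
                           by = c("gene", "factor"))
  expect_equal(cmp$statistic.x, cmp$statistic.y)
})

test_that("diagnosis-level comparisons: self-comparison is null, shifts detected", {
  sc <- screen_cohort(default_simulation_config(seed = 64))
  self <- diagnosis_level_comparison(sc$averages, sc$metadata, "FOXC1",
                                     pairs = list(c("DCIS", "DCIS")),
                                     n_perm = 99, seed = 5)
  expect_equal(self$p_perm, 1)

  # type-I: under a null gene all pairwise p behave like uniform draws
  null_p <- c()
  for (i in 1:20) {
    sc0 <- screen_cohort(null_simulation_config(seed = 7000 + i,
                                                genes = "MGMT"))
    res <- diagnosis_level_comparison(sc0$averages, sc0$metadata, "MGMT",
                                      n_perm = 199, seed = i)
    null_p <- c(null_p, res$p_perm)
  }
  expect_gte(mean(null_p >= 0.05), 0.9)

  # power: a 1.5-SD DCIS-vs-invasive shift is detected at study sizes
  detected <- 0L
  for (i in 1:20) {
    cfg <- null_simulation_config(seed = 7100 + i, genes = "MGMT")
    cfg$genes$MGMT$missing_rate <- 0
    sim <- simulate_cohort(cfg)
    sd0 <- cfg$genes$MGMT$baseline_sd
    sim$measurements$methylation_percent[
      sim$measurements$sample_id %in%
        sim$metadata$sample_id[sim$metadata$diagnosis == "invasive"]
    ] <- sim$measurements$methylation_percent[
      sim$measurements$sample_id %in%
        sim$metadata$sample_id[sim$metadata$diagnosis == "invasive"]
    ] + 1.5 * sd0
    cohort <- join_cohort(sim$measurements, sim$metadata, gene_panel("MGMT"))
    res <- diagnosis_level_comparison(gene_sample_averages(cohort),
                                      cohort$metadata, "MGMT",
                                      pairs = list(c("DCIS", "invasive")),
                                      n_perm = 999, seed = i)
    detected <- detected + as.integer(res$p_perm < 0.05)
  }
  expect_gte(detected / 20, 0.8)
})

test_that("co-methylation reports symmetric rho with exact rho-squared", {
  cfg <- default_simulation_config(seed = 65)
  sim <- simulate_cohort(cfg)
  cohort <- join_cohort(sim$measurements, sim$metadata)
  avg <- gene_sample_averages(cohort)
  tum <- cohort$metadata$sample_id[cohort$metadata$diagnosis != "normal"]
  res <- comethylation(avg[avg$sample_id %in% tum, ],
                       genes = c("FOXC1", "RASSF1A", "ABCB1"),
                       n_perm = 499, seed = 9)
  expect_identical(nrow(res), 3L)
  expect_equal(res$rho_squared, res$rho^2)
  expect_true(all(abs(res$rho) <= 1))
  ok <- !is.na(res$p_perm)
  expect_equal(res$q_value[ok], oracle_bh(res$p_perm[ok]), tolerance = 1e-12)

  # swapping the gene-vector roles leaves rho unchanged
  wide <- tidyr::pivot_wider(
    avg[avg$sample_id %in% tum & avg$gene %in% c("FOXC1", "ABCB1"),
        c("sample_id", "gene", "avg_methylation")],
    names_from = "gene", values_from = "avg_methylation"
  )
  a <- spearman_perm(wide$FOXC1, wide$ABCB1, n_perm = 99, seed = 2)
  b <- spearman_perm(wide$ABCB1, wide$FOXC1, n_perm = 99, seed = 2)
  expect_equal(a$rho, b$rho)
})
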