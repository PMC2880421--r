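# Fixtures and independent oracles used across the suite. The oracles are
# deliberately naive (pair counting, exhaustive enumeration, direct formula)
# and share no code with the implementation they check.

# Small two-gene cohort built in code: 3 normals (GENE1 averages 4/5/6,
# GENE2 averages 10/10/10) and 4 tumours with known averages.
tiny_panel <- function() gene_panel(c("GENE1", "GENE2"),
                                    imprinted = c(FALSE, TRUE))

tiny_measurements <- function() {
  rows <- list()
  add <- function(sample, gene, vals) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      sample_id = sample, gene = gene,
      cpg_index = seq_along(vals), methylation_percent = vals
    )
  }
  add("N1", "GENE1", c(3, 4, 5));  add("N1", "GENE2", c(10, 10))
  add("N2", "GENE1", c(4, 5, 6));  add("N2", "GENE2", c(9, 12))
  add("N3", "GENE1", c(5, 6, 7));  add("N3", "GENE2", c(10, 10))
  add("T1", "GENE1", c(39, 40, 41))          # hyper (avg 40)
  add("T1", "GENE2", c(10, 10))              # in range
  add("T2", "GENE1", c(4, 5, 6))             # in range (equals normal mean)
  add("T2", "GENE2", c(1, 1))                # hypo for GENE2 if sigma small
  add("T3", "GENE1", c(2, NA, 4))            # avg 3, n_used 2
  add("T3", "GENE2", c(NA_real_, NA_real_))  # missing assay
  add("T4", "GENE1", c(7, 7, 7))             # boundary area
  dplyr::bind_rows(rows)
}

tiny_metadata <- function() {
  tibble::tibble(
    sample_id = c("N1", "N2", "N3", "T1", "T2", "T3", "T4"),
    diagnosis = c("normal", "normal", "normal", "DCIS", "DCIS",
                  "invasive", "mixed"),
    er = c("unknown", "unknown", "unknown", "positive", "negative",
           "positive", "unknown"),
    pr = "unknown", tp53 = "unknown", ki67 = "unknown",
    grade = c("unknown", "unknown", "unknown", "B_II", "C_III",
              "A_I", "B_II")
  )
}

tiny_cohort <- function() {
  join_cohort(tiny_measurements(), tiny_metadata(), tiny_panel())
}

# Independent Mann-Whitney oracle: U by pair counting (wins + half ties),
# exact two-sided permutation p by enumerating every assignment.
oracle_mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n_a <- length(x)
  e_u <- n_a * (n - n_a) / 2
  obs <- abs(oracle_mw_u(x, y) - e_u)
  picks <- utils::combn(n, n_a)
  devs <- apply(picks, 2L, function(ii) {
    abs(oracle_mw_u(pooled[ii], pooled[-ii]) - e_u)
  })
  mean(devs >= obs - 1e-9)
}

# Independent Kruskal-Wallis oracle: H from first principles on midranks,
# exact upper-tail p over all distinct assignments (3 groups).
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  n <- length(r)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, sum)^2 / table(groups)) - 3 * (n + 1)
  tt <- table(r)
  h / (1 - sum(tt^3 - tt) / (n^3 - n))
}

oracle_kw_exact_p <- function(values, sizes) {
  n <- length(values)
  stopifnot(sum(sizes) == n, length(sizes) == 3L)
  obs <- oracle_kw_h(values, rep(seq_along(sizes), times = sizes))
  hs <- c()
  first <- utils::combn(n, sizes[1])
  for (i in seq_len(ncol(first))) {
    rest <- setdiff(seq_len(n), first[, i])
    second <- utils::combn(length(rest), sizes[2])
    for (j in seq_len(ncol(second))) {
      g <- integer(n)
      g[first[, i]] <- 1L
      g[rest[second[, j]]] <- 2L
      g[g == 0L] <- 3L
      hs <- c(hs, oracle_kw_h(values, g))
    }
  }
  mean(hs >= obs - 1e-9)
}

# Direct BH step-up formula, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  if (m >= 2) {
    for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Null config helper: default model with every aberrant fraction zeroed.
null_simulation_config <- function(seed, group_sizes = NULL, genes = NULL) {
  cfg <- if (is.null(group_sizes)) default_simulation_config(seed = seed)
         else default_simulation_config(seed = seed, group_sizes = group_sizes)
  zero <- c(DCIS = 0, invasive = 0, mixed = 0)
  for (g in names(cfg$genes)) {
    cfg$genes[[g]]$hyper_fraction <- zero
    cfg$genes[[g]]$hypo_fraction <- zero
  }
  if (!is.null(genes)) cfg$genes <- cfg$genes[genes]
  cfg
}
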