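# Permutation machinery for the rank-based tests. Ties are handled by
# midranks everywhere; permuting labels over a fixed rank vector makes
# variance tie-corrections irrelevant to the p-value, so the tests are valid
# under arbitrary ties.

# 31-bit polynomial string hash (no external digest dependency). Exact in
# double arithmetic: h < 2^31, h*131 + 255 < 2^39 < 2^53.
string_hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  h
}

#' Derive a per-test seed from a root seed and a label
#'
#' A single root seed feeds a deterministic per-test seed (hash of the test
#' label, e.g. `"FOXC1:er"`), so adding or reordering tests in a screen never
#' perturbs the permutation stream of the others.
#'
#' @param root_seed Integer root seed.
#' @param key Character label identifying the test.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root_seed, key) {
  as.integer((string_hash31(key) + (as.numeric(root_seed) %% 2147483629) *
                2654435) %% 2147483629 + 1)
}

n_distinct_nonmissing <- function(x) length(unique(x[!is.na(x)]))

# Shared Monte-Carlo p-value: observed arrangement included, so p >= 1/(B+1)
# and p = 0 is impossible.
mc_pvalue <- function(perm_stats, observed, tol = 1e-9) {
  (1 + sum(perm_stats >= observed - tol)) / (length(perm_stats) + 1)
}

#' Permutation Mann-Whitney test
#'
#' Two-sided two-sample rank test. The statistic is the Mann-Whitney U of
#' the first group with midranks for ties; the p-value is the proportion of
#' group-label permutations whose `|U - n_a n_b / 2|` is at least the
#' observed deviation. When the number of distinct assignments
#' `choose(n_a + n_b, n_a)` is at most `exact_cap`, all assignments are
#' enumerated (`exact = TRUE`); otherwise `n_perm` random permutations are
#' sampled and the observed arrangement is included, so the p-value is
#' `(b + 1) / (n_perm + 1)`.
#'
#' @param x,y Numeric vectors for the two groups; missing values dropped.
#' @param n_perm Number of sampled permutations when enumeration is not used.
#' @param seed Integer seed for the sampled case (`NULL` leaves the RNG
#'   state alone).
#' @param exact_cap Enumerate exhaustively when `choose(n, n_a) <= exact_cap`.
#' @return One-row tibble: `statistic_kind`, `statistic` (U), `p_perm`,
#'   `n_perm` (number of permutations actually used), `exact`, `seed`,
#'   `n_a`, `n_b`.
#' @examples
#' mann_whitney_perm(c(1, 2, 3), c(4, 5))$p_perm  # exact 0.2
#' @export
mann_whitney_perm <- function(x, y, n_perm = 1e5, seed = NULL,
                              exact_cap = 10000) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n_a <- length(x)
  n_b <- length(y)
  if (n_a < 2L || n_b < 2L) {
    abort("each group needs >= 2 non-missing values",
          class = "methcall_untestable_error")
  }
  r <- rank(c(x, y))
  n <- n_a + n_b
  u_of <- function(ra_sum) ra_sum - n_a * (n_a + 1) / 2
  obs_u <- u_of(sum(r[seq_len(n_a)]))
  e_u <- n_a * n_b / 2
  obs_dev <- abs(obs_u - e_u)
  n_comb <- choose(n, n_a)
  if (n_comb <= exact_cap) {
    idx <- combn(n, n_a)
    dev <- abs(u_of(colSums(matrix(r[idx], nrow = n_a))) - e_u)
    p <- sum(dev >= obs_dev - 1e-9) / n_comb
    used <- as.integer(n_comb)
    exact <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    dev <- vapply(seq_len(n_perm), function(i) {
      abs(u_of(sum(r[sample.int(n, n_a)])) - e_u)
    }, numeric(1))
    p <- mc_pvalue(dev, obs_dev)
    used <- as.integer(n_perm)
    exact <- FALSE
  }
  tibble::tibble(statistic_kind = "mann_whitney_U", statistic = obs_u,
                 p_perm = p, n_perm = used, exact = exact,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 n_a = n_a, n_b = n_b)
}

# Tie-corrected Kruskal-Wallis H from pooled midranks r and group index g.
kw_stat <- function(r, g, tie_factor) {
  n <- length(r)
  rs <- tapply(r, g, sum)
  ns <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  h / tie_factor
}

#' Permutation Kruskal-Wallis test
#'
#' k-group rank test with the tie-corrected H statistic; the p-value is the
#' upper-tail proportion of group-label permutations with `H >=` the observed
#' value (observed arrangement included when sampling). Full enumeration of
#' all distinct assignments is used when their multinomial count is at most
#' `exact_cap`.
#'
#' @param values Numeric vector; missing values dropped (with their labels).
#' @param groups Group labels, same length as `values`.
#' @inheritParams mann_whitney_perm
#' @return One-row tibble as in [mann_whitney_perm()] with
#'   `statistic_kind = "kruskal_wallis_H"` and `n_groups` instead of
#'   `n_a`/`n_b`.
#' @examples
#' kruskal_wallis_perm(1:6, rep(c("a", "b", "c"), each = 2))$p_perm  # 6/90
#' @export
kruskal_wallis_perm <- function(values, groups, n_perm = 1e5, seed = NULL,
                                exact_cap = 10000) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  ns <- tabulate(groups)
  if (sum(ns >= 2L) < 2L || length(values) < 4L) {
    abort("need >= 2 groups with >= 2 non-missing values",
          class = "methcall_untestable_error")
  }
  r <- rank(values)
  n <- length(r)
  t_counts <- table(r)
  tie_factor <- 1 - sum(t_counts^3 - t_counts) / (n^3 - n)
  if (tie_factor == 0) {  # all values identical
    return(tibble::tibble(statistic_kind = "kruskal_wallis_H", statistic = 0,
                          p_perm = 1, n_perm = 0L, exact = TRUE,
                          seed = if (is.null(seed)) NA_integer_
                                 else as.integer(seed),
                          n_groups = nlevels(groups)))
  }
  g <- as.integer(groups)
  obs_h <- kw_stat(r, g, tie_factor)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(ns + 1)))
  if (n_assign <= exact_cap + 0.5) {
    hs <- enumerate_kw(r, ns, tie_factor)
    p <- sum(hs >= obs_h - 1e-9) / length(hs)
    used <- length(hs)
    exact <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    # Permuting the rank vector over fixed group positions is equivalent to
    # permuting labels and avoids regrouping work per draw.
    idx <- split(seq_len(n), g)
    const_a <- 12 / (n * (n + 1))
    const_b <- 3 * (n + 1)
    hs <- vapply(seq_len(n_perm), function(i) {
      rp <- r[sample.int(n)]
      s2 <- 0
      for (j in seq_along(idx)) s2 <- s2 + sum(rp[idx[[j]]])^2 / ns[j]
      (const_a * s2 - const_b) / tie_factor
    }, numeric(1))
    p <- mc_pvalue(hs, obs_h)
    used <- as.integer(n_perm)
    exact <- FALSE
  }
  tibble::tibble(statistic_kind = "kruskal_wallis_H", statistic = obs_h,
                 p_perm = p, n_perm = used, exact = exact,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 n_groups = nlevels(groups))
}

# Enumerate every distinct assignment of ranks r to groups of sizes ns and
# return the H statistic of each. Recursive over groups: choose which of the
# remaining positions go to the next group.
enumerate_kw <- function(r, ns, tie_factor) {
  n <- length(r)
  out <- numeric(0)
  assign_rec <- function(remaining, g_idx, g_vec) {
    if (g_idx == length(ns)) {
      g_vec[remaining] <- g_idx
      out[[length(out) + 1]] <<- kw_stat(r, g_vec, tie_factor)
      return(invisible())
    }
    picks <- combn(length(remaining), ns[g_idx])
    for (j in seq_len(ncol(picks))) {
      g2 <- g_vec
      g2[remaining[picks[, j]]] <- g_idx
      assign_rec(remaining[-picks[, j]], g_idx + 1L, g2)
    }
  }
  assign_rec(seq_len(n), 1L, integer(n))
  unlist(out)
}

#' Permutation Spearman correlation
#'
#' Spearman's rho computed as the Pearson correlation of midranks, with a
#' two-sided permutation p-value obtained by shuffling `y`. `rho_squared`
#' is reported alongside rho, as co-methylation strength is conventionally
#' quoted as a squared correlation.
#'
#' @param x,y Numeric vectors; pairs with any missing value are dropped.
#' @inheritParams mann_whitney_perm
#' @return One-row tibble: `statistic_kind = "spearman_rho"`, `rho`,
#'   `rho_squared`, `p_perm`, `n_perm`, `exact = FALSE`, `seed`, `n`.
#' @export
spearman_perm <- function(x, y, n_perm = 1e5, seed = NULL) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    abort("need >= 3 complete pairs", class = "methcall_untestable_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("zero variance: Spearman correlation undefined",
          class = "methcall_untestable_error")
  }
  obs <- cor(rx, ry)
  if (!is.null(seed)) set.seed(seed)
  devs <- vapply(seq_len(n_perm), function(i) {
    abs(cor(rx, ry[sample.int(n)]))
  }, numeric(1))
  p <- mc_pvalue(devs, abs(obs))
  tibble::tibble(statistic_kind = "spearman_rho", rho = obs,
                 rho_squared = obs^2, p_perm = p,
                 n_perm = as.integer(n_perm), exact = FALSE,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment over a family of p-values:
#' sorted ascending, `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and
#' mapped back to the input order. Missing entries are excluded from the
#' family and stay missing.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) {
    abort("p-values must lie in (0, 1]", class = "methcall_validation_error")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
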