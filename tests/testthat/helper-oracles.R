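# Independent oracles used to cross-check the package implementations.

# Exhaustive AMOC search: per-split segment costs computed directly from
# mean/variance on slices, no shared code with the scan in amoc_meanvar().
oracle_amoc <- function(y, var_floor = 1e-12) {
  n <- length(y)
  cost <- function(seg) {
    length(seg) * log(max(mean((seg - mean(seg))^2), var_floor))
  }
  taus <- 2:(n - 2)
  split_costs <- vapply(taus, function(tau) {
    cost(y[1:tau]) + cost(y[(tau + 1):n])
  }, numeric(1))
  best <- which.min(split_costs)
  list(tau = taus[best],
       statistic = max(cost(y) - split_costs[best], 0))
}

# Kruskal-Wallis H from first principles: mid-ranks and the tie
# correction divisor, chi-square p on k - 1 df.
oracle_kruskal <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) -
    3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  k <- length(unique(groups))
  list(statistic = h, p_value = stats::pchisq(h, k - 1, lower.tail = FALSE))
}

# Classical one-way ANOVA from explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  k <- nlevels(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) {
    length(x) * (mean(x) - grand)^2
  }))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f,
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# A small multi-site PRS table with sub-annual control over ages/values.
make_prs_table <- function(site_values) {
  purrr::imap_dfr(site_values, function(df, id) {
    tibble::tibble(site_id = id, age_ce = df$age_ce, prs = df$prs)
  })
}
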