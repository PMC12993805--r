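test_that("elevation and footprint groupings honour the boundary rules", {
  expect_equal(as.character(assign_elevation_group(c(120, 500, 1500, 3800))),
               c("lowland", "upland", "upland", "highland"))
  expect_equal(as.character(assign_footprint_class(c(0.5, 1, 4, 17))),
               c("wilderness", "intact", "intact", "highly_modified"))
  expect_error(assign_footprint_class(60), "0, 50")
  expect_error(assign_elevation_group(-5), ">= 0")
})

test_that("Kruskal-Wallis matches the hand rank formula on the toy case", {
  df <- data.frame(g = rep(c("A", "B"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  out <- kw_test(df, "y", "g")
  expect_equal(out$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(out$df, 1)

  same <- data.frame(g = rep(c("A", "B"), each = 3), y = rep(c(1, 2, 3), 2))
  expect_equal(kw_test(same, "y", "g")$statistic, 0, tolerance = 1e-9)

  flat <- data.frame(g = rep(c("A", "B"), 3), y = rep(1, 6))
  out_flat <- kw_test(flat, "y", "g")
  expect_equal(out_flat$statistic, 0)
  expect_equal(out_flat$p_value, 1)

  # label permutation invariance
  perm <- df[sample(nrow(df)), ]
  expect_equal(kw_test(perm, "y", "g"), out)
})

test_that("one-way ANOVA matches hand sums of squares and conventions", {
  df <- data.frame(g = rep(c("A", "B"), each = 3), y = c(1, 2, 3, 2, 3, 4))
  out <- anova_oneway(df, "y", "g")
  expect_equal(out$statistic, 1.5, tolerance = 1e-9)

  eq <- data.frame(g = rep(c("A", "B"), each = 2), y = c(1, 2, 1, 2))
  expect_equal(anova_oneway(eq, "y", "g")$statistic, 0, tolerance = 1e-12)

  deg <- data.frame(g = rep(c("A", "B"), each = 2), y = c(0, 0, 1, 1))
  out_deg <- anova_oneway(deg, "y", "g")
  expect_equal(out_deg$statistic, Inf)
  expect_equal(out_deg$p_value, 0)
})

test_that("group tests agree with independent oracles on random fixtures", {
  set.seed(42)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    g <- rep(paste0("g", seq_len(k)), times = sample(3:8, k, replace = TRUE))
    y <- round(rnorm(length(g)), sample(c(1, 2, 6), 1))  # induce ties
    df <- data.frame(g = g, y = y)
    if (length(unique(y)) == 1L) next
    kw <- kw_test(df, "y", "g")
    okw <- oracle_kruskal(y, g)
    expect_equal(kw$statistic, okw$statistic, tolerance = 1e-8)
    expect_equal(kw$p_value, okw$p_value, tolerance = 1e-8)
    av <- anova_oneway(df, "y", "g")
    oav <- oracle_anova(y, g)
    expect_equal(av$statistic, oav$statistic, tolerance = 1e-8)
    expect_equal(av$p_value, oav$p_value, tolerance = 1e-8)
  }
})

test_that("climate PCA standardises, orders, orients, and reconstructs", {
  set.seed(9)
  n <- 30
  base <- rnorm(n)
  df <- tibble::tibble(site_id = paste0("s", 1:n),
                       v1 = base, v2 = 2 * base + 3,  # perfectly correlated
                       v3 = rnorm(n), v4 = rnorm(n))
  p2 <- pca_climate(df, c("v1", "v2"))
  expect_equal(p2$var_explained, c(100, 0), tolerance = 1e-9)
  expect_equal(sum(p2$var_explained), 100, tolerance = 1e-9)

  p4 <- pca_climate(df, c("v1", "v2", "v3", "v4"))
  expect_equal(sum(p4$var_explained), 100, tolerance = 1e-9)
  expect_true(all(diff(p4$var_explained) <= 1e-9))
  # orientation: dominant loading positive per component
  for (j in 2:5) {
    l <- p4$loadings[[j]]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # reconstruction: scores %*% t(loadings) = standardised data
  S <- as.matrix(p4$scores[, -1])
  L <- as.matrix(p4$loadings[, -1])
  X <- scale(as.matrix(df[, c("v1", "v2", "v3", "v4")]))
  expect_equal(S %*% t(L), X, tolerance = 1e-8, ignore_attr = TRUE)

  dfc <- dplyr::mutate(df, v5 = 1)
  expect_warning(pca_climate(dfc, c("v1", "v3", "v5")), "constant")
})

test_that("screening and backward elimination follow the protocol", {
  set.seed(21)
  n <- 40
  x1 <- rnorm(n)
  df <- tibble::tibble(
    site_id = paste0("s", 1:n),
    resp = x1,                       # exactly one candidate
    x1 = x1,
    weak = 0.05 * x1 + rnorm(n),     # screened out at 0.25
    noise = rnorm(n))
  fit <- suppressWarnings(
    screen_and_regress(df, "resp", c("x1", "weak", "noise")))
  expect_equal(fit$variables, "x1")
  expect_equal(suppressWarnings(glance(fit))$r_squared, 1, tolerance = 1e-9)
  co <- suppressWarnings(tidy(fit))
  expect_equal(co$estimate[co$term == "x1"], 1, tolerance = 1e-9)
  expect_match(fit$screen$fate[fit$screen$variable == "weak"],
               "screened out")

  # collinear pair: the one less correlated with the response is dropped
  z <- rnorm(n)
  df2 <- tibble::tibble(
    site_id = paste0("s", 1:n),
    a = z + 0.4 * rnorm(n))
  df2$b <- df2$a + 0.1 * rnorm(n)          # |cor(a, b)| > 0.8
  df2$resp <- df2$a + 0.8 * rnorm(n)       # a more predictive than b
  df2$c <- rnorm(n)
  fit2 <- screen_and_regress(df2, "resp", c("a", "b", "c"))
  expect_true("a" %in% fit2$variables)
  expect_false("b" %in% fit2$variables)
  expect_match(fit2$screen$fate[fit2$screen$variable == "b"], "collinear")

  # nothing survives: empty model reported, not an error
  df3 <- tibble::tibble(site_id = paste0("s", 1:n), resp = rnorm(n),
                        u = rnorm(n), v = rnorm(n))
  fit3 <- screen_and_regress(df3, "resp", c("u", "v"), r_keep = 0.9)
  expect_length(fit3$variables, 0)
  expect_equal(glance(fit3)$n_terms, 0)

  # every surviving term is significant at the stay threshold
  expect_true(all(tidy(fit2)$p_value[tidy(fit2)$term != "(Intercept)"] <
                    0.05))
})

test_that("synthetic covariates hit their target correlations roughly", {
  set.seed(2)
  target <- rnorm(400)
  cov <- synth_covariates(target, c(p_dryq = -0.5, t_seas = 0.3), seed = 4)
  expect_equal(cor(target, cov$p_dryq), -0.5, tolerance = 0.2)
  expect_equal(cor(target, cov$t_seas), 0.3, tolerance = 0.3)
})
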