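#' Elevation grouping of peat sites
#'
#' Lowland below 500 m a.s.l., upland between 500 and 1500 m (boundaries
#' inclusive), highland above 1500 m.
#'
#' @param elevation_m Elevation(s) in metres (>= 0).
#' @return Factor with levels lowland, upland, highland.
#' @examples
#' assign_elevation_group(c(120, 500, 3800))
#' @export
assign_elevation_group <- function(elevation_m) {
  if (any(elevation_m < 0, na.rm = TRUE)) abort("elevation must be >= 0")
  lab <- dplyr::case_when(
    elevation_m < 500 ~ "lowland",
    elevation_m <= 1500 ~ "upland",
    TRUE ~ "highland")
  factor(lab, levels = c("lowland", "upland", "highland"))
}

#' Human-footprint class of a site
#'
#' Wilderness below 1, intact between 1 and 4 (boundaries inclusive),
#' highly modified above 4, on the 0-50 cumulative human pressure index.
#'
#' @param footprint Footprint value(s) in \[0, 50\].
#' @return Factor with levels wilderness, intact, highly_modified.
#' @export
assign_footprint_class <- function(footprint) {
  if (any(footprint < 0 | footprint > 50, na.rm = TRUE)) {
    abort("footprint must lie in [0, 50]")
  }
  lab <- dplyr::case_when(
    footprint < 1 ~ "wilderness",
    footprint <= 4 ~ "intact",
    TRUE ~ "highly_modified")
  factor(lab, levels = c("wilderness", "intact", "highly_modified"))
}

#' Kruskal-Wallis rank-sum test, tidy interface
#'
#' Wraps [stats::kruskal.test()] (mid-ranks with tie correction, chi-square
#' reference on k-1 df). When every value is identical the test is
#' degenerate and `H = 0`, `p = 1` is returned.
#'
#' @param df Data frame.
#' @param value,group Column names (tidy-eval) of the response and the
#'   grouping label.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `k`.
#' @examples
#' kw_test(data.frame(g = rep(c("a", "b"), each = 3), y = c(1:3, 4:6)),
#'         y, g)
#' @export
kw_test <- function(df, value, group) {
  v <- dplyr::pull(df, {{ value }})
  g <- factor(dplyr::pull(df, {{ group }}))
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (length(unique(v)) == 1L) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                  n = length(v), k = nlevels(g)))
  }
  ht <- stats::kruskal.test(v, g)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n = length(v), k = nlevels(g))
}

#' One-way ANOVA, tidy interface
#'
#' Classical between/within mean-square F ratio via [stats::lm()] and
#' [stats::anova()]. When the within-group variance is exactly zero while
#' group means differ, `F = Inf`, `p = 0` is returned by convention; when
#' additionally the means are equal, `F = 0`, `p = 1`.
#'
#' @inheritParams kw_test
#' @return One-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `n`, `k`.
#' @export
anova_oneway <- function(df, value, group) {
  v <- dplyr::pull(df, {{ value }})
  g <- factor(dplyr::pull(df, {{ group }}))
  k <- nlevels(g)
  n <- length(v)
  if (k < 2 || n <= k) abort("need >= 2 groups and n > k")
  within_ss <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  means <- tapply(v, g, mean)
  if (within_ss == 0) {
    equal <- length(unique(means)) == 1L
    return(tibble(statistic = if (equal) 0 else Inf,
                  df_between = k - 1L, df_within = n - k,
                  p_value = if (equal) 1 else 0, n = n, k = k))
  }
  a <- stats::anova(stats::lm(v ~ g))
  tibble(statistic = a$`F value`[1], df_between = a$Df[1],
         df_within = a$Df[2], p_value = a$`Pr(>F)`[1], n = n, k = k)
}

#' Principal component analysis of site climate space
#'
#' Correlation-matrix PCA (variables standardised to zero mean and unit
#' variance) via [stats::prcomp()]. Constant variables are dropped with a
#' warning. For reproducible orientation, each component is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param summaries Site-summary tibble (one row per site).
#' @param variables Character vector of numeric column names to ordinate.
#' @param id Column holding site ids (default `"site_id"`).
#' @return Object of class `climate_pca`: list with `scores` (tibble,
#'   site_id + components), `loadings` (tibble, variable x components),
#'   `var_explained` (percent per component, summing to 100), `sdev`.
#' @export
pca_climate <- function(summaries, variables, id = "site_id") {
  if (nrow(summaries) < 3) abort("PCA needs >= 3 sites")
  X <- as.matrix(summaries[, variables, drop = FALSE])
  if (any(colSums(is.na(X)) == nrow(X))) abort("all-NA variable supplied")
  const <- apply(X, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)
  if (any(const)) {
    warn(sprintf("dropping constant variable(s): %s",
                 paste(variables[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 2) abort("need >= 2 non-constant variables")
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # orient: largest-magnitude loading of each component positive
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  structure(
    list(scores = dplyr::bind_cols(
           tibble(site_id = summaries[[id]]), as_tibble(scores)),
         loadings = dplyr::bind_cols(tibble(variable = colnames(X)),
                                     as_tibble(rot)),
         var_explained = 100 * p$sdev^2 / sum(p$sdev^2),
         sdev = p$sdev),
    class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  cat("<climate_pca>", nrow(x$loadings), "variables,",
      nrow(x$scores), "sites; PC1", sprintf("%.1f%%", x$var_explained[1]),
      "PC2", sprintf("%.1f%%", x$var_explained[2]), "\n")
  invisible(x)
}

#' Correlation-screened multiple regression with backward elimination
#'
#' Reproduces the covariate-selection protocol for burning-status
#' regressions: (1) keep candidates whose absolute Pearson correlation
#' with the response exceeds `r_keep` (default 0.25; 0.3 is the screen
#' used before ordination); (2) among the kept set, where a pair is
#' collinear (|r| > `r_collinear`, default 0.8) drop the member less
#' correlated with the response; (3) fit ordinary least squares and
#' eliminate the largest-p term until every remaining term has
#' p < `p_stay` (default 0.05). Screening that leaves no candidate
#' returns an intercept-only report, not an error.
#'
#' @param summaries Site-summary tibble.
#' @param response Name of the response column (string).
#' @param candidates Character vector of candidate covariate columns.
#' @param r_keep,r_collinear,p_stay Screening thresholds.
#' @return Object of class `prs_screen`: list with `screen` (tibble of
#'   candidate correlations and their fate), `variables` (final terms),
#'   `model` (the `lm` fit), `response`.
#' @export
screen_and_regress <- function(summaries, response, candidates,
                               r_keep = 0.25, r_collinear = 0.8,
                               p_stay = 0.05) {
  if (length(candidates) < 2) abort("need >= 2 candidate variables")
  if (nrow(summaries) <= length(candidates) + 2) {
    abort("need more sites than candidates + 2")
  }
  y <- summaries[[response]]
  r_resp <- vapply(candidates, function(v) {
    suppressWarnings(stats::cor(y, summaries[[v]],
                                use = "pairwise.complete.obs"))
  }, numeric(1))
  r_resp[is.na(r_resp)] <- 0
  kept <- candidates[abs(r_resp) > r_keep]
  fate <- ifelse(abs(r_resp) > r_keep, "kept",
                 sprintf("screened out (|r| <= %g)", r_keep))
  names(fate) <- candidates

  # collinearity pruning: strongest response-correlation wins
  if (length(kept) > 1) {
    ord <- kept[order(-abs(r_resp[kept]))]
    retained <- character()
    for (v in ord) {
      clash <- vapply(retained, function(u) {
        abs(suppressWarnings(stats::cor(summaries[[v]], summaries[[u]],
                                        use = "pairwise.complete.obs"))) >
          r_collinear
      }, logical(1))
      if (any(clash)) {
        fate[v] <- sprintf("collinear with %s (|r| > %g)",
                           names(clash)[clash][1], r_collinear)
      } else {
        retained <- c(retained, v)
      }
    }
    kept <- candidates[candidates %in% retained]
  }

  vars <- kept
  dat <- summaries[, c(response, candidates), drop = FALSE]
  repeat {
    fml <- stats::reformulate(if (length(vars) > 0) vars else "1",
                              response = response)
    fit <- stats::lm(fml, data = dat)
    if (length(vars) == 0) break
    ps <- summary(fit)$coefficients[-1, 4, drop = TRUE]
    worst <- which.max(ps)
    if (ps[worst] < p_stay) break
    fate[vars[worst]] <- sprintf("eliminated (p = %.3f)", ps[worst])
    vars <- vars[-worst]
  }
  structure(
    list(screen = tibble(variable = candidates, r_response = r_resp,
                         fate = unname(fate[candidates])),
         variables = vars, model = fit, response = response),
    class = "prs_screen")
}

#' @export
print.prs_screen <- function(x, ...) {
  cat("<prs_screen>", x$response, "~",
      if (length(x$variables)) paste(x$variables, collapse = " + ")
      else "1 (no variable survived)", "\n")
  cat("  R-squared:", round(summary(x$model)$r.squared, 4), "\n")
  invisible(x)
}

#' @rdname screen_and_regress
#' @param x A `prs_screen` object.
#' @param ... Unused.
#' @return `tidy()`: coefficient table of the final model; `glance()`:
#'   one-row fit summary including the surviving variable count.
#' @export
tidy.prs_screen <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble(term = rownames(co), estimate = unname(co[, 1]),
         std_error = unname(co[, 2]), statistic = unname(co[, 3]),
         p_value = unname(co[, 4]))
}

#' @rdname screen_and_regress
#' @export
glance.prs_screen <- function(x, ...) {
  s <- summary(x$model)
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         sigma = s$sigma, n = length(s$residuals),
         n_terms = length(x$variables))
}

#' Synthetic climate covariates with controlled response correlation
#'
#' Generates standard-normal covariates whose population correlation with
#' `target` equals `r` (one covariate per named element), the mechanism
#' used to exercise the screening/regression protocol with known ground
#' truth.
#'
#' @param target Numeric vector (e.g. cube-root median PRS per site).
#' @param r Named numeric vector of desired correlations in (-1, 1).
#' @param seed Integer seed.
#' @return Tibble with one column per name in `r`, `length(target)` rows.
#' @export
synth_covariates <- function(target, r, seed = 1) {
  if (any(abs(r) >= 1)) abort("correlations must lie in (-1, 1)")
  z <- as.numeric(scale(target))
  with_seed(derive_seed(seed, "covariates"), {
    out <- purrr::imap(r, function(rho, nm) {
      rho * z + sqrt(1 - rho^2) * rnorm(length(z))
    })
    as_tibble(out)
  })
}
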