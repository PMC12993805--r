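#' Bin a transformed charcoal series onto a fixed calendar grid
#'
#' Bin `k` covers `[origin + k*w, origin + (k+1)*w)`; each dated sample is
#' assigned by age and a bin's value is the arithmetic mean of its member
#' PRS values. Empty bins carry NA (absence of samples, not zero burning).
#' Samples outside `[origin, end)` are excluded. The default 25-yr width
#' matches the compilation's median sampling resolution.
#'
#' @param prs_df Tibble with `site_id`, `age_ce`, `prs` (one or many sites).
#' @param bin_width Bin width in years (> 0), default 25.
#' @param origin Grid origin (CE), default 0.
#' @param end Grid end (CE, exclusive), default 2000.
#' @return Tibble with the full grid per site: `site_id`, `bin_start`,
#'   `bin_end`, `prs_mean`, `n_samples`.
#' @examples
#' x <- tibble::tibble(site_id = "a", age_ce = c(1905, 1910, 1930),
#'                     prs = c(10, 20, 60))
#' dplyr::filter(bin_series(x), n_samples > 0)
#' @export
bin_series <- function(prs_df, bin_width = 25, origin = 0, end = 2000) {
  if (bin_width <= 0) abort("`bin_width` must be positive")
  starts <- seq(origin, end - bin_width, by = bin_width)
  grid <- tibble(bin_start = starts, bin_end = starts + bin_width)
  inside <- filter(prs_df, .data$age_ce >= origin, .data$age_ce < end)
  inside <- mutate(inside,
                   bin_start = origin + bin_width *
                     floor((.data$age_ce - origin) / bin_width))
  stats_df <- inside |>
    group_by(.data$site_id, .data$bin_start) |>
    summarise(prs_mean = mean(.data$prs), n_samples = dplyr::n(),
              .groups = "drop")
  tidyr::crossing(site_id = unique(prs_df$site_id), grid) |>
    left_join(stats_df, by = c("site_id", "bin_start")) |>
    mutate(n_samples = dplyr::coalesce(.data$n_samples, 0L)) |>
    arrange(.data$site_id, .data$bin_start)
}

# Local linear smoother weights for one target: tricube kernel over
# |x - target| <= half-window. Returns the linear functional l such that
# yhat(target) = sum(l * y). Falls back to the weighted mean when fewer
# than two points fall in the window or the in-window spread is degenerate.
.lowess_weights <- function(x, target, half) {
  d <- abs(x - target)
  w <- ifelse(d <= half, (1 - (d / half)^3)^3, 0)
  nz <- sum(w > 0)
  if (nz == 0) return(NULL)
  if (nz < 2 || sum(w * (x - mean(x[w > 0]))^2) < 1e-12) {
    return(w / sum(w))
  }
  xc <- x - target
  s0 <- sum(w); s1 <- sum(w * xc); s2 <- sum(w * xc^2)
  det <- s0 * s2 - s1^2
  if (det < 1e-12) return(w / sum(w))
  # intercept of the weighted degree-1 fit evaluated at the target
  (w * (s2 - s1 * xc)) / det
}

# Full smoother matrix: rows are target weights; yhat = S %*% y.
.smoother_matrix <- function(x, targets, window) {
  half <- window / 2
  t(vapply(targets, function(tg) {
    l <- .lowess_weights(x, tg, half)
    if (is.null(l)) rep(NA_real_, length(x)) else l
  }, numeric(length(x))))
}

#' Locally weighted (tricube, locally linear) scatterplot smoother
#'
#' Fits a weighted degree-1 polynomial at each target using tricube
#' weights over a fixed metric window (default 200 yr, i.e. a 100-yr
#' half-window). Exactly reproduces constants and straight lines. Targets
#' with fewer than two in-window points fall back to the tricube-weighted
#' mean; targets with no in-window points give NA. Deterministic.
#'
#' @param x Numeric predictor (years); NA pairs are dropped.
#' @param y Numeric response.
#' @param window Full window width in years (default 200).
#' @param targets Evaluation points (default `x`).
#' @return Numeric vector of smoothed values at `targets`.
#' @export
lowess_smooth <- function(x, y, window = 200, targets = x) {
  if (window <= 0) abort("`window` must be positive")
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) == 0) return(rep(NA_real_, length(targets)))
  if (sum(keep) < 2) {
    warn("fewer than 2 finite points; returning the single value everywhere")
  }
  S <- .smoother_matrix(x[keep], targets, window)
  as.numeric(S %*% y[keep])
}

#' Bootstrap composite burning curve for a group of sites
#'
#' The point curve is the per-bin NA-ignoring mean across sites, smoothed
#' with [lowess_smooth()]. Each bootstrap replicate resamples sites (whole
#' binned records) with replacement, recomputes per-bin means and smooths
#' them identically; the confidence band is the per-target 5% and 95%
#' percentile over `B` replicates (the defaults: 1000 replicates, 5/95
#' limits). Bins with no contributing site are skipped as smoothing
#' targets. Site order does not affect the result: resampling operates on
#' the site list sorted by id.
#'
#' @param binned Output of [bin_series()] for >= 2 sites (one group).
#' @param B Number of bootstrap replicates (default 1000).
#' @param probs Lower/upper band percentiles as probabilities
#'   (default `c(0.05, 0.95)`).
#' @param window Smoothing window in years (default 200).
#' @param seed Integer seed for resampling.
#' @param group Label stored on the result (default "composite").
#' @return A `composite_curve` tibble: `group`, `target_ce` (bin
#'   midpoints), `mean`, `lower`, `upper`, `n_sites` (contributing sites
#'   per bin, from the unresampled group). Attributes record `B`, `probs`,
#'   `window`, `seed`.
#' @export
bootstrap_composite <- function(binned, B = 1000, probs = c(0.05, 0.95),
                                window = 200, seed = 1,
                                group = "composite") {
  sites <- sort(unique(binned$site_id))
  if (length(sites) < 2) {
    abort("composite needs >= 2 sites (a one-site band is undefined)")
  }
  if (B < 1) abort("`B` must be >= 1")
  wide <- binned |>
    arrange(.data$site_id, .data$bin_start) |>
    select("site_id", "bin_start", "prs_mean") |>
    tidyr::pivot_wider(names_from = "bin_start", values_from = "prs_mean") |>
    arrange(.data$site_id)
  M <- as.matrix(wide[, -1, drop = FALSE])
  bin_start <- as.numeric(colnames(M))
  bin_width <- if (length(bin_start) > 1) diff(bin_start)[1] else {
    unique(binned$bin_end - binned$bin_start)[1]
  }
  mids <- bin_start + bin_width / 2
  n_sites_bin <- unname(colSums(!is.na(M)))
  targets <- mids[n_sites_bin > 0]

  col_mean <- function(mat) {
    s <- colSums(mat, na.rm = TRUE)
    k <- colSums(!is.na(mat))
    ifelse(k > 0, s / k, NA_real_)
  }
  # The smoother is linear in y, so a smoother matrix can be reused across
  # replicates sharing the same finite-bin pattern.
  cache <- new.env(parent = emptyenv())
  smooth_vec <- function(y) {
    keep <- is.finite(y)
    if (!any(keep)) return(rep(NA_real_, length(targets)))
    key <- paste(which(keep), collapse = ",")
    S <- cache[[key]]
    if (is.null(S)) {
      S <- .smoother_matrix(mids[keep], targets, window)
      cache[[key]] <- S
    }
    as.numeric(S %*% y[keep])
  }

  point <- smooth_vec(col_mean(M))
  n <- length(sites)
  reps <- with_seed(derive_seed(seed, paste0("boot:", group)), {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
    t(vapply(seq_len(B), function(b) {
      smooth_vec(col_mean(M[idx[b, ], , drop = FALSE]))
    }, numeric(length(targets))))
  })
  qs <- apply(reps, 2, quantile, probs = probs, na.rm = TRUE, names = FALSE)

  structure(
    tibble(group = group, target_ce = targets, mean = point,
           lower = qs[1, ], upper = qs[2, ],
           n_sites = n_sites_bin[n_sites_bin > 0]),
    class = c("composite_curve", "tbl_df", "tbl", "data.frame"),
    B = B, probs = probs, window = window, seed = seed, n_group = n)
}

#' Plot a composite burning curve with its bootstrap band
#'
#' @param object A `composite_curve` from [bootstrap_composite()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composite_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$target_ce)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Calendar year (CE)", y = "Composite PRS",
                  title = "Composite burning curve (bootstrap 5-95% band)") +
    ggplot2::theme_minimal()
}

#' Select landscape sites within a great-circle buffer of peat sites
#'
#' A candidate is retained when its haversine distance (Earth radius
#' 6371 km) to at least one peat site is within `radius_km` (default
#' 800 km, the buffer used to pair wider landscape burning records with
#' the peatland network).
#'
#' @param peat_sites,candidates Site tibbles with `lat`/`lon` in degrees.
#' @param radius_km Buffer radius in km.
#' @return The retained rows of `candidates`, with a `min_dist_km` column.
#' @export
select_landscape_sites <- function(peat_sites, candidates, radius_km = 800) {
  if (nrow(candidates) == 0) return(mutate(candidates, min_dist_km = numeric(0)))
  d <- geosphere::distm(
    as.matrix(candidates[, c("lon", "lat")]),
    as.matrix(peat_sites[, c("lon", "lat")]),
    fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000))
  min_km <- apply(d, 1, min) / 1000
  candidates |>
    mutate(min_dist_km = min_km) |>
    filter(.data$min_dist_km <= radius_km)
}
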