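#' Chronology quality-control rule
#'
#' A core is usable when at least two age controls fall within the last
#' 3000 years (ages at or after `window_start_ce`, default -1000 CE, i.e.
#' 3000 years before 2000 CE), which permits age interpolation over the
#' last two millennia.
#'
#' @param controls Age-control tibble (`depth_cm`, `age_ce`, `sd_yr`).
#' @param window_start_ce Earliest calendar year counted (default -1000).
#' @return Single logical.
#' @export
passes_chronology_qc <- function(controls, window_start_ce = -1000) {
  sum(controls$age_ce >= window_start_ce) >= 2
}

#' Fit a Monte-Carlo piecewise-linear age-depth ensemble
#'
#' Each ensemble draw samples every control age from
#' `Normal(age_ce, sd_yr)` and is accepted only if age strictly decreases
#' with depth (deeper is older); a draw failing 1000 resampling attempts is
#' sorted into monotone order and flagged. Ages between controls are linear
#' interpolations; no extrapolation beyond the outermost controls. The
#' median chronology (per-control-depth median over draws) is the single
#' series used downstream for dating and influx; the full ensemble is kept
#' for uncertainty diagnostics.
#'
#' @param controls Age-control tibble for one site (`depth_cm`, `age_ce`,
#'   `sd_yr`), depths strictly increasing.
#' @param n_draws Ensemble size (default 200).
#' @param seed Integer seed.
#' @param qc Apply [passes_chronology_qc()] first (default TRUE).
#' @return An object of class `age_model`: list with `site_id`, `depth`
#'   (control depths), `draws` (n_draws x n_controls matrix of ages CE),
#'   `median_age` (per-depth medians), `n_flagged` (draws forced monotone
#'   by sorting), `n_draws`, `seed`.
#' @examples
#' ctrl <- tibble::tibble(site_id = "a", depth_cm = c(0, 100),
#'                        age_ce = c(2000, 0), sd_yr = c(1, 30))
#' m <- fit_age_model(ctrl, n_draws = 50, seed = 1)
#' age_at_depth(m, 50)
#' @export
fit_age_model <- function(controls, n_draws = 200, seed = 1, qc = TRUE) {
  controls <- arrange(as_tibble(controls), .data$depth_cm)
  if (nrow(controls) < 2) {
    abort("age model needs at least 2 controls")
  }
  if (qc && !passes_chronology_qc(controls)) {
    abort(paste("chronology QC failed: fewer than two age controls in the",
                "last 3000 years"))
  }
  k <- nrow(controls)
  with_seed(derive_seed(seed, paste0("agemodel:", controls$site_id[1])), {
    draws <- matrix(NA_real_, n_draws, k)
    pending <- rep(TRUE, n_draws)
    flagged <- rep(FALSE, n_draws)
    for (attempt in seq_len(1000)) {
      if (!any(pending)) break
      m <- sum(pending)
      cand <- matrix(rnorm(m * k, mean = rep(controls$age_ce, each = m),
                           sd = rep(controls$sd_yr, each = m)), m, k)
      ok <- apply(cand, 1, function(a) all(diff(a) < 0))
      idx <- which(pending)
      draws[idx[ok], ] <- cand[ok, , drop = FALSE]
      pending[idx[ok]] <- FALSE
    }
    if (any(pending)) {
      # persistent non-monotone draws: sort into age order and flag
      idx <- which(pending)
      m <- length(idx)
      cand <- matrix(rnorm(m * k, mean = rep(controls$age_ce, each = m),
                           sd = rep(controls$sd_yr, each = m)), m, k)
      draws[idx, ] <- t(apply(cand, 1, sort, decreasing = TRUE))
      flagged[idx] <- TRUE
    }
    structure(
      list(site_id = controls$site_id[1], depth = controls$depth_cm,
           draws = draws, median_age = apply(draws, 2, median),
           n_flagged = sum(flagged), n_draws = n_draws, seed = seed),
      class = "age_model")
  })
}

#' @export
print.age_model <- function(x, ...) {
  cat("<age_model> site", x$site_id, "-", length(x$depth), "controls,",
      x$n_draws, "draws,", x$n_flagged, "flagged\n")
  invisible(x)
}

#' Interpolate ages from the median chronology
#'
#' @param model An [fit_age_model()] object.
#' @param depth Depths (cm); values outside the outermost controls give NA
#'   (no extrapolation) with a warning.
#' @param draw Optional draw index to interpolate a single ensemble member
#'   instead of the median chronology.
#' @return Numeric vector of ages (CE).
#' @export
age_at_depth <- function(model, depth, draw = NULL) {
  ages <- if (is.null(draw)) model$median_age else model$draws[draw, ]
  out <- stats::approx(model$depth, ages, xout = depth, rule = 1)$y
  if (anyNA(out)) {
    warn(sprintf("%d depth(s) outside the modelled range [%g, %g] cm return NA",
                 sum(is.na(out)), min(model$depth), max(model$depth)))
  }
  out
}

#' Accumulation rate at a depth (median across the ensemble)
#'
#' Within each draw the rate over the segment containing `depth` is
#' segment thickness divided by elapsed years; the median over draws is
#' returned. Always positive for monotone draws.
#'
#' @param model An [fit_age_model()] object.
#' @param depth Depths (cm) within the modelled range.
#' @return Numeric vector of rates (cm/yr).
#' @export
accumulation_rate <- function(model, depth) {
  rng <- range(model$depth)
  if (any(depth < rng[1] | depth > rng[2])) {
    abort(sprintf("depth outside modelled range [%g, %g] cm", rng[1], rng[2]))
  }
  k <- length(model$depth)
  seg <- pmin(pmax(findInterval(depth, model$depth, rightmost.closed = TRUE),
                   1L), k - 1L)
  d_depth <- diff(model$depth)
  # per-draw elapsed years over each segment: age decreases with depth
  d_age <- model$draws[, seq_len(k - 1L), drop = FALSE] -
    model$draws[, -1L, drop = FALSE]
  rate_draws <- sweep(1 / d_age, 2, d_depth, `*`)
  med <- apply(rate_draws, 2, median)
  med[seg]
}

#' @rdname fit_age_model
#' @param x An `age_model` object.
#' @param ... Unused.
#' @return `tidy()`: tibble of control depths with median, 5% and 95%
#'   ensemble ages. `glance()`: one-row summary.
#' @export
tidy.age_model <- function(x, ...) {
  tibble(site_id = x$site_id, depth_cm = x$depth,
         age_ce_median = x$median_age,
         age_ce_q05 = apply(x$draws, 2, quantile, 0.05),
         age_ce_q95 = apply(x$draws, 2, quantile, 0.95))
}

#' @rdname fit_age_model
#' @export
glance.age_model <- function(x, ...) {
  tibble(site_id = x$site_id, n_controls = length(x$depth),
         n_draws = x$n_draws, n_flagged = x$n_flagged,
         span_yr = x$median_age[1] - x$median_age[length(x$median_age)])
}
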