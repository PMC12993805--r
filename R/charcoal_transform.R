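#' Convert charcoal concentrations to influx using an age model
#'
#' Influx (particles cm^-2 yr^-1) is concentration (particles cm^-3) times
#' the accumulation rate (cm yr^-1) of the age-model segment containing the
#' sample's midpoint depth; sample ages come from the median chronology at
#' the midpoint. Samples outside the modelled depth range are dropped with
#' a warning giving the count. A series already in influx units passes
#' through unchanged apart from dating.
#'
#' @param charcoal One site's charcoal tibble (`site_id`, `depth_top_cm`,
#'   `depth_bottom_cm`, `value`, `unit`).
#' @param model The site's [fit_age_model()] object.
#' @return Tibble with `site_id`, `depth_cm` (midpoint), `age_ce`, `influx`.
#' @examples
#' ctrl <- tibble::tibble(site_id = "a", depth_cm = c(0, 100),
#'                        age_ce = c(2000, 0), sd_yr = c(1e-9, 1e-9))
#' m <- fit_age_model(ctrl, n_draws = 10, seed = 1)
#' cc <- tibble::tibble(site_id = "a", depth_top_cm = 9.5,
#'                      depth_bottom_cm = 10.5, value = 10,
#'                      unit = "concentration")
#' concentration_to_influx(cc, m)  # influx = 10 * 0.05 = 0.5
#' @export
concentration_to_influx <- function(charcoal, model) {
  unit <- unique(charcoal$unit)
  if (length(unit) != 1L) abort("series must carry a single unit flag")
  mid <- (charcoal$depth_top_cm + charcoal$depth_bottom_cm) / 2
  rng <- range(model$depth)
  inside <- mid >= rng[1] & mid <= rng[2]
  if (!any(inside)) {
    abort(sprintf("site %s: no samples overlap the modelled depth range",
                  charcoal$site_id[1]))
  }
  if (any(!inside)) {
    warn(sprintf("site %s: dropped %d sample(s) outside the modelled range",
                 charcoal$site_id[1], sum(!inside)))
  }
  mid <- mid[inside]
  value <- charcoal$value[inside]
  age <- stats::approx(model$depth, model$median_age, xout = mid)$y
  influx <- if (unit == "concentration") {
    value * accumulation_rate(model, mid)
  } else {
    value
  }
  tibble(site_id = charcoal$site_id[inside], depth_cm = mid, age_ce = age,
         influx = influx)
}

#' Proportional relative scaling (PRS) of a charcoal influx record
#'
#' The PRS transform maps a record's influx values onto a 0-100 scale,
#' down-weighted by the record's proportion of charcoal-bearing samples:
#' `prs_i = (c_i / c_max) * 100 * (f / N)` where `c_max` is the record
#' maximum, `f` the number of positive values and `N` the record length.
#' An all-zero record maps to all zeros. The transform is invariant to
#' rescaling all influxes by a positive constant.
#'
#' @param influx Non-negative numeric vector (one record).
#' @return Numeric vector of PRS values in \[0, 100\], with attributes
#'   `f`, `N` and `c_max`.
#' @examples
#' prs_transform(c(0, 2, 4))  # 0, 33.33, 66.67
#' @export
prs_transform <- function(influx) {
  if (any(is.na(influx))) abort("influx must not contain NA")
  if (any(influx < 0)) abort("influx must be non-negative")
  N <- length(influx)
  if (N < 1) abort("record must contain at least one value")
  f <- sum(influx > 0)
  c_max <- max(influx)
  prs <- if (f == 0) rep(0, N) else (influx / c_max) * 100 * (f / N)
  structure(prs, f = f, N = N, c_max = if (f == 0) 0 else c_max)
}

#' Add a PRS column to a multi-site influx table
#'
#' Applies [prs_transform()] record-wise (per site). The proportion of
#' positives `f/N` and the maximum are taken over the full record by
#' default; set `window` to restrict the transform to samples dated within
#' a calendar window first.
#'
#' @param influx_df Tibble with `site_id`, `age_ce`, `influx`.
#' @param window Optional `c(start_ce, end_ce)`; samples outside are
#'   dropped before transforming.
#' @return The (possibly windowed) tibble with a `prs` column.
#' @export
add_prs <- function(influx_df, window = NULL) {
  if (!is.null(window)) {
    influx_df <- filter(influx_df, .data$age_ce >= window[1],
                        .data$age_ce <= window[2])
  }
  influx_df |>
    group_by(.data$site_id) |>
    mutate(prs = as.numeric(prs_transform(.data$influx))) |>
    ungroup()
}

#' Median PRS over a calendar window, and the cube-root transform
#'
#' The site-level burning status statistic: the median of PRS values whose
#' ages fall in `window`, optionally cube-root transformed (the variance
#' stabilisation used before regression and ordination).
#'
#' @param prs_df Tibble with `age_ce` and `prs` (one site).
#' @param window `c(start_ce, end_ce)`, closed interval.
#' @param cube_root Return the cube root of the median (default FALSE).
#' @return Single number; NA with a warning when the window is empty.
#' @export
median_prs <- function(prs_df, window = c(0, 2000), cube_root = FALSE) {
  v <- prs_df$prs[prs_df$age_ce >= window[1] & prs_df$age_ce <= window[2]]
  if (length(v) == 0) {
    warn("no samples in the requested window; returning NA")
    return(NA_real_)
  }
  m <- median(v)
  if (cube_root) cube_root(m) else m
}

#' Cube root (defined for non-negative values)
#' @param x Non-negative numeric.
#' @return `x^(1/3)`.
#' @export
cube_root <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("cube_root expects non-negative input")
  x^(1 / 3)
}
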