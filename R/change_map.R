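#' Twentieth-century change in burning per site
#'
#' For each site the mean PRS over the recent window (1900-2000 CE,
#' inclusive) is contrasted against the prior window (0-1900 CE, 1900
#' exclusive): `delta = mean_recent - mean_prior`, and `relative = delta /
#' mean over the whole period (0-2000 CE)`. Sites lacking samples in
#' either window are excluded and listed with a reason (the compilation
#' retains only sites with data in both periods). Window means use raw
#' dated samples, not bins.
#'
#' @param prs_df Tibble with `site_id`, `age_ce`, `prs` (many sites).
#' @param recent,prior,whole Calendar windows; recent and whole are
#'   closed, prior is closed-open so 1900 CE belongs to the recent window
#'   only.
#' @param classify Add the `signal_class` column via [classify_change()]
#'   (default TRUE).
#' @return A tibble (`site_id`, `mean_recent`, `mean_prior`, `delta`,
#'   `relative`, and `signal_class` when requested) with an `excluded`
#'   attribute tibble (`site_id`, `reason`).
#' @examples
#' x <- tibble::tibble(site_id = "a", age_ce = c(500, 1000, 1950),
#'                     prs = c(10, 10, 30))
#' period_change(x)
#' @export
period_change <- function(prs_df, recent = c(1900, 2000),
                          prior = c(0, 1900), whole = c(0, 2000),
                          classify = TRUE) {
  per_site <- prs_df |>
    group_by(.data$site_id) |>
    summarise(
      n_recent = sum(.data$age_ce >= recent[1] & .data$age_ce <= recent[2]),
      n_prior = sum(.data$age_ce >= prior[1] & .data$age_ce < prior[2]),
      mean_recent = mean(.data$prs[.data$age_ce >= recent[1] &
                                     .data$age_ce <= recent[2]]),
      mean_prior = mean(.data$prs[.data$age_ce >= prior[1] &
                                    .data$age_ce < prior[2]]),
      mean_whole = mean(.data$prs[.data$age_ce >= whole[1] &
                                    .data$age_ce <= whole[2]]),
      .groups = "drop")
  excluded <- per_site |>
    filter(.data$n_recent == 0 | .data$n_prior == 0) |>
    mutate(reason = dplyr::case_when(
      n_recent == 0 & n_prior == 0 ~ "no samples in either window",
      n_recent == 0 ~ "no samples in 1900-2000 window",
      TRUE ~ "no samples in 0-1900 window")) |>
    select("site_id", "reason")
  out <- per_site |>
    filter(.data$n_recent > 0, .data$n_prior > 0) |>
    mutate(delta = .data$mean_recent - .data$mean_prior,
           relative = ifelse(.data$mean_whole > 0,
                             .data$delta / .data$mean_whole, NA_real_)) |>
    select("site_id", "mean_recent", "mean_prior", "delta", "relative")
  if (classify) out <- mutate(out, signal_class = classify_change(.data$delta))
  attr(out, "excluded") <- excluded
  out
}

#' Signal classes for 20th-century change, ordered negative to positive
#' @export
signal_class_levels <- c(
  "extremely strong negative", "strong negative", "negative",
  "weak negative", "no change", "weak positive", "positive",
  "strong positive", "extremely strong positive")

#' Classify a 20th-century change value into the eight signal classes
#'
#' Classes on delta (mean PRS 1900-2000 minus mean PRS 0-1900): greater
#' than 50 extremely strong positive; (15, 50\] strong positive; (5, 15\]
#' positive; (0, 5\] weak positive; exactly 0 no change; \[-5, 0) weak
#' negative; \[-15, -5) negative; \[-50, -15) strong negative. Intervals
#' are closed on the side away from zero. Values below -50 (outside the
#' published table) are classified "extremely strong negative" by
#' symmetry.
#'
#' @param delta Numeric vector; NA stays unclassified (NA).
#' @return Ordered factor with levels [signal_class_levels].
#' @examples
#' classify_change(c(60, 20, 10, 2, 0, -2, -7, -20))
#' @export
classify_change <- function(delta) {
  lab <- dplyr::case_when(
    is.na(delta) ~ NA_character_,
    delta > 50 ~ "extremely strong positive",
    delta > 15 ~ "strong positive",
    delta > 5 ~ "positive",
    delta > 0 ~ "weak positive",
    delta == 0 ~ "no change",
    delta >= -5 ~ "weak negative",
    delta >= -15 ~ "negative",
    delta >= -50 ~ "strong negative",
    TRUE ~ "extremely strong negative")
  factor(lab, levels = signal_class_levels, ordered = TRUE)
}

#' Plot the per-site change map as a signal-class dot chart
#'
#' A geographic scatter (longitude/latitude) coloured by signal class; a
#' lightweight stand-in for a map figure that needs no basemap data.
#'
#' @param change Output of [period_change()] joined to site coordinates
#'   (`lat`, `lon` columns present).
#' @return A ggplot object.
#' @export
plot_change_map <- function(change) {
  stopifnot(all(c("lat", "lon", "signal_class") %in% names(change)))
  ggplot2::ggplot(change, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       colour = .data$signal_class)) +
    ggplot2::geom_point(size = 3, alpha = 0.9) +
    ggplot2::scale_colour_brewer(palette = "RdBu", direction = -1,
                                 drop = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  colour = "20th-century signal",
                  title = "Change in peatland burning, 1900-2000 vs 0-1900 CE") +
    ggplot2::theme_minimal()
}
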