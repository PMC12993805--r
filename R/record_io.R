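#' Read the site, charcoal and age-control tables
#'
#' Expects three UTF-8 comma-delimited files with documented headers:
#' `sites.csv` (site_id, region, ecosystem, lat, lon, elevation_m,
#' footprint, om_pct, c_pct, is_peat), `charcoal.csv` (site_id,
#' depth_top_cm, depth_bottom_cm, value, unit) and `age_controls.csv`
#' (site_id, depth_cm, age_ce, sd_yr). All tables are validated with
#' [validate_site_tables()] before being returned.
#'
#' @param dir Directory holding the three files, or a named list/vector
#'   with elements `sites`, `charcoal`, `age_controls` giving paths.
#' @return A named list of tibbles: `sites`, `charcoal`, `age_controls`.
#' @export
read_site_tables <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    list(sites = file.path(dir, "sites.csv"),
         charcoal = file.path(dir, "charcoal.csv"),
         age_controls = file.path(dir, "age_controls.csv"))
  } else {
    as.list(dir)[c("sites", "charcoal", "age_controls")]
  }
  missing <- !purrr::map_lgl(paths, file.exists)
  if (any(missing)) {
    abort(sprintf("input file not found: %s",
                  paste(unlist(paths[missing]), collapse = ", ")))
  }
  tabs <- list(
    sites = readr::read_csv(paths$sites, show_col_types = FALSE),
    charcoal = readr::read_csv(paths$charcoal, show_col_types = FALSE),
    age_controls = readr::read_csv(paths$age_controls, show_col_types = FALSE))
  validate_site_tables(tabs$sites, tabs$charcoal, tabs$age_controls)
  tabs
}

#' Write the site, charcoal and age-control tables
#'
#' Inverse of [read_site_tables()]; the round trip is lossless for the
#' documented columns (a `regime` list-column on synthetic site tables is
#' dropped on write).
#'
#' @param tables Named list with `sites`, `charcoal`, `age_controls`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_site_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- tables$sites
  sites <- sites[, setdiff(names(sites), c("regime")), drop = FALSE]
  readr::write_csv(sites, file.path(dir, "sites.csv"))
  readr::write_csv(tables$charcoal, file.path(dir, "charcoal.csv"))
  readr::write_csv(tables$age_controls, file.path(dir, "age_controls.csv"))
  invisible(dir)
}

site_schema <- list(
  sites = c("site_id", "region", "ecosystem", "lat", "lon", "elevation_m",
            "footprint"),
  charcoal = c("site_id", "depth_top_cm", "depth_bottom_cm", "value", "unit"),
  age_controls = c("site_id", "depth_cm", "age_ce", "sd_yr"))

#' Validate the three input tables against the schema and join rules
#'
#' Checks required columns, uniqueness of `site_id` in the site table,
#' that every charcoal series and age-control set joins to a site, that
#' depths strictly increase within each series/control set, that charcoal
#' values are non-negative with one unit flag per series, and that control
#' uncertainties are positive. Malformed rows are reported with their row
#' numbers.
#'
#' @param sites,charcoal,age_controls The three tibbles.
#' @return Invisibly `TRUE`; aborts with an informative message otherwise.
#' @export
validate_site_tables <- function(sites, charcoal, age_controls) {
  for (nm in names(site_schema)) {
    tab <- switch(nm, sites = sites, charcoal = charcoal,
                  age_controls = age_controls)
    miss <- setdiff(site_schema[[nm]], names(tab))
    if (length(miss) > 0) {
      abort(sprintf("%s table is missing column(s): %s", nm,
                    paste(miss, collapse = ", ")))
    }
  }
  if (anyDuplicated(sites$site_id)) {
    abort(sprintf("duplicate site_id in sites table: %s",
                  sites$site_id[duplicated(sites$site_id)][1]))
  }
  bad_region <- setdiff(unique(sites$region), c(realm_labels, "unknown"))
  if (length(bad_region) > 0) {
    abort(sprintf("unknown region label: %s", paste(bad_region, collapse = ", ")))
  }
  for (nm in c("charcoal", "age_controls")) {
    tab <- if (nm == "charcoal") charcoal else age_controls
    orphan <- setdiff(unique(tab$site_id), sites$site_id)
    if (length(orphan) > 0) {
      abort(sprintf("%s table references unknown site_id: %s", nm,
                    paste(orphan, collapse = ", ")))
    }
  }
  neg <- which(charcoal$value < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative charcoal value at row(s): %s",
                  paste(utils::head(neg, 5), collapse = ", ")))
  }
  bad_unit <- which(!charcoal$unit %in% c("concentration", "influx"))
  if (length(bad_unit) > 0) {
    abort(sprintf("unit must be 'concentration' or 'influx'; bad row(s): %s",
                  paste(utils::head(bad_unit, 5), collapse = ", ")))
  }
  multi_unit <- charcoal |>
    group_by(.data$site_id) |>
    summarise(k = dplyr::n_distinct(.data$unit), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(multi_unit) > 0) {
    abort(sprintf("series with mixed units: %s",
                  paste(multi_unit$site_id, collapse = ", ")))
  }
  check_monotone <- function(tab, col, label) {
    bad <- tab |>
      mutate(.row = row_number()) |>
      group_by(.data$site_id) |>
      filter(c(FALSE, diff(.data[[col]]) <= 0)) |>
      ungroup()
    if (nrow(bad) > 0) {
      abort(sprintf("%s depths must strictly increase; offending row(s): %s",
                    label, paste(utils::head(bad$.row, 5), collapse = ", ")))
    }
  }
  check_monotone(charcoal, "depth_top_cm", "charcoal")
  check_monotone(age_controls, "depth_cm", "age_controls")
  if (any(age_controls$sd_yr <= 0)) {
    abort(sprintf("age-control sd_yr must be > 0; offending row(s): %s",
                  paste(utils::head(which(age_controls$sd_yr <= 0), 5),
                        collapse = ", ")))
  }
  invisible(TRUE)
}

#' Apply the peat-layer inclusion criterion
#'
#' A site passes when its organic-matter content is at least 30%, or
#' failing that when its carbon content is at least 15%. When neither
#' measurement is available the published description (`is_peat` flag) is
#' used as a fallback. The reason column records which rule fired.
#'
#' @param sites Site tibble with optional `om_pct`, `c_pct`, `is_peat`.
#' @param om_threshold,c_threshold Percent thresholds (defaults 30 and 15).
#' @return The input with logical `peat_pass` and character `peat_reason`
#'   columns added.
#' @examples
#' passes_peat_criterion(tibble::tibble(site_id = "a", om_pct = 35,
#'   c_pct = NA, is_peat = FALSE))
#' @export
passes_peat_criterion <- function(sites, om_threshold = 30, c_threshold = 15) {
  om <- if ("om_pct" %in% names(sites)) sites$om_pct else NA_real_
  cc <- if ("c_pct" %in% names(sites)) sites$c_pct else NA_real_
  flag <- if ("is_peat" %in% names(sites)) sites$is_peat else NA
  n <- nrow(sites)
  om <- rep_len(om, n); cc <- rep_len(cc, n); flag <- rep_len(flag, n)
  pass <- rep(FALSE, n)
  reason <- rep("no evidence of peat", n)
  use_flag <- is.na(om) & is.na(cc)
  pass[use_flag & !is.na(flag) & flag] <- TRUE
  reason[use_flag & !is.na(flag) & flag] <- "publication description"
  hit_c <- !use_flag & !is.na(cc) & cc >= c_threshold
  pass[hit_c] <- TRUE
  reason[hit_c] <- sprintf("carbon %.4g%% >= %g%%", cc[hit_c], c_threshold)
  hit_om <- !is.na(om) & om >= om_threshold
  pass[hit_om] <- TRUE
  reason[hit_om] <- sprintf("organic matter %.4g%% >= %g%%", om[hit_om],
                            om_threshold)
  mutate(sites, peat_pass = pass, peat_reason = reason)
}

#' Tropical-latitude inclusion rule
#'
#' A site is tropical when its absolute latitude is at most 30 degrees
#' (closed interval), or when it is explicitly allowlisted — the mechanism
#' for retaining valuable sites just outside the band.
#'
#' @param sites Site tibble with `lat` and `site_id`.
#' @param allowlist Character vector of site_ids always included.
#' @return Logical vector, one element per site.
#' @export
in_tropics <- function(sites, allowlist = character()) {
  abs(sites$lat) <= 30 | sites$site_id %in% allowlist
}
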