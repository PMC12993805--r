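#' Pipeline configuration with the compilation's default settings
#'
#' Defaults reproduce the synthesis settings: 25-yr bins over 0-2000 CE,
#' 200-yr locally weighted smoothing, 1000 bootstrap replicates with 5/95
#' percentile limits, an 800-km landscape buffer, period contrast
#' 1900-2000 vs 0-1900 CE, analysis periods 0-850 / 850-1900 / 1900-2000
#' CE, correlation screens 0.25 (regression) and 0.8 (collinearity), and
#' the MBIC-style change-point penalty.
#'
#' @param bin_width Bin width, years.
#' @param smooth_window Smoothing window, years.
#' @param bootstrap_reps Bootstrap replicates.
#' @param percentiles Band probabilities `c(low, high)`.
#' @param buffer_km Landscape buffer radius, km.
#' @param window Analysis window `c(start, end)` CE.
#' @param periods List of period windows (CE) for per-period statistics.
#' @param recent,prior Windows of the 20th-century contrast.
#' @param n_draws Age-model ensemble size.
#' @param penalty Change-point penalty (number or "MBIC").
#' @param min_composite_sites Smallest group composited (default 5; a
#'   handful of sites cannot support a regional curve, which is why the
#'   Oceanian realm never receives one).
#' @param r_keep,r_collinear,p_stay Regression screening thresholds.
#' @param covariates Character vector of site-table covariate columns to
#'   feed the regression protocol, or NULL.
#' @param tropics_allowlist Site ids retained despite |lat| > 30.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_width = 25, smooth_window = 200,
                            bootstrap_reps = 1000,
                            percentiles = c(0.05, 0.95), buffer_km = 800,
                            window = c(0, 2000),
                            periods = list(c(0, 850), c(850, 1900),
                                           c(1900, 2000)),
                            recent = c(1900, 2000), prior = c(0, 1900),
                            n_draws = 200, penalty = "MBIC",
                            min_composite_sites = 5,
                            r_keep = 0.25, r_collinear = 0.8, p_stay = 0.05,
                            covariates = NULL,
                            tropics_allowlist = character()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full charcoal-synthesis pipeline
#'
#' Orchestrates ingestion QC -> chronologies -> influx -> PRS ->
#' composites -> change-points -> 20th-century change map -> site
#' statistics. Sites are excluded (with a logged reason) when they fail
#' the tropics rule, the peat criterion, the two-controls-in-3000-yr
#' chronology rule, or lack samples in either contrast window; included
#' plus excluded always accounts for every input site.
#'
#' @param tables Named list with `sites`, `charcoal`, `age_controls`
#'   tibbles (e.g. from [read_site_tables()] or [synth_study()]).
#' @param config A [pipeline_config()].
#' @param seed Integer seed governing all randomness (age models and
#'   bootstraps derive per-stream seeds from it).
#' @param group_by Site columns to composite over (default region and
#'   ecosystem).
#' @return A list of class `peatfire_run`: `chronologies`, `prs`
#'   (dated/transformed samples), `binned`, `composites` (named list of
#'   `composite_curve`), `changepoints` (tibble), `change_map`,
#'   `summaries`, `stats` (Kruskal-Wallis/ANOVA tables, optional
#'   regression reports), `excluded`, `manifest`.
#' @examples
#' \donttest{
#' study <- synth_study(n_sites = 8, seed = 2)
#' run <- run_pipeline(study, pipeline_config(bootstrap_reps = 50), seed = 2)
#' run$manifest$n_included
#' }
#' @export
run_pipeline <- function(tables, config = pipeline_config(), seed = 1,
                         group_by = c("region", "ecosystem")) {
  stopifnot(inherits(config, "pipeline_config"))
  sites <- tables$sites
  charcoal <- tables$charcoal
  controls <- tables$age_controls
  validate_site_tables(sites, charcoal, controls)

  # --- inclusion rules ------------------------------------------------
  excl <- list()
  tropical <- in_tropics(sites, config$tropics_allowlist)
  excl$tropics <- tibble(site_id = sites$site_id[!tropical],
                         reason = "outside 30N-30S and not allowlisted")
  peat <- passes_peat_criterion(sites)
  excl$peat <- tibble(site_id = sites$site_id[tropical & !peat$peat_pass],
                      reason = "fails peat criterion (30% OM / 15% C)")
  ok_ids <- sites$site_id[tropical & peat$peat_pass]
  qc_pass <- vapply(ok_ids, function(id) {
    passes_chronology_qc(filter(controls, .data$site_id == id))
  }, logical(1))
  excl$chronology <- tibble(
    site_id = ok_ids[!qc_pass],
    reason = "fewer than two age controls in the last 3000 years")
  ok_ids <- ok_ids[qc_pass]
  if (length(ok_ids) == 0) abort("stage inclusion: no site passes QC")

  # --- chronologies and transforms ------------------------------------
  models <- purrr::map(ok_ids, function(id) {
    fit_age_model(filter(controls, .data$site_id == id),
                  n_draws = config$n_draws, seed = seed)
  })
  names(models) <- ok_ids
  prs_df <- purrr::map_dfr(ok_ids, function(id) {
    infl <- concentration_to_influx(filter(charcoal, .data$site_id == id),
                                    models[[id]])
    mutate(infl, prs = as.numeric(prs_transform(.data$influx)))
  })
  chronologies <- purrr::map_dfr(models, tidy)

  # --- composites and change-points -----------------------------------
  binned <- bin_series(prs_df, bin_width = config$bin_width,
                       origin = config$window[1], end = config$window[2])
  site_meta <- select(sites, all_of(c("site_id", intersect(group_by,
                                                           names(sites)))))
  composites <- list()
  for (gv in intersect(group_by, names(sites))) {
    labs <- split(site_meta$site_id, site_meta[[gv]])
    for (lab in names(labs)) {
      ids <- intersect(labs[[lab]], ok_ids)
      if (length(ids) < config$min_composite_sites) next
      key <- paste(gv, lab, sep = ":")
      composites[[key]] <- bootstrap_composite(
        filter(binned, .data$site_id %in% ids),
        B = config$bootstrap_reps, probs = config$percentiles,
        window = config$smooth_window, seed = seed, group = key)
    }
  }
  if (length(ok_ids) >= config$min_composite_sites) {
    composites[["all"]] <- bootstrap_composite(
      binned, B = config$bootstrap_reps, probs = config$percentiles,
      window = config$smooth_window, seed = seed, group = "all")
  }
  changepoints <- purrr::map_dfr(composites, function(cc) {
    fit <- changepoint_on_composite(cc, penalty = config$penalty)
    tidy(fit) |> mutate(group = cc$group[1], .before = 1)
  })

  # --- change map -----------------------------------------------------
  change <- period_change(prs_df, recent = config$recent,
                          prior = config$prior, whole = config$window)
  excl$window <- attr(change, "excluded")
  change <- left_join(change, site_meta, by = "site_id")

  # --- site summaries and statistics ----------------------------------
  summaries <- prs_df |>
    group_by(.data$site_id) |>
    summarise(median_prs = median(.data$prs[.data$age_ce >= config$window[1] &
                                              .data$age_ce <= config$window[2]]),
              .groups = "drop") |>
    mutate(median_prs_cuberoot = cube_root(.data$median_prs)) |>
    left_join(select(sites, -dplyr::any_of("regime")), by = "site_id") |>
    mutate(elevation_group = assign_elevation_group(.data$elevation_m),
           footprint_class = assign_footprint_class(
             pmin(.data$footprint, 50)))
  for (i in seq_along(config$periods)) {
    p <- config$periods[[i]]
    col <- sprintf("median_prs_cuberoot_%g_%g", p[1], p[2])
    per <- prs_df |>
      group_by(.data$site_id) |>
      summarise(v = {
        x <- .data$prs[.data$age_ce >= p[1] & .data$age_ce <= p[2]]
        if (length(x) == 0) NA_real_ else cube_root(median(x))
      }, .groups = "drop")
    summaries[[col]] <- per$v[match(summaries$site_id, per$site_id)]
  }

  stats_out <- list()
  if (dplyr::n_distinct(change$region) >= 2) {
    stats_out$kw_region_delta <- kw_test(change, "delta", "region")
  }
  for (gv in c("ecosystem", "elevation_group", "footprint_class")) {
    sub <- summaries[!is.na(summaries[[gv]]), ]
    if (dplyr::n_distinct(sub[[gv]]) >= 2) {
      stats_out[[paste0("kw_", gv)]] <-
        kw_test(sub, "median_prs_cuberoot", gv)
      counts <- table(sub[[gv]])
      if (sum(counts > 0) >= 2 && nrow(sub) > length(counts)) {
        stats_out[[paste0("anova_", gv)]] <-
          anova_oneway(sub, "median_prs_cuberoot", gv)
      }
    }
  }
  if (!is.null(config$covariates) &&
      all(config$covariates %in% names(summaries)) &&
      nrow(summaries) > length(config$covariates) + 2) {
    stats_out$pca <- pca_climate(summaries, config$covariates)
    stats_out$regression <- screen_and_regress(
      summaries, "median_prs_cuberoot", config$covariates,
      r_keep = config$r_keep, r_collinear = config$r_collinear,
      p_stay = config$p_stay)
    for (i in seq_along(config$periods)) {
      p <- config$periods[[i]]
      col <- sprintf("median_prs_cuberoot_%g_%g", p[1], p[2])
      sub <- summaries[!is.na(summaries[[col]]), ]
      if (nrow(sub) > length(config$covariates) + 2) {
        stats_out[[sprintf("regression_%g_%g", p[1], p[2])]] <-
          screen_and_regress(sub, col, config$covariates,
                             r_keep = config$r_keep,
                             r_collinear = config$r_collinear,
                             p_stay = config$p_stay)
      }
    }
  }

  excluded <- bind_rows(excl)
  manifest <- list(
    seed = seed,
    config = unclass(config),
    n_input = nrow(sites), n_included = length(ok_ids),
    n_excluded = nrow(excluded),
    included = ok_ids,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  stopifnot(manifest$n_included + manifest$n_excluded == manifest$n_input +
              nrow(excl$window))

  structure(
    list(chronologies = chronologies, prs = prs_df, binned = binned,
         composites = composites, changepoints = changepoints,
         change_map = change, summaries = summaries, stats = stats_out,
         excluded = excluded, manifest = manifest),
    class = "peatfire_run")
}

#' @export
print.peatfire_run <- function(x, ...) {
  cat("<peatfire_run>", x$manifest$n_included, "of", x$manifest$n_input,
      "sites included;", length(x$composites), "composites;",
      nrow(x$change_map), "sites in the change map\n")
  if (nrow(x$changepoints) > 0) {
    sig <- x$changepoints[x$changepoints$significant, ]
    if (nrow(sig) > 0) {
      cat("  significant change-points:",
          paste(sprintf("%s @ %g CE", sig$group, round(sig$tau_year)),
                collapse = "; "), "\n")
    }
  }
  invisible(x)
}

#' Run the pipeline from and to directories of delimited-text tables
#'
#' Reads the three input tables from `in_dir`, runs [run_pipeline()], and
#' writes `chronologies.csv`, `series.csv`, `composite.csv`,
#' `changepoints.csv`, `change_map.csv`, `summaries.csv`,
#' `exclusions.csv`, and (when jsonlite is installed) `stats_report.json`
#' and `manifest.json` into `out_dir`.
#'
#' @param in_dir Input directory (see [read_site_tables()]).
#' @param out_dir Output directory, created if needed.
#' @inheritParams run_pipeline
#' @return The `peatfire_run` object, invisibly.
#' @export
run_pipeline_dir <- function(in_dir, out_dir, config = pipeline_config(),
                             seed = 1) {
  run <- run_pipeline(read_site_tables(in_dir), config = config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$chronologies, file.path(out_dir, "chronologies.csv"))
  readr::write_csv(run$prs, file.path(out_dir, "series.csv"))
  readr::write_csv(bind_rows(lapply(run$composites, as_tibble)),
                   file.path(out_dir, "composite.csv"))
  readr::write_csv(run$changepoints, file.path(out_dir, "changepoints.csv"))
  readr::write_csv(run$change_map, file.path(out_dir, "change_map.csv"))
  readr::write_csv(select(run$summaries, -dplyr::any_of("regime")),
                   file.path(out_dir, "summaries.csv"))
  readr::write_csv(run$excluded, file.path(out_dir, "exclusions.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    simple <- purrr::map(run$stats, function(s) {
      if (inherits(s, "prs_screen")) {
        list(variables = s$variables, coefficients = tidy(s),
             fit = glance(s))
      } else if (inherits(s, "climate_pca")) {
        list(var_explained = s$var_explained, loadings = s$loadings)
      } else s
    })
    jsonlite::write_json(simple, file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(run)
}
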