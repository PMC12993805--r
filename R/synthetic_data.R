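#' Fire-regime specification for synthetic charcoal records
#'
#' A regime describes the generative model for one site's charcoal influx:
#' a log-normal baseline, step-change multipliers at known calendar years,
#' a linear per-century trend multiplier, Poisson fire-event pulses, and
#' Bernoulli zero-inflation. The synthetic generator draws observed influx
#' as `exp(baseline_log_mean + baseline_log_sd * eps) * steps(t) * trend(t)
#' * pulse_scale^k`, then masks a fraction of samples to zero.
#'
#' @param baseline_log_mean Log of the baseline influx level
#'   (log particles cm^-2 yr^-1).
#' @param baseline_log_sd Log-scale multiplicative noise standard deviation.
#' @param zero_prob Probability that a sample records zero charcoal, in
#'   \[0, 1\]. Zero-inflation is applied after all multiplicative terms.
#' @param event_rate Expected fire-event pulses per 1000 years; each pulse
#'   multiplies one sample's influx by `pulse_scale`.
#' @param pulse_scale Multiplicative magnitude of a fire-event pulse (> 0).
#' @param breaks Step changes as a data frame with columns `year` (CE) and
#'   `multiplier` (> 0), or `NULL` for none. Multipliers of all breaks with
#'   `year <= t` apply at time `t`.
#' @param trend Linear multiplier per century: influx at year `t` is scaled
#'   by `1 + (trend - 1) * t / 100` (floored at 1e-6). `trend = 1` (the
#'   default) means no trend.
#'
#' @return An object of class `regime_spec` (a named list).
#' @examples
#' regime_spec(zero_prob = 0.3, breaks = data.frame(year = 1900, multiplier = 5))
#' @export
regime_spec <- function(baseline_log_mean = log(5), baseline_log_sd = 0.7,
                        zero_prob = 0.2, event_rate = 2, pulse_scale = 10,
                        breaks = NULL, trend = 1) {
  check_number(baseline_log_mean, "baseline_log_mean")
  check_number(baseline_log_sd, "baseline_log_sd", lower = 0)
  check_number(zero_prob, "zero_prob", lower = 0, upper = 1)
  check_number(event_rate, "event_rate", lower = 0)
  check_number(pulse_scale, "pulse_scale", lower = 1e-12)
  check_number(trend, "trend", lower = 1e-12)
  if (!is.null(breaks)) {
    breaks <- as_tibble(breaks)
    if (!all(c("year", "multiplier") %in% names(breaks))) {
      abort("`breaks` needs columns `year` and `multiplier`")
    }
    if (any(breaks$multiplier <= 0)) abort("break multipliers must be > 0")
    breaks <- arrange(breaks, .data$year)
  }
  structure(
    list(baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         zero_prob = zero_prob, event_rate = event_rate,
         pulse_scale = pulse_scale, breaks = breaks, trend = trend),
    class = "regime_spec")
}

#' @export
print.regime_spec <- function(x, ...) {
  cat("<regime_spec> baseline exp(", round(x$baseline_log_mean, 3),
      " +/- ", round(x$baseline_log_sd, 3), "), zero_prob ", x$zero_prob,
      ", events/kyr ", x$event_rate, " x", x$pulse_scale, "\n", sep = "")
  if (!is.null(x$breaks)) {
    cat("  breaks:", paste(sprintf("x%g @ %g CE", x$breaks$multiplier,
                                   x$breaks$year), collapse = ", "), "\n")
  }
  invisible(x)
}

# Deterministic noise-free regime mean at calendar years t (CE).
regime_mean <- function(regime, t) {
  base <- exp(regime$baseline_log_mean)
  step <- rep(1, length(t))
  if (!is.null(regime$breaks)) {
    for (i in seq_len(nrow(regime$breaks))) {
      step <- step * ifelse(t >= regime$breaks$year[i],
                            regime$breaks$multiplier[i], 1)
    }
  }
  tr <- pmax(1 + (regime$trend - 1) * t / 100, 1e-6)
  base * step * tr
}

#' Biogeographic realms used to stratify synthetic sites
#' @export
realm_labels <- c("Neotropical", "Afrotropical", "Indomalayan",
                  "Australasian", "Oceanian")

#' Ecosystem (peatland type) labels
#' @export
ecosystem_labels <- c("cushion_sedge", "hardwood_swamp", "palm_swamp", "other")

# Coordinate boxes and default regimes per realm. Indomalayan and
# Australasian sites default to a x5 step increase at 1900 CE; Neotropical
# and Afrotropical to a x0.5 decrease, matching the regional contrast the
# generator is meant to emulate. Oceanian sites carry no break.
realm_defaults <- function(region) {
  box <- switch(region,
    Neotropical  = list(lat = c(-20, 10),  lon = c(-80, -50)),
    Afrotropical = list(lat = c(-15, 10),  lon = c(10, 40)),
    Indomalayan  = list(lat = c(-5, 20),   lon = c(95, 120)),
    Australasian = list(lat = c(-20, 0),   lon = c(120, 150)),
    Oceanian     = list(lat = c(-20, -10), lon = c(160, 179)))
  brk <- switch(region,
    Indomalayan  = ,
    Australasian = tibble(year = 1900, multiplier = 5),
    Neotropical  = ,
    Afrotropical = tibble(year = 1900, multiplier = 0.5),
    Oceanian     = NULL)
  list(box = box, breaks = brk,
       change_year = if (is.null(brk)) NA_real_ else 1900)
}

#' Generate a stratified set of synthetic peatland sites
#'
#' Region counts follow largest-remainder rounding of `region_mix`, so a
#' mix of 16/15/16/8/3 over 58 sites reproduces those counts exactly. Each
#' site receives coordinates inside its realm's bounding box, an elevation
#' drawn from a lowland/upland/highland mixture, an ecosystem label
#' (cushion/sedge peat above 1500 m), a human-footprint value, and a
#' [regime_spec()] with the realm's default 20th-century break.
#'
#' @param n_sites Number of sites (>= 1).
#' @param region_mix Named numeric vector of realm proportions summing to 1.
#'   Names must be among [realm_labels].
#' @param seed Integer seed; the full site table is deterministic given it.
#' @return A tibble with one row per site: `site_id`, `region`, `ecosystem`,
#'   `lat`, `lon`, `elevation_m`, `footprint`, `om_pct`, `c_pct`, `is_peat`,
#'   `regime` (list-column of [regime_spec()]), `true_change_year`.
#' @examples
#' synth_sites(6, c(Neotropical = 0.5, Indomalayan = 0.5), seed = 1)
#' @export
synth_sites <- function(n_sites,
                        region_mix = c(Neotropical = 16, Afrotropical = 15,
                                       Indomalayan = 16, Australasian = 8,
                                       Oceanian = 3) / 58,
                        seed = 1) {
  check_number(n_sites, "n_sites", lower = 1)
  bad <- setdiff(names(region_mix), realm_labels)
  if (length(bad) > 0) {
    abort(sprintf("unknown region label in `region_mix`: %s",
                  paste(bad, collapse = ", ")))
  }
  if (is.null(names(region_mix)) || any(!nzchar(names(region_mix)))) {
    abort("`region_mix` must be a named vector of realm proportions")
  }
  if (any(region_mix < 0)) {
    abort(sprintf("negative proportion for label %s",
                  names(region_mix)[which(region_mix < 0)[1]]))
  }
  if (abs(sum(region_mix) - 1) > 1e-9) {
    abort(sprintf("`region_mix` proportions sum to %.6f, not 1",
                  sum(region_mix)))
  }

  # largest-remainder apportionment
  quota <- n_sites * region_mix
  counts <- floor(quota)
  left <- n_sites - sum(counts)
  if (left > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }

  regions <- rep(names(counts), counts)
  purrr::map_dfr(seq_along(regions), function(i) {
    region <- regions[i]
    site_id <- sprintf("S%03d", i)
    def <- realm_defaults(region)
    with_seed(derive_seed(seed, paste0("site:", site_id)), {
      lat <- runif(1, def$box$lat[1], def$box$lat[2])
      lon <- runif(1, def$box$lon[1], def$box$lon[2])
      band <- sample.int(3, 1, prob = c(0.6, 0.2, 0.2))
      elevation <- switch(band, runif(1, 0, 500), runif(1, 500, 1500),
                          runif(1, 1500, 4200))
      ecosystem <- if (elevation > 1500) "cushion_sedge" else {
        sample(c("hardwood_swamp", "palm_swamp", "other"), 1,
               prob = c(0.5, 0.3, 0.2))
      }
      footprint <- round(runif(1, 0, 20), 2)
      om <- round(runif(1, 35, 95), 1)
      regime <- regime_spec(
        baseline_log_mean = log(5) + rnorm(1, 0, 0.3),
        baseline_log_sd = 0.7, zero_prob = 0.2, event_rate = 2,
        pulse_scale = 10, breaks = def$breaks)
      tibble(site_id = site_id, region = region, ecosystem = ecosystem,
             lat = lat, lon = lon, elevation_m = elevation,
             footprint = footprint, om_pct = om, c_pct = NA_real_,
             is_peat = TRUE, regime = list(regime),
             true_change_year = def$change_year)
    })
  })
}

#' Simulate one peat core: age controls, charcoal series, and ground truth
#'
#' Builds a true chronology from piecewise-constant accumulation rates
#' (log-normal per segment, rescaled so the core spans `span_yr` years,
#' which guarantees coverage of the last 3000 years with the default
#' range), places `n_age_controls` controls evenly in depth including the
#' core top (whose age is the collection year, known exactly), perturbs
#' control ages with Gaussian noise, and draws charcoal concentrations as
#' regime-driven influx divided by the local accumulation rate.
#'
#' @param site One row of a [synth_sites()] tibble (or any list with
#'   `site_id` and `regime`).
#' @param depth_cm Core depth in cm (> 0).
#' @param sample_step_cm Sampling interval thickness in cm (> 0).
#' @param n_age_controls Number of age controls (>= 1).
#' @param age_sd_yr 1-sigma uncertainty applied to non-top control ages.
#' @param collection_year Calendar year CE of coring; the core-top age.
#' @param span_yr Range from which the core's total time span is drawn
#'   (uniform); default 3200-4800 yr gives ~25-35 yr sample resolution at
#'   1-cm steps over 150 cm.
#' @param seed Integer seed (per-core stream derived from it).
#' @return A list with `age_controls` (tibble: site_id, depth_cm, age_ce,
#'   sd_yr), `charcoal` (tibble: site_id, depth_top_cm, depth_bottom_cm,
#'   value, unit = "concentration"), and `truth` (tibble of per-sample
#'   depth, true age, time span, accumulation rate, noise-free regime mean
#'   influx `influx_true`, realised influx `influx_obs`) plus
#'   `true_change_year` as an attribute of `truth`.
#' @export
synth_core <- function(site, depth_cm = 150, sample_step_cm = 1,
                       n_age_controls = 5, age_sd_yr = 30,
                       collection_year = 2000, span_yr = c(3200, 4800),
                       seed = 1) {
  if (depth_cm <= 0 || sample_step_cm <= 0) {
    abort("`depth_cm` and `sample_step_cm` must be positive")
  }
  check_number(n_age_controls, "n_age_controls", lower = 1)
  regime <- if (is.list(site$regime) && inherits(site$regime[[1]], "regime_spec")) {
    site$regime[[1]]
  } else {
    site$regime
  }
  site_id <- site$site_id[[1]]

  with_seed(derive_seed(seed, paste0("core:", site_id)), {
    ctrl_depth <- seq(0, depth_cm, length.out = max(n_age_controls, 2))
    n_seg <- length(ctrl_depth) - 1

    # segment accumulation rates: log-normal around 0.05 cm/yr, rescaled so
    # the whole core spans `span` years
    rate <- exp(log(0.05) + rnorm(n_seg, 0, 0.4))
    seg_len <- diff(ctrl_depth)
    span <- runif(1, span_yr[1], span_yr[2])
    rate <- rate * sum(seg_len / rate) / span

    ctrl_age_true <- collection_year - c(0, cumsum(seg_len / rate))

    n_samp <- floor(depth_cm / sample_step_cm)
    top <- (seq_len(n_samp) - 1) * sample_step_cm
    bottom <- top + sample_step_cm
    mid <- (top + bottom) / 2
    seg <- pmin(findInterval(mid, ctrl_depth, rightmost.closed = TRUE), n_seg)
    rate_i <- rate[seg]
    age_mid <- stats::approx(ctrl_depth, ctrl_age_true, xout = mid)$y
    dt_i <- sample_step_cm / rate_i

    mu <- regime_mean(regime, age_mid)
    noise <- exp(rnorm(n_samp, 0, regime$baseline_log_sd))
    pulses <- rpois(n_samp, regime$event_rate * dt_i / 1000)
    nonzero <- rbinom(n_samp, 1, 1 - regime$zero_prob)
    influx_obs <- mu * noise * regime$pulse_scale^pulses * nonzero
    concentration <- influx_obs / rate_i

    controls <- tibble(
      site_id = site_id, depth_cm = ctrl_depth,
      age_ce = ctrl_age_true + c(0, rnorm(n_seg, 0, age_sd_yr)),
      sd_yr = c(1, rep(age_sd_yr, n_seg)))
    if (n_age_controls == 1) controls <- controls[1, ]

    truth <- tibble(site_id = site_id, depth_cm = mid, age_ce = age_mid,
                    dt_yr = dt_i, rate_cm_yr = rate_i, influx_true = mu,
                    influx_obs = influx_obs)
    attr(truth, "true_change_year") <- site$true_change_year[[1]] %||% NA_real_

    list(
      age_controls = controls,
      charcoal = tibble(site_id = site_id, depth_top_cm = top,
                        depth_bottom_cm = bottom, value = concentration,
                        unit = "concentration"),
      truth = truth)
  })
}

#' Generate a full synthetic study: sites, cores, and truth tables
#'
#' The `"tropical-58"` preset draws 58 sites split 16/15/16/8/3 across the
#' Neotropical, Afrotropical, Indomalayan, Australasian and Oceanian
#' realms, with 3-10 age controls per core and the realm-default
#' 20th-century regime breaks.
#'
#' @param n_sites Number of sites.
#' @param seed Integer seed controlling every draw.
#' @param preset Currently only `"tropical-58"`.
#' @param out_dir If non-NULL, the four tables are written there as
#'   `sites.csv`, `charcoal.csv`, `age_controls.csv`, `truth.csv`.
#' @return A list of tibbles: `sites` (without the regime list-column when
#'   written), `charcoal`, `age_controls`, `truth`.
#' @examples
#' study <- synth_study(n_sites = 6, seed = 1)
#' names(study)
#' @export
synth_study <- function(n_sites = 58, seed = 1, preset = "tropical-58",
                        out_dir = NULL) {
  preset <- match.arg(preset)
  sites <- synth_sites(n_sites, seed = seed)
  cores <- purrr::map(seq_len(nrow(sites)), function(i) {
    n_ctrl <- with_seed(derive_seed(seed, paste0("nctrl:", sites$site_id[i])),
                        sample(3:10, 1))
    synth_core(sites[i, ], n_age_controls = n_ctrl, seed = seed)
  })
  charcoal <- purrr::map_dfr(cores, "charcoal")
  age_controls <- purrr::map_dfr(cores, "age_controls")
  truth <- purrr::map_dfr(cores, "truth")
  out <- list(sites = sites, charcoal = charcoal,
              age_controls = age_controls, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_site_tables(out, out_dir)
    truth_flat <- left_join(
      truth,
      select(sites, "site_id", "true_change_year"), by = "site_id")
    readr::write_csv(truth_flat, file.path(out_dir, "truth.csv"))
  }
  out
}
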