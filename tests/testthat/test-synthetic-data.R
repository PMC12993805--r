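test_that("region counts follow largest-remainder rounding of the mix", {
  s4 <- synth_sites(4, c(Neotropical = 0.5, Indomalayan = 0.5), seed = 1)
  expect_equal(unname(table(s4$region)[c("Neotropical", "Indomalayan")]),
               c(2L, 2L), ignore_attr = TRUE)

  s58 <- synth_sites(58, seed = 7)
  expect_equal(
    as.integer(table(s58$region)[c("Neotropical", "Afrotropical",
                                   "Indomalayan", "Australasian",
                                   "Oceanian")]),
    c(16L, 15L, 16L, 8L, 3L))
})

test_that("invalid region mixes are rejected with the offending label", {
  expect_error(synth_sites(4, c(Neotropical = 0.5, Atlantis = 0.5), seed = 1),
               "Atlantis")
  expect_error(synth_sites(4, c(Neotropical = 0.6, Indomalayan = 0.6),
                           seed = 1), "sum")
})

test_that("site and core generation are deterministic given the seed", {
  a <- synth_sites(12, seed = 42)
  b <- synth_sites(12, seed = 42)
  expect_identical(a, b)
  core1 <- synth_core(a[1, ], seed = 42)
  core2 <- synth_core(a[1, ], seed = 42)
  expect_identical(core1, core2)
  # serialisation round trip is byte-identical
  s1 <- serialize(synth_study(n_sites = 4, seed = 5), NULL)
  s2 <- serialize(synth_study(n_sites = 4, seed = 5), NULL)
  expect_identical(s1, s2)
})

test_that("cores have the requested geometry and a monotone chronology", {
  site <- synth_sites(1, c(Neotropical = 1), seed = 3)
  core <- synth_core(site, depth_cm = 100, sample_step_cm = 1,
                     n_age_controls = 5, age_sd_yr = 30, seed = 3)
  expect_equal(nrow(core$charcoal), 100)
  expect_equal(nrow(core$age_controls), 5)
  expect_true(all(diff(core$truth$age_ce) < 0))
  # spans at least the last 3000 years with >= 2 controls
  expect_lt(min(core$truth$age_ce), -1000)
  expect_error(synth_core(site, depth_cm = -1, seed = 1), "positive")
})

test_that("a zero_prob = 1 regime yields an all-zero record", {
  site <- synth_sites(1, c(Neotropical = 1), seed = 3)
  site$regime[[1]] <- regime_spec(zero_prob = 1)
  core <- synth_core(site, seed = 1)
  expect_true(all(core$charcoal$value == 0))
})

test_that("charcoal mass is conserved between influx and concentration", {
  sites <- synth_sites(3, seed = 11)
  for (i in 1:3) {
    core <- synth_core(sites[i, ], seed = 11)
    mass_conc <- sum(core$charcoal$value *
                       (core$charcoal$depth_bottom_cm -
                          core$charcoal$depth_top_cm))
    mass_flux <- sum(core$truth$influx_obs * core$truth$dt_yr)
    expect_equal(mass_conc, mass_flux, tolerance = 1e-9)
  }
})

test_that("a x5 break at 1900 CE raises mean influx by a factor of 5", {
  site <- synth_sites(1, c(Indomalayan = 1), seed = 1)
  site$regime[[1]] <- regime_spec(
    zero_prob = 0, event_rate = 0,
    breaks = data.frame(year = 1900, multiplier = 5))
  ratios <- vapply(1:500, function(s) {
    core <- synth_core(site, seed = s)
    tr <- core$truth
    post <- tr$influx_obs[tr$age_ce >= 1900]
    pre <- tr$influx_obs[tr$age_ce >= 1400 & tr$age_ce < 1900]
    mean(post) / mean(pre)
  }, numeric(1))
  expect_equal(mean(ratios, na.rm = TRUE), 5, tolerance = 0.1)
})
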