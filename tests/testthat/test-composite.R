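test_that("binning assigns samples by age and averages within bins", {
  x <- tibble::tibble(site_id = "a", age_ce = c(1905, 1910, 1930),
                      prs = c(10, 20, 60))
  b <- bin_series(x)
  expect_equal(b$prs_mean[b$bin_start == 1900], 15)
  expect_equal(b$prs_mean[b$bin_start == 1925], 60)
  # empty bins carry NA, not zero
  expect_true(is.na(b$prs_mean[b$bin_start == 1950]))
  expect_equal(sum(b$n_samples), 3)
})

test_that("one sample per bin makes binning the identity on values", {
  ages <- seq(12.5, 487.5, by = 25)
  x <- tibble::tibble(site_id = "a", age_ce = ages, prs = seq_along(ages))
  b <- dplyr::filter(bin_series(x, end = 500), n_samples > 0)
  expect_equal(b$prs_mean, as.numeric(seq_along(ages)))
})

test_that("binning conserves the dated samples inside the window", {
  set.seed(5)
  x <- tibble::tibble(site_id = "a", age_ce = runif(200, -100, 2100),
                      prs = runif(200, 0, 50))
  b <- bin_series(x)
  expect_equal(sum(b$n_samples), sum(x$age_ce >= 0 & x$age_ce < 2000))
})

test_that("the smoother reproduces constants and straight lines exactly", {
  x <- seq(0, 2000, by = 25)
  expect_equal(lowess_smooth(x, rep(3.7, length(x))), rep(3.7, length(x)),
               tolerance = 1e-9)
  y <- 2 + 0.01 * x
  expect_equal(lowess_smooth(x, y), y, tolerance = 1e-9)
})

test_that("smoothing a step is monotone across the jump", {
  x <- seq(0, 2000, by = 25)
  y <- as.numeric(x >= 1000)
  s <- lowess_smooth(x, y)
  expect_true(all(diff(s) >= -1e-12))
  expect_true(all(s >= -1e-9 & s <= 1 + 1e-9))
})

make_binned <- function(values_by_site) {
  purrr::imap_dfr(values_by_site, function(v, id) {
    starts <- seq(0, by = 25, length.out = length(v))
    tibble::tibble(site_id = id, bin_start = starts, bin_end = starts + 25,
                   prs_mean = v, n_samples = ifelse(is.na(v), 0L, 1L))
  })
}

test_that("identical constant sites give a zero-width band equal to the mean", {
  b <- make_binned(list(a = rep(4, 40), b = rep(4, 40), c = rep(4, 40)))
  cc <- bootstrap_composite(b, B = 200, seed = 1)
  expect_equal(cc$mean, rep(4, 40), tolerance = 1e-9)
  expect_equal(cc$lower, rep(4, 40), tolerance = 1e-9)
  expect_equal(cc$upper, rep(4, 40), tolerance = 1e-9)
  expect_equal(cc$n_sites, rep(3L, 40))
})

test_that("two-site toy band stays inside the site range", {
  b <- make_binned(list(a = rep(0, 40), b = rep(10, 40)))
  cc <- bootstrap_composite(b, B = 1000, seed = 2)
  expect_equal(cc$mean, rep(5, 40), tolerance = 1e-9)
  expect_true(all(cc$lower >= -1e-9 & cc$upper <= 10 + 1e-9))
  expect_true(all(cc$lower <= cc$mean + 1e-9 & cc$mean <= cc$upper + 1e-9))
})

test_that("a single-site group is refused", {
  b <- make_binned(list(a = rep(1, 10)))
  expect_error(bootstrap_composite(b, B = 10, seed = 1), ">= 2 sites")
})

test_that("site order does not change the composite", {
  set.seed(7)
  vals <- purrr::map(1:6, ~ runif(40, 0, 20))
  names(vals) <- paste0("s", 1:6)
  b1 <- make_binned(vals)
  b2 <- dplyr::arrange(b1, dplyr::desc(site_id), bin_start)
  c1 <- bootstrap_composite(b1, B = 300, seed = 3)
  c2 <- bootstrap_composite(b2, B = 300, seed = 3)
  expect_equal(as.data.frame(c1), as.data.frame(c2), tolerance = 1e-12)
})

test_that("landscape buffer selection follows haversine distance", {
  peat <- tibble::tibble(site_id = "p", lat = 0, lon = 0)
  cand <- tibble::tibble(site_id = c("same", "far", "lat7.2"),
                         lat = c(0, 40, 7.2), lon = c(0, 60, 0))
  kept <- select_landscape_sites(peat, cand, radius_km = 800)
  # 7.2 deg of latitude is ~800.6 km: excluded at an 800-km radius
  expect_equal(kept$site_id, "same")
  kept2 <- select_landscape_sites(peat, cand, radius_km = 801)
  expect_setequal(kept2$site_id, c("same", "lat7.2"))
  expect_equal(kept2$min_dist_km[kept2$site_id == "lat7.2"],
               7.2 * pi / 180 * 6371, tolerance = 1e-6)
})
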