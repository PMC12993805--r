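test_that("influx is concentration times the segment accumulation rate", {
  m <- fit_age_model(
    tibble::tibble(site_id = "a", depth_cm = c(0, 100),
                   age_ce = c(2000, 0), sd_yr = 1e-12),
    n_draws = 10, seed = 1)
  cc <- tibble::tibble(site_id = "a", depth_top_cm = c(9.5, 49.5),
                       depth_bottom_cm = c(10.5, 50.5), value = c(10, 0),
                       unit = "concentration")
  out <- concentration_to_influx(cc, m)
  expect_equal(out$influx, c(0.5, 0), tolerance = 1e-9)
  expect_equal(out$age_ce, c(1800, 1000), tolerance = 1e-9)
})

test_that("two-segment cores use the rate of the containing segment", {
  m <- fit_age_model(
    tibble::tibble(site_id = "a", depth_cm = c(0, 50, 100),
                   age_ce = c(2000, 1000, -2000), sd_yr = 1e-12),
    n_draws = 10, seed = 1)
  cc <- tibble::tibble(site_id = "a", depth_top_cm = c(19.5, 59.5, 79.5),
                       depth_bottom_cm = c(20.5, 60.5, 80.5),
                       value = c(10, 6, 3), unit = "concentration")
  out <- concentration_to_influx(cc, m)
  expect_equal(out$influx, c(10 * 0.05, 6 * 50 / 3000, 3 * 50 / 3000),
               tolerance = 1e-9)
})

test_that("influx-unit series pass through unchanged and samples outside the
          model are dropped with a count", {
  m <- fit_age_model(
    tibble::tibble(site_id = "a", depth_cm = c(0, 100),
                   age_ce = c(2000, 0), sd_yr = 1e-12),
    n_draws = 10, seed = 1)
  cc <- tibble::tibble(site_id = "a", depth_top_cm = c(9.5, 119.5),
                       depth_bottom_cm = c(10.5, 120.5), value = c(7, 7),
                       unit = "influx")
  expect_warning(out <- concentration_to_influx(cc, m), "dropped 1")
  expect_equal(out$influx, 7)
  cc_out <- dplyr::mutate(cc, depth_top_cm = c(149.5, 159.5),
                          depth_bottom_cm = c(150.5, 160.5))
  expect_error(concentration_to_influx(cc_out, m), "overlap")
})

test_that("PRS reproduces the record-wise scaling formula", {
  p <- prs_transform(c(0, 2, 4))
  expect_equal(as.numeric(p), c(0, 100 / 3, 200 / 3), tolerance = 1e-12)
  expect_equal(attr(p, "f"), 2)
  expect_equal(attr(p, "N"), 3)
  expect_equal(attr(p, "c_max"), 4)

  expect_equal(as.numeric(prs_transform(rep(5, 4))), rep(100, 4))
  z <- prs_transform(c(0, 0))
  expect_equal(as.numeric(z), c(0, 0))
  expect_equal(attr(z, "c_max"), 0)
  expect_error(prs_transform(c(-1, 2)), "non-negative")
})

test_that("PRS is scale invariant and obeys the max and range identities", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(3:60, 1)
    x <- rexp(n) * sample(c(0, 1), n, replace = TRUE, prob = c(0.3, 0.7))
    p <- as.numeric(prs_transform(x))
    expect_true(all(p >= 0 & p <= 100))
    f <- sum(x > 0)
    if (f > 0) {
      expect_equal(max(p), 100 * f / n, tolerance = 1e-9)
      k <- runif(1, 0.01, 100)
      expect_equal(as.numeric(prs_transform(k * x)), p, tolerance = 1e-9)
    }
    expect_identical(p == 0, x == 0)
  }
})

test_that("appending a zero sample shrinks nonzero PRS by f/(N+1) / (f/N)", {
  x <- c(3, 0, 7, 1)  # f = 3, N = 4
  p0 <- as.numeric(prs_transform(x))
  p1 <- as.numeric(prs_transform(c(x, 0)))  # f = 3, N = 5
  shrink <- (3 / 5) / (3 / 4)
  expect_lt(shrink, 1)
  expect_equal(p1[which(x > 0)], p0[which(x > 0)] * shrink,
               tolerance = 1e-12)
})

test_that("median PRS and its cube root evaluate over calendar windows", {
  df <- tibble::tibble(age_ce = c(500, 1000, 1500),
                       prs = c(0, 100 / 3, 200 / 3))
  expect_equal(median_prs(df), 100 / 3, tolerance = 1e-9)
  expect_equal(median_prs(df, cube_root = TRUE), 3.2183, tolerance = 1e-4)
  expect_equal(median_prs(df, window = c(900, 1100)), 100 / 3)
  two <- tibble::tibble(age_ce = c(1910, 1990), prs = c(10, 30))
  expect_equal(median_prs(two, window = c(1900, 2000)), 20)
  expect_warning(out <- median_prs(df, window = c(1800, 1900)), "window")
  expect_true(is.na(out))
})

test_that("add_prs transforms record-wise across sites", {
  df <- tibble::tibble(site_id = rep(c("a", "b"), each = 3),
                       age_ce = rep(c(100, 200, 300), 2),
                       influx = c(0, 2, 4, 5, 5, 5))
  out <- add_prs(df)
  expect_equal(out$prs, c(0, 100 / 3, 200 / 3, 100, 100, 100),
               tolerance = 1e-12)
})
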