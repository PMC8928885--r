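test_that("circle radius conversion matches closed form and round-trips", {
  expect_equal(radius_from_area(pi), 1000)
  # inverse property: area of a circle of radius r maps back to round(r)
  for (r in c(10, 57, 136, 1140, 9999, 1e5)) {
    expect_equal(radius_from_area(pi * r^2 / 1e6), round(r))
  }
  expect_error(radius_from_area(0), class = "partmigr_validation_error")
  expect_error(radius_from_area(-1), class = "partmigr_validation_error")
})

test_that("range baseline threshold is the sum of the two rounded radii", {
  b <- range_baseline(2, 0.5)
  expect_equal(b$threshold, radius_from_area(2) + radius_from_area(0.5))
})

test_that("spike filter applies the consecutive-distance rule", {
  # equally spaced collinear track: no interior fix can be flagged
  out <- filter_gps_outliers(c(0, 100, 200, 300), rep(0, 4))
  expect_length(out$flagged, 0)
  expect_equal(out$retained, 1:4)
  # classic spike: 1000 > 2 * 50
  out <- filter_gps_outliers(c(0, 1000, 50), c(0, 0, 0))
  expect_equal(out$flagged, 2L)
  expect_equal(out$retained, c(1L, 3L))
  expect_error(filter_gps_outliers(c(0, 1), c(0, 0)), class = "partmigr_validation_error")
  expect_error(
    filter_gps_outliers(c(0, 1, 2), c(0, 0, 0), timestamps = c(3, 2, 1)),
    class = "partmigr_validation_error"
  )
})

test_that("spike filter agrees with exhaustive triple evaluation on random tracks", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      x <- cumsum(rnorm(n, 0, 50))
      y <- cumsum(rnorm(n, 0, 50))
      expect_equal(filter_gps_outliers(x, y)$flagged, oracle_outlier_flags(x, y))
    }
  })
})

test_that("injected GPS spikes are exactly recovered by the filter", {
  cfg <- sim_config(outlier_rate = 0.05, outlier_multiplier = 20)
  tr <- withr::with_seed(7, simulate_gps_track(c(0, 0), cfg, n_fixes = 500))
  flt <- filter_gps_outliers(tr$fixes$x_m, tr$fixes$y_m, tr$fixes$datetime)
  expect_equal(flt$flagged, tr$outlier_idx)
  # injected count is plausible under (thinned) Bernoulli(0.05) sampling
  expect_gt(length(tr$outlier_idx), 8)
  expect_lt(length(tr$outlier_idx), 45)
  # no injection -> no flags on a clean confined track
  cfg0 <- sim_config(outlier_rate = 0)
  tr0 <- withr::with_seed(8, simulate_gps_track(c(0, 0), cfg0, n_fixes = 500))
  expect_length(tr0$outlier_idx, 0)
  expect_length(filter_gps_outliers(tr0$fixes$x_m, tr0$fixes$y_m)$flagged, 0)
})

test_that("mcp retains the nearest fixes and returns the hull area", {
  # unit square in km
  sq <- mcp(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000), percent = 100)
  expect_equal(sq$area_km2, 1)
  # 10 fixes on a 100 m circle plus one 10 km away; 95% drops the far fix
  th <- 2 * pi * (0:9) / 10
  x <- c(100 * cos(th), 10000)
  y <- c(100 * sin(th), 0)
  m <- mcp(x, y, percent = 95)
  expect_equal(sort(m$retained), 1:10)
  expect_equal(nrow(m$vertices), 10) # regular decagon
  expect_equal(m$area_km2, oracle_mcp_area_km2(x, y, 95))
  # collinear points: degenerate geometry error carrying area 0
  err <- tryCatch(mcp(c(0, 1, 2), c(0, 1, 2)), condition = function(c) c)
  expect_s3_class(err, "partmigr_degenerate_geometry")
  expect_equal(err$area_km2, 0)
})

test_that("mcp agrees with brute-force distance ranking on random point sets", {
  withr::with_seed(55, {
    for (rep in 1:25) {
      n <- sample(5:15, 1)
      x <- rnorm(n, 0, 300)
      y <- rnorm(n, 0, 300)
      pct <- sample(c(50, 75, 90, 95, 100), 1)
      got <- tryCatch(mcp(x, y, pct)$area_km2, condition = function(c) c$area_km2)
      expect_equal(got, oracle_mcp_area_km2(x, y, pct), tolerance = 1e-12)
    }
  })
})

test_that("mcp area is non-decreasing in percent and hull contains retained fixes", {
  withr::with_seed(56, {
    x <- rnorm(40, 0, 500)
    y <- rnorm(40, 0, 500)
    areas <- vapply(c(50, 70, 90, 95, 100), function(p) mcp(x, y, p)$area_km2, numeric(1))
    expect_true(all(diff(areas) >= 0))
    m <- mcp(x, y, 95)
    vx <- m$vertices$x
    vy <- m$vertices$y
    nv <- length(vx)
    for (i in m$retained) { # inside-or-on test against every CCW hull edge
      cross <- (vx[c(2:nv, 1)] - vx) * (y[i] - vy) - (vy[c(2:nv, 1)] - vy) * (x[i] - vx)
      expect_true(all(cross >= -1e-6))
    }
  })
})

test_that("summer baseline is the median per-bird hull area", {
  # one bird: right triangle with 100 m legs -> 0.005 km^2
  one <- tibble::tibble(bird_id = "a", x_m = c(0, 100, 0), y_m = c(0, 0, 100))
  expect_equal(summer_baseline(one)$median_km2, 0.005)
  # three birds with hull areas 0.02, 0.058, 0.1 km^2 -> median 0.058
  tri <- function(id, area_km2) {
    tibble::tibble(bird_id = id, x_m = c(0, 200, 0), y_m = c(0, 0, area_km2 * 1e6 / 100))
  }
  three <- dplyr::bind_rows(tri("a", 0.02), tri("b", 0.058), tri("c", 0.1))
  expect_equal(summer_baseline(three)$median_km2, 0.058)
  # even count: midpoint of the central pair
  four <- dplyr::bind_rows(tri("a", 0.02), tri("b", 0.04), tri("c", 0.06), tri("d", 0.1))
  expect_equal(summer_baseline(four)$median_km2, 0.05)
  # birds with < 3 fixes are excluded; none eligible -> error
  expect_error(
    summer_baseline(tibble::tibble(bird_id = "a", x_m = c(0, 1), y_m = c(0, 1))),
    class = "partmigr_validation_error"
  )
})

test_that("fix scatter calibration reproduces the configured 95% MCP area", {
  # design target: mean 95% MCP area over 200 simulated 100-fix seasons
  # within 5% of the configured baseline
  sd_w <- partmigr:::scatter_sd_for_area(4.08)
  areas <- withr::with_seed(77, replicate(200, {
    mcp(rnorm(100, 0, sd_w), rnorm(100, 0, sd_w), 95)$area_km2
  }))
  expect_lt(abs(mean(areas) / 4.08 - 1), 0.05)
})
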