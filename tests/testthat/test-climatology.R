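make_cube <- function(values_fun, lon = c(130, 130.1), lat = c(26, 26.1),
                      from = "2001-01-01", to = "2002-12-31") {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  vals <- array(NA_real_, c(length(lat), length(lon), length(dates)))
  for (t in seq_along(dates)) vals[, , t] <- values_fun(dates[t])
  sst_cube(vals, lon, lat, dates)
}

test_that("monthly aggregation is the plain arithmetic mean of available days", {
  cube <- make_cube(function(d) 28)
  monthly <- monthly_aggregate(cube)
  expect_true(all(monthly$values == 28))
  expect_equal(length(monthly$year), 24)

  # January alternating 27/29: 16 odd days at 27, 15 even days at 29
  cube2 <- make_cube(function(d) {
    if (format(d, "%m") == "01") {
      if (as.integer(format(d, "%d")) %% 2 == 1) 27 else 29
    } else 25
  }, from = "2001-01-01", to = "2001-12-31")
  m2 <- monthly_aggregate(cube2)
  expect_equal(m2$values[1, 1, 1], (16 * 27 + 15 * 29) / 31)
})

test_that("months with insufficient coverage are flagged missing, not zero", {
  cube <- make_cube(function(d) 28, from = "2001-01-01", to = "2001-03-31")
  cube$values[1, 1, 32:59] <- NA   # all of February at one cell
  m <- monthly_aggregate(cube)
  expect_true(is.na(m$values[1, 1, 2]))
  expect_false(is.na(m$values[2, 2, 2]))
  expect_error(monthly_aggregate(sst_cube(array(1, c(1, 1, 0)), 1, 1,
                                          as.Date(character()))), "empty")
})

test_that("product harmonization recovers month-dependent biases", {
  fine <- monthly_aggregate(make_cube(function(d) 27))
  # identical products: zero correction
  same <- harmonize_products(fine, fine, overlap = c(2001, 2002))
  expect_equal(same$values, fine$values)

  # uniform -0.3 offset: corrected equals the fine values
  coarse <- fine
  coarse$values <- fine$values - 0.3
  corr <- harmonize_products(coarse, fine, overlap = c(2001, 2002))
  expect_equal(corr$values, fine$values)

  # month-dependent offset {Jan: +0.2, Jul: -0.1} recovered per month
  coarse2 <- fine
  off <- ifelse(fine$month == 1, 0.2, ifelse(fine$month == 7, -0.1, 0))
  for (i in seq_along(off)) coarse2$values[, , i] <- fine$values[, , i] + off[i]
  corr2 <- harmonize_products(coarse2, fine, overlap = c(2001, 2002))
  expect_equal(corr2$values, fine$values, tolerance = 1e-12)

  expect_error(harmonize_products(coarse, fine, overlap = c(1990, 1991)),
               "overlap")
})

test_that("MMM recentering subtracts slope times the center gap", {
  sc <- flat_scenario(trend = 0.02, seasonal_amplitude = 0)
  monthly <- monthly_aggregate(generate_sst(sc))
  plain <- compute_mmm(monthly, recenter = NULL)
  rec <- compute_mmm(monthly,
                     recenter = list(full_span_center = 2011.5,
                                     heritage_center = 2000.0))
  # slope is exactly 0.02, gap 11.5 years: MMM lowered by 0.23
  expect_equal(rec$mmm, plain$mmm - 0.23, tolerance = 1e-6)

  # zero-slope series: recentering is the identity
  sc0 <- flat_scenario(seasonal_amplitude = 0)
  m0 <- monthly_aggregate(generate_sst(sc0))
  expect_equal(compute_mmm(m0, recenter = recenter_spec())$mmm,
               compute_mmm(m0, recenter = NULL)$mmm)
  # zero center gap: identity on any series
  m1 <- monthly_aggregate(generate_sst(tiny_scenario(seed = 3)))
  expect_equal(compute_mmm(m1, recenter = list(full_span_center = 2002,
                                               heritage_center = 2002))$mmm,
               compute_mmm(m1, recenter = NULL)$mmm)
  expect_error(compute_mmm(monthly_field(array(1, c(1, 1, 12)), 1, 1,
                                         rep(2001, 12), 1:12)),
               ">= 2 years")
})

test_that("MMM equals the maximum climatological monthly mean (oracle)", {
  sc <- tiny_scenario(seed = 9)
  monthly <- monthly_aggregate(generate_sst(sc))
  got <- compute_mmm(monthly, recenter = NULL)$mmm
  for (i in 1:2) for (j in 1:2) {
    clim12 <- vapply(1:12, function(m)
      mean(monthly$values[i, j, monthly$month == m]), numeric(1))
    expect_equal(got[i, j], max(clim12))
  }
})

test_that("default recentering centers follow the month-midpoint convention", {
  rs <- recenter_spec()
  expect_equal(rs$full_span_center, 2000.5)
  expect_equal(rs$heritage_center, mean(c(1985:1990, 1993)) + 0.5)
})

test_that("MMM_max is the mean annual maximum and never below MMM", {
  # hand-built field: annual maxima 29, 30, 31
  vals <- array(20, c(1, 1, 36))
  vals[1, 1, c(8, 20, 32)] <- c(29, 30, 31)   # August of each year
  mf <- monthly_field(vals, 1, 1, rep(2001:2003, each = 12), rep(1:12, 3))
  expect_equal(compute_mmm_max(mf)[1, 1], 30)
  expect_equal(compute_sigma_m(mf)[1, 1], 1)

  # single year: MMM_max equals that year's max
  mf1 <- monthly_field(vals[, , 1:12, drop = FALSE], 1, 1, rep(2001, 12), 1:12)
  expect_equal(compute_mmm_max(mf1)[1, 1], 29)

  # warmest month alternates across years: MMM_max >= MMM
  sc <- tiny_scenario(seed = 5, interannual_sd = 0.6)
  monthly <- monthly_aggregate(generate_sst(sc))
  expect_true(all(compute_mmm_max(monthly) >=
                    compute_mmm(monthly, recenter = NULL)$mmm - 1e-12))
})

test_that("sigma_m matches a brute-force SD over extracted annual maxima", {
  vals <- array(25, c(1, 1, 24))
  mf <- monthly_field(vals, 1, 1, rep(2001:2002, each = 12), rep(1:12, 2))
  expect_equal(compute_sigma_m(mf)[1, 1], 0)
  expect_error(compute_sigma_m(monthly_field(vals[, , 1:12, drop = FALSE],
                                             1, 1, rep(2001, 12), 1:12)),
               "2 complete years")

  sc <- tiny_scenario(seed = 31)
  monthly <- monthly_aggregate(generate_sst(sc))
  got <- compute_sigma_m(monthly)
  for (i in 1:2) for (j in 3:4) {
    maxima <- vapply(sort(unique(monthly$year)), function(y)
      max(monthly$values[i, j, monthly$year == y]), numeric(1))
    expect_equal(got[i, j], sd(maxima))
  }
})

test_that("IDW follows the distance-power weight formula", {
  # coincident target: exact source value
  expect_equal(idw_interpolate(c(130, 131), c(26, 27), c(5, 9), 130, 26), 5)
  # equidistant sources 10 and 20: midpoint for any power
  for (p in c(1, 2, 4)) {
    expect_equal(idw_interpolate(c(130, 130), c(25.9, 26.1), c(10, 20),
                                 130, 26, power = p), 15)
  }
  # distances 1:2 along a meridian, power 2: (10*1 + 20*0.25)/1.25 = 12
  expect_equal(idw_interpolate(c(130, 130), c(26.009, 25.982), c(10, 20),
                               130, 26, power = 2), 12, tolerance = 1e-9)
  expect_error(idw_interpolate(1, 1, NA_real_, 2, 2), "finite")

  # bounded by the source range
  set.seed(3)
  v <- runif(20, 3, 7)
  out <- idw_interpolate(runif(20, 130, 131), runif(20, 25, 26), v,
                         runif(10, 130, 131), runif(10, 25, 26))
  expect_true(all(out >= 3 & out <= 7))
})

test_that("bilinear interpolation blends the four surrounding nodes", {
  f <- matrix(c(10, 30, 20, 40), 2, 2)   # [lat, lon]: rows y, cols x
  lon <- c(0, 1); lat <- c(0, 1)
  expect_equal(bilinear_interpolate(f, lon, lat, 0, 0), 10)
  expect_equal(bilinear_interpolate(f, lon, lat, 1, 1), 40)
  f01 <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(bilinear_interpolate(f01, lon, lat, 0.5, 0.5), 0.5)
  # corners 10/20/30/40 at fractional offsets (fx, fy) = (0.25, 0.75)
  g <- matrix(c(10, 30, 20, 40), 2, 2)
  expect_equal(bilinear_interpolate(g, lon, lat, 0.25, 0.75), 27.5)
  # outside the hull: NA
  expect_true(is.na(bilinear_interpolate(f, lon, lat, 2, 0.5)))
})
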