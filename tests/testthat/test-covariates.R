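test_that("current speed is the Euclidean magnitude", {
  expect_equal(current_speed(0, 0), 0)
  expect_equal(current_speed(3, 4), 5)
  expect_equal(current_speed(-1, 1), sqrt(2))
})

test_that("seasonal composites take the per-cell median over target months", {
  vals <- array(5, c(1, 1, 12))
  mf <- monthly_field(vals, 1, 1, rep(2001, 12), 1:12)
  expect_equal(seasonal_composite(mf)[1, 1], 5)

  vals2 <- array(0, c(1, 1, 12)); vals2[1, 1, 7:9] <- c(1, 2, 9)
  mf2 <- monthly_field(vals2, 1, 1, rep(2001, 12), 1:12)
  expect_equal(seasonal_composite(mf2)[1, 1], 2)

  # two years with Jul-Sep {1,2,9} each: 6-value median is still 2
  vals3 <- array(0, c(1, 1, 24))
  vals3[1, 1, c(7:9, 19:21)] <- rep(c(1, 2, 9), 2)
  mf3 <- monthly_field(vals3, 1, 1, rep(2001:2002, each = 12), rep(1:12, 2))
  expect_equal(seasonal_composite(mf3)[1, 1], median(rep(c(1, 2, 9), 2)))

  expect_error(seasonal_composite(mf, months = integer(0)), "months")
})

test_that("the typhoon calm index is the season minus the union of exposures", {
  season <- as.POSIXct(c("2010-07-01", "2010-10-01"), tz = "UTC")
  total <- as.numeric(difftime(season[2], season[1], units = "hours"))
  no_tracks <- data.frame(track_id = integer(), time = as.POSIXct(character()),
                          lon = numeric(), lat = numeric(),
                          max_wind_ms = numeric())
  expect_equal(typhoon_calm_index(no_tracks, 130, 26, season), total)

  # a 24 h passage right over the cell (4 points at 6-h spacing)
  t0 <- as.POSIXct("2010-08-01 00:00:00", tz = "UTC")
  tr <- data.frame(track_id = 1, time = t0 + (0:3) * 21600,
                   lon = 130, lat = 26, max_wind_ms = 20)
  expect_equal(typhoon_calm_index(tr, 130, 26, season), total - 24)
  # a far-away cell is untouched
  expect_equal(typhoon_calm_index(tr, 135, 30, season), total)
  # winds below 15 m/s do not count
  tr_weak <- transform(tr, max_wind_ms = 10)
  expect_equal(typhoon_calm_index(tr_weak, 130, 26, season), total)

  # two overlapping passages: the overlap is counted once
  tr2 <- rbind(tr, transform(tr, track_id = 2, time = time + 43200))
  expect_equal(typhoon_calm_index(tr2, 130, 26, season), total - 36)

  # never exceeds the season, equality iff unexposed
  expect_true(all(typhoon_calm_index(tr2, c(130, 140), c(26, 35), season)
                  <= total))
})

test_that("coastal fill interpolates only the missing cells and is idempotent", {
  f <- matrix(7, 4, 4)
  lon <- seq(130, 130.3, by = 0.1); lat <- seq(26, 26.3, by = 0.1)
  expect_identical(coastal_fill(f, lon, lat), f)

  f[2, 2] <- NA
  filled <- coastal_fill(f, lon, lat)
  expect_equal(filled[2, 2], 7)

  # a gap midway between 10 and 20 at equal distance
  g <- matrix(NA_real_, 1, 3)
  g[1, 1] <- 10; g[1, 3] <- 20
  gf <- coastal_fill(g, c(130, 130.1, 130.2), 26)
  expect_equal(gf[1, 2], 15)
  expect_identical(coastal_fill(gf, c(130, 130.1, 130.2), 26), gf)

  expect_error(coastal_fill(matrix(NA_real_, 2, 2), 1:2, 1:2), "all-missing")
})

test_that("record extraction reproduces grid values and window time-dependence", {
  sc <- tiny_scenario(seed = 21,
                      anomaly_events = list(list(start = "2003-07-01",
                                                 duration = 60, peak = 2.5,
                                                 shape = "plateau")))
  sst <- generate_sst(sc)
  clim <- climatology_set(monthly_aggregate(sst))
  fields <- generate_covariates(sc)
  recs <- data.frame(lon = sst$lon[2], lat = sst$lat[3],
                     date = as.Date(c("2003-08-01", "2003-09-30")),
                     depth_m = c(5, 12))
  tab <- extract_at_records(sst, clim, fields, recs, index_spec())
  expect_equal(nrow(tab), 2)
  # cell-center record: field values exactly
  expect_equal(tab$k[1], fields$k490[3, 2])
  expect_equal(tab$v[1], clim$sigma_m[3, 2])
  expect_equal(tab$u[1], fields$uv[3, 2, 8])
  expect_equal(tab$d, recs$depth_m)
  # same cell, dates 60 days apart during a heat event: DHW differs
  expect_false(isTRUE(all.equal(tab$dhw[1], tab$dhw[2])))
  # DHW recomputed from the cached windows matches the reported column
  W <- attr(tab, "hs_windows")
  expect_equal(degree_heating_week(W, 1), tab$dhw)

  # uncovered record (window precedes the cube) is excluded and listed
  recs2 <- rbind(recs, data.frame(lon = sst$lon[1], lat = sst$lat[1],
                                  date = as.Date("2000-02-01"), depth_m = 3))
  expect_message(tab2 <- extract_at_records(sst, clim, fields, recs2,
                                            index_spec()), "excluded")
  expect_equal(nrow(tab2), 2)
  expect_equal(attr(tab2, "excluded"), 3L)
})

test_that("the collinearity screen drops the lower-priority member of hot pairs", {
  set.seed(8)
  n <- 1000
  tab <- data.frame(dhw = rnorm(n), c = rnorm(n), u = rnorm(n), k = rnorm(n),
                    d = rnorm(n), s = rnorm(n), v = rnorm(n))
  attr(tab, "index_column") <- "dhw"
  # independent Gaussians: nothing dropped
  scr <- collinearity_screen(tab)
  expect_length(scr$dropped, 0)

  # duplicated column: r = 1, the lower-priority copy goes
  tab2 <- tab; tab2$v <- tab2$u
  scr2 <- collinearity_screen(tab2)
  expect_identical(scr2$dropped, "v")
  expect_equal(scr2$pairs$r, 1)

  # a pair constructed at exactly r = 0.79 is broken up
  cp <- correlated_pair(n, 0.79)
  tab3 <- tab; tab3$u <- cp$x; tab3$k <- cp$y
  scr3 <- collinearity_screen(tab3)
  expect_identical(scr3$dropped, "k")
  expect_equal(abs(scr3$pairs$r), 0.79, tolerance = 1e-12)

  # no retained pair exceeds the cutoff
  R <- abs(cor(tab3[scr3$retained])); diag(R) <- 0
  expect_lt(max(R), 0.7)

  # constant columns are flagged, not correlated
  tab4 <- tab; tab4$s <- 1
  expect_identical(collinearity_screen(tab4)$flagged_constant, "s")
  expect_error(collinearity_screen(tab[1:2, ]), ">= 3 rows")
})
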