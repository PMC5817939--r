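# SST climatologies: monthly aggregation, inter-product bias harmonization,
# recentered MMM, MMM_max, historical variability sigma_m, and the spatial
# interpolators used for downscaling and coastal fill.

# Mean decimal year of the days of a calendar month; the regression axis
# for trend fitting, consistent with daily-data aggregation.
month_mean_decyear <- function(year, month) {
  vapply(seq_along(year), function(i) {
    d0 <- as.Date(sprintf("%d-%02d-01", year[i], month[i]))
    d1 <- seq(d0, by = "month", length.out = 2)[2] - 1
    mean(decimal_year(seq(d0, d1, by = "day")))
  }, numeric(1))
}

#' Aggregate a daily SST cube to monthly means
#'
#' Arithmetic mean of available days per cell per calendar month.  A cell's
#' month is set missing (NA) when fewer than `min_coverage` of the month's
#' days are finite; the slice-level `complete` flag marks months fully
#' covered by the cube's date range.
#'
#' @param sst an [sst_cube()].
#' @param min_coverage minimum fraction of days required (default 0.5).
#' @return a [monthly_field()] of monthly mean SST.
#' @export
monthly_aggregate <- function(sst, min_coverage = 0.5) {
  stopifnot(inherits(sst, "sst_cube"))
  if (length(sst$dates) == 0) stop("empty cube", call. = FALSE)
  ym <- format(sst$dates, "%Y-%m")
  uym <- unique(ym)
  if (length(uym) < 1) stop("cube holds no complete month", call. = FALSE)
  nlat <- length(sst$lat); nlon <- length(sst$lon)
  vals <- array(NA_real_, c(nlat, nlon, length(uym)))
  year <- as.integer(substr(uym, 1, 4))
  month <- as.integer(substr(uym, 6, 7))
  complete <- logical(length(uym))
  for (i in seq_along(uym)) {
    idx <- which(ym == uym[i])
    days_in_month <- as.integer(format(
      seq(as.Date(sprintf("%d-%02d-01", year[i], month[i])),
          by = "month", length.out = 2)[2] - 1, "%d"))
    complete[i] <- length(idx) == days_in_month
    block <- sst$values[, , idx, drop = FALSE]
    nfin <- apply(!is.na(block), c(1, 2), sum)
    m <- apply(block, c(1, 2), function(v) mean(v, na.rm = TRUE))
    m[nfin < min_coverage * days_in_month] <- NA_real_
    m[nfin == 0] <- NA_real_
    vals[, , i] <- m
  }
  monthly_field(vals, sst$lon, sst$lat, year, month, complete)
}

#' Harmonize a coarse SST product to a fine one by monthly-climatology bias
#'
#' Adds, per calendar month, the overlap-period climatology difference
#' (fine minus coarse) to the coarse product, so the corrected series
#' matches the fine product's monthly climatology on the overlap.  The
#' coarse field must already be on the fine grid (downscale first, e.g.
#' with [idw_interpolate()] or [bilinear_interpolate()]).
#'
#' @param coarse_monthly,fine_monthly [monthly_field()]s on the same grid.
#' @param overlap inclusive year span `c(first, last)` used for the bias
#'   climatologies.
#' @return the corrected coarse [monthly_field()].
#' @export
harmonize_products <- function(coarse_monthly, fine_monthly, overlap) {
  stopifnot(inherits(coarse_monthly, "monthly_field"),
            inherits(fine_monthly, "monthly_field"))
  in_c <- coarse_monthly$year >= overlap[1] & coarse_monthly$year <= overlap[2]
  in_f <- fine_monthly$year >= overlap[1] & fine_monthly$year <= overlap[2]
  if (!any(in_c) || !any(in_f)) stop("empty overlap period", call. = FALSE)
  clim <- function(mf, keep) {
    out <- array(NA_real_, c(dim(mf$values)[1:2], 12))
    for (m in 1:12) {
      sel <- keep & mf$month == m
      if (any(sel)) {
        out[, , m] <- apply(mf$values[, , sel, drop = FALSE], c(1, 2),
                            mean, na.rm = TRUE)
      }
    }
    out
  }
  bias <- clim(fine_monthly, in_f) - clim(coarse_monthly, in_c)
  corrected <- coarse_monthly$values
  for (i in seq_along(coarse_monthly$year)) {
    corrected[, , i] <- corrected[, , i] + bias[, , coarse_monthly$month[i]]
  }
  monthly_field(corrected, coarse_monthly$lon, coarse_monthly$lat,
                coarse_monthly$year, coarse_monthly$month,
                coarse_monthly$complete)
}

#' Recentering specification for the MMM climatology
#'
#' The climatological monthly means are recentered to the temporal midpoint
#' of the heritage coarse-resolution baseline era by subtracting
#' `slope * (full_span_center - heritage_center)` before taking the
#' maximum.  Centers default to the mean month-midpoint decimal years of
#' 1985-2015 (2000.5) and of 1985-1990 plus 1993 (1988.7857).
#'
#' @param full_years years of the full climatology span.
#' @param heritage_years years of the heritage baseline era.
#' @return list with `full_span_center` and `heritage_center` decimal years.
#' @export
recenter_spec <- function(full_years = 1985:2015,
                          heritage_years = c(1985:1990, 1993)) {
  list(full_span_center = mean(full_years) + 0.5,
       heritage_center = mean(heritage_years) + 0.5)
}

# Per-cell least-squares slope of the monthly series against the mean
# decimal year of each month.  NA-tolerant.
monthly_trend_slope <- function(monthly) {
  x <- month_mean_decyear(monthly$year, monthly$month)
  d <- dim(monthly$values)
  Y <- matrix(monthly$values, nrow = d[1] * d[2])   # cells x months
  slope <- rep(NA_real_, nrow(Y))
  fin <- is.finite(Y)
  allfin <- rowSums(!fin) == 0
  if (any(allfin)) {
    xc <- x - mean(x)
    denom <- sum(xc^2)
    slope[allfin] <- (Y[allfin, , drop = FALSE] %*% xc) / denom
  }
  for (i in which(!allfin)) {
    ok <- fin[i, ]
    if (sum(ok) >= 2) {
      xc <- x[ok] - mean(x[ok])
      slope[i] <- sum(xc * Y[i, ok]) / sum(xc^2)
    }
  }
  matrix(slope, d[1], d[2])
}

# Climatological mean per calendar month: array [nlat, nlon, 12].
monthly_climatology <- function(monthly) {
  d <- dim(monthly$values)
  out <- array(NA_real_, c(d[1], d[2], 12))
  for (m in 1:12) {
    sel <- monthly$month == m
    if (any(sel)) {
      out[, , m] <- apply(monthly$values[, , sel, drop = FALSE], c(1, 2),
                          mean, na.rm = TRUE)
    }
  }
  out
}

#' Maximum monthly mean climatology (MMM) with trend recentering
#'
#' Per cell: fit the least-squares linear trend of the monthly mean series,
#' recenter each of the 12 climatological monthly means by subtracting
#' `slope * (full_span_center - heritage_center)`, and take the maximum.
#' With `recenter = NULL` the centers coincide and MMM is the plain
#' maximum of the 12 climatological monthly means.
#'
#' @param monthly a [monthly_field()] with at least 2 distinct years.
#' @param recenter a [recenter_spec()] or `NULL` for no recentering.
#' @return list: `mmm` matrix (degC), `slope` matrix (degC/yr),
#'   `monthly_clim` array `[nlat, nlon, 12]` (un-recentered).
#' @export
compute_mmm <- function(monthly, recenter = NULL) {
  stopifnot(inherits(monthly, "monthly_field"))
  if (length(unique(monthly$year)) < 2) {
    stop("recentering needs >= 2 years of monthly data (slope undefined)",
         call. = FALSE)
  }
  slope <- monthly_trend_slope(monthly)
  clim <- monthly_climatology(monthly)
  gap <- if (is.null(recenter)) 0 else
    recenter$full_span_center - recenter$heritage_center
  rec <- sweep(clim, c(1, 2), slope * gap, "-")
  mmm <- apply(rec, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else
    max(v, na.rm = TRUE))
  list(mmm = mmm, slope = slope, monthly_clim = clim)
}

# Annual maximum monthly SST per cell: matrix cells stacked over complete years.
annual_max_monthly <- function(monthly, require_complete_year = TRUE) {
  yrs <- sort(unique(monthly$year))
  d <- dim(monthly$values)
  keep_yrs <- yrs[vapply(yrs, function(y) {
    sum(monthly$year == y) == 12 || !require_complete_year
  }, logical(1))]
  if (length(keep_yrs) == 0) stop("no complete year in monthly field",
                                  call. = FALSE)
  out <- array(NA_real_, c(d[1], d[2], length(keep_yrs)))
  for (i in seq_along(keep_yrs)) {
    sel <- monthly$year == keep_yrs[i]
    out[, , i] <- apply(monthly$values[, , sel, drop = FALSE], c(1, 2),
                        function(v) if (all(is.na(v))) NA_real_ else
                          max(v, na.rm = TRUE))
  }
  out
}

#' Mean annual maximum climatology (MMM_max)
#'
#' Per cell, the mean over years of each year's warmest monthly mean SST.
#' Because the warmest calendar month may differ between years, MMM_max is
#' never below MMM from the same series (no recentering is applied).
#'
#' @param monthly a [monthly_field()] with at least one complete year.
#' @return matrix of MMM_max (degC).
#' @export
compute_mmm_max <- function(monthly) {
  stopifnot(inherits(monthly, "monthly_field"))
  am <- annual_max_monthly(monthly)
  apply(am, c(1, 2), mean, na.rm = TRUE)
}

#' Historical SST variability (sigma_m)
#'
#' Per cell, the sample standard deviation (n - 1 denominator) of the
#' annual maximum monthly SST across years.
#'
#' @param monthly a [monthly_field()] with at least 2 complete years.
#' @return matrix of sigma_m (degC).
#' @export
compute_sigma_m <- function(monthly) {
  stopifnot(inherits(monthly, "monthly_field"))
  am <- annual_max_monthly(monthly)
  if (dim(am)[3] < 2) stop("sigma_m needs >= 2 complete years", call. = FALSE)
  apply(am, c(1, 2), sd, na.rm = TRUE)
}

#' Build the full climatology set from a monthly field
#'
#' @param monthly a [monthly_field()].
#' @param recenter a [recenter_spec()] or `NULL`.
#' @return object of class `climatology_set`: matrices `mmm`, `mmm_max`,
#'   `sigma_m`, `slope`, array `monthly_clim`, axes and year span.
#' @export
climatology_set <- function(monthly, recenter = NULL) {
  m <- compute_mmm(monthly, recenter)
  structure(list(mmm = m$mmm, mmm_max = compute_mmm_max(monthly),
                 sigma_m = compute_sigma_m(monthly), slope = m$slope,
                 monthly_clim = m$monthly_clim,
                 lon = monthly$lon, lat = monthly$lat,
                 span = range(monthly$year)),
            class = "climatology_set")
}

#' Inverse-distance-weighted interpolation
#'
#' Weighted mean of the `k` nearest finite sources with weights
#' `distance^-power` (great-circle distances); exact at coincident points;
#' outputs never leave the source value range.
#'
#' @param src_lon,src_lat,src_val source point coordinates and values.
#' @param tgt_lon,tgt_lat target coordinates.
#' @param power IDW exponent (default 2).
#' @param k number of nearest neighbors used (default 12).
#' @return numeric vector of interpolated values at the targets.
#' @export
idw_interpolate <- function(src_lon, src_lat, src_val, tgt_lon, tgt_lat,
                            power = 2, k = 12) {
  fin <- is.finite(src_val)
  if (!any(fin)) stop("no finite source values for IDW", call. = FALSE)
  src_lon <- src_lon[fin]; src_lat <- src_lat[fin]; src_val <- src_val[fin]
  D <- gc_dist_km(tgt_lon, tgt_lat, src_lon, src_lat)
  k <- min(k, length(src_val))
  out <- numeric(length(tgt_lon))
  for (i in seq_along(out)) {
    d <- D[i, ]
    nn <- order(d)[seq_len(k)]
    if (d[nn[1]] < 1e-9) {
      out[i] <- src_val[nn[1]]
    } else {
      w <- d[nn]^(-power)
      out[i] <- sum(w * src_val[nn]) / sum(w)
    }
  }
  out
}

#' Bilinear interpolation on a regular lon/lat grid
#'
#' Standard 4-node blend; exact at nodes; targets outside the grid hull are
#' returned NA (to be filled afterwards by coastal IDW).
#'
#' @param field matrix `[nlat, nlon]`.
#' @param lon,lat grid axes (ascending).
#' @param tgt_lon,tgt_lat target coordinates.
#' @return numeric vector of interpolated values.
#' @export
bilinear_interpolate <- function(field, lon, lat, tgt_lon, tgt_lat) {
  out <- rep(NA_real_, length(tgt_lon))
  for (i in seq_along(out)) {
    x <- tgt_lon[i]; y <- tgt_lat[i]
    if (x < lon[1] || x > lon[length(lon)] ||
        y < lat[1] || y > lat[length(lat)]) next
    jx <- findInterval(x, lon, rightmost.closed = TRUE)
    jy <- findInterval(y, lat, rightmost.closed = TRUE)
    jx <- min(jx, length(lon) - 1L); jy <- min(jy, length(lat) - 1L)
    if (length(lon) == 1L || length(lat) == 1L) { out[i] <- field[jy, jx]; next }
    fx <- (x - lon[jx]) / (lon[jx + 1] - lon[jx])
    fy <- (y - lat[jy]) / (lat[jy + 1] - lat[jy])
    out[i] <- field[jy, jx] * (1 - fx) * (1 - fy) +
      field[jy, jx + 1] * fx * (1 - fy) +
      field[jy + 1, jx] * (1 - fx) * fy +
      field[jy + 1, jx + 1] * fx * fy
  }
  out
}
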