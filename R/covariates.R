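# Non-thermal covariates: current speed, seasonal composites, typhoon calm
# index, coastal gap fill, extraction of all covariates at observation
# points, and the collinearity screen.

#' Surface current speed from velocity components
#'
#' Euclidean magnitude `sqrt(u^2 + v^2)` per cell, m s-1.
#'
#' @param u_component,v_component longitudinal / latitudinal velocity
#'   (m s-1), co-registered scalars, vectors or matrices.
#' @return current speed, same shape as the inputs.
#' @export
current_speed <- function(u_component, v_component) {
  sqrt(u_component^2 + v_component^2)
}

#' Seasonal climatological composite of a monthly field
#'
#' Per-cell statistic (default: median) over all values of the target
#' months across years, e.g. the July-September climatological median used
#' for current speed and turbidity.
#'
#' @param monthly a [monthly_field()] or array `[nlat, nlon, 12]` of one
#'   climatological year.
#' @param months calendar months to composite (default 7:9).
#' @param statistic summary function (default [stats::median]).
#' @return matrix `[nlat, nlon]`.
#' @export
seasonal_composite <- function(monthly, months = 7:9, statistic = stats::median) {
  if (inherits(monthly, "monthly_field")) {
    sel <- monthly$month %in% months
    if (!any(sel)) stop("no data in the requested months", call. = FALSE)
    vals <- monthly$values[, , sel, drop = FALSE]
  } else {
    vals <- monthly[, , months, drop = FALSE]
  }
  apply(vals, c(1, 2), function(v) statistic(v[is.finite(v)]))
}

# Union length (hours) of a set of [start, end) intervals given as a
# 2-column matrix of POSIXct seconds.
interval_union_hours <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  o <- order(intervals[, 1])
  s <- intervals[o, 1]; e <- intervals[o, 2]
  total <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  (total + (cur_e - cur_s)) / 3600
}

#' Typhoon calm index
#'
#' Length of time (hours) within the season during which a cell is NOT
#' exposed to typhoon winds, typhoons being track points with maximum wind
#' above `wind_threshold` (15 m s-1) within `radius_km` of the cell.  Each
#' qualifying track point exerts influence for `dt_hours` (the track's
#' reporting interval); overlapping exposures are counted once.
#'
#' @param tracks data.frame with columns `time` (POSIXct), `lon`, `lat`,
#'   `max_wind_ms`.
#' @param cell_lon,cell_lat cell-center coordinates (vectorized).
#' @param season `c(start, end)` POSIXct (or Date) bounds of the season.
#' @param wind_threshold wind cutoff defining a typhoon, m s-1 (default 15).
#' @param radius_km influence radius of a track point (default 100 km).
#' @param dt_hours influence duration per track point (default 6 h).
#' @return numeric vector of calm hours, one per cell; at most the season
#'   duration, with equality iff the cell has no qualifying exposure.
#' @export
typhoon_calm_index <- function(tracks, cell_lon, cell_lat, season,
                               wind_threshold = 15, radius_km = 100,
                               dt_hours = 6) {
  season <- as.POSIXct(season, tz = "UTC")
  total_h <- as.numeric(difftime(season[2], season[1], units = "hours"))
  if (nrow(tracks) == 0) return(rep(total_h, length(cell_lon)))
  tt <- as.POSIXct(tracks$time, tz = "UTC")
  in_season <- tt >= season[1] & tt < season[2] &
    tracks$max_wind_ms > wind_threshold
  tr <- tracks[in_season, , drop = FALSE]
  tt <- tt[in_season]
  out <- numeric(length(cell_lon))
  for (i in seq_along(cell_lon)) {
    if (nrow(tr) == 0) { out[i] <- total_h; next }
    d <- gc_dist_km(cell_lon[i], cell_lat[i], tr$lon, tr$lat)[1, ]
    hit <- d <= radius_km
    if (!any(hit)) { out[i] <- total_h; next }
    s <- as.numeric(tt[hit])
    iv <- cbind(pmax(s, as.numeric(season[1])),
                pmin(s + dt_hours * 3600, as.numeric(season[2])))
    out[i] <- total_h - interval_union_hours(iv)
  }
  out
}

#' Fill missing coastal cells by inverse distance weighting
#'
#' Missing cells are filled from the `k` nearest finite cells; finite cells
#' are untouched, so the operation is idempotent.
#'
#' @param field matrix `[nlat, nlon]` with NAs to fill.
#' @param lon,lat grid axes.
#' @param power,k IDW parameters (see [idw_interpolate()]).
#' @return the filled matrix.
#' @export
coastal_fill <- function(field, lon, lat, power = 2, k = 12) {
  fin <- is.finite(field)
  if (!any(fin)) stop("cannot fill an all-missing field", call. = FALSE)
  if (all(fin)) return(field)
  ij_fin <- which(fin, arr.ind = TRUE)
  ij_na <- which(!fin, arr.ind = TRUE)
  filled <- idw_interpolate(lon[ij_fin[, 2]], lat[ij_fin[, 1]], field[fin],
                            lon[ij_na[, 2]], lat[ij_na[, 1]],
                            power = power, k = k)
  field[!fin] <- filled
  field
}

nearest_cell <- function(lon, lat, rec_lon, rec_lat) {
  cbind(row = vapply(rec_lat, function(y) which.min(abs(lat - y)), integer(1)),
        col = vapply(rec_lon, function(x) which.min(abs(lon - x)), integer(1)))
}

#' Join thermal indices and environmental covariates to observation records
#'
#' For each record: the thermal index of `spec` and the degree cooling week
#' are evaluated over trailing windows ending on the record date; UV-B is
#' read at the record's calendar month; turbidity `k` and current speed `s`
#' come from their (July-September composite) fields; `v` is sigma_m at the
#' cell; `d` is the observer-reported depth.  Records whose trailing window
#' is not covered by the cube are excluded and listed in the
#' `"excluded"` attribute.
#'
#' @param sst an [sst_cube()] covering the record dates (and 84 prior days).
#' @param clim a [climatology_set()] on the same grid.
#' @param fields list from [generate_covariates()] (or equivalent): `uv`
#'   array `[nlat, nlon, 12]`, `k490`, `u_current`, `v_current` matrices.
#' @param records data.frame with `lon`, `lat`, `date`, `depth_m` and
#'   optionally `bleached`, `severity`, `nonthermal_flag`.
#' @param spec an [index_spec()] choosing the thermal index.
#' @param keep_windows attach the per-record HotSpot window matrix as
#'   attribute `"hs_windows"` (daily kinds) or `"hs_monthly"` (DHM), so
#'   filtering-threshold searches can recompute the index cheaply.
#' @return a covariate table (data.frame): thermal index column (named by
#'   `spec$kind`: `dhw`, `dhm`, `sst_week` or `sst_month`), `c`, `u`, `k`,
#'   `d`, `s`, `v`, plus the record columns.  Attributes: `"index_column"`,
#'   `"excluded"`, and the window cache when requested.
#' @export
extract_at_records <- function(sst, clim, fields, records, spec = index_spec(),
                               keep_windows = TRUE) {
  stopifnot(inherits(sst, "sst_cube"), inherits(clim, "climatology_set"),
            inherits(spec, "index_spec"))
  n <- nrow(records)
  cells <- nearest_cell(sst$lon, sst$lat, records$lon, records$lat)
  date_idx <- match(as.Date(records$date), sst$dates)
  covered <- !is.na(date_idx) & date_idx >= 84
  excluded <- which(!covered)
  if (length(excluded) > 0) {
    message(length(excluded),
            " record(s) excluded: trailing window not covered by the SST cube")
  }
  keep <- which(covered)
  rec <- records[keep, , drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  date_idx <- date_idx[keep]
  m <- nrow(rec)

  baseline_mat <- if (spec$baseline == "mmm_max") clim$mmm_max else clim$mmm
  base_v <- baseline_mat[cbind(cells[, "row"], cells[, "col"])]
  mmm_v <- clim$mmm[cbind(cells[, "row"], cells[, "col"])]
  sigma_v <- clim$sigma_m[cbind(cells[, "row"], cells[, "col"])]

  sst_win <- matrix(NA_real_, m, 84)
  for (i in seq_len(m)) {
    sst_win[i, ] <- sst$values[cells[i, "row"], cells[i, "col"],
                               (date_idx[i] - 83):date_idx[i]]
  }
  hs_win <- pmax(sst_win - base_v, 0)

  thr <- if (spec$filter_mode == "sigma_scaled_beta") spec$beta * sigma_v
         else spec$alpha

  hs_monthly <- NULL
  index_val <- switch(spec$kind,
    dhw = degree_heating_week(hs_win, thr),
    dcw = degree_cooling_week(sst_win, mmm_v),
    weekly_sst = rowMeans(sst_win[, 78:84, drop = FALSE]),
    monthly_sst = rowMeans(sst_win[, 55:84, drop = FALSE]),
    dhm = {
      monthly <- monthly_aggregate(sst)
      hs_monthly <- matrix(NA_real_, m, 12)
      for (i in seq_len(m)) {
        rd <- as.Date(rec$date[i])
        yy <- as.integer(format(rd, "%Y")); mm <- as.integer(format(rd, "%m"))
        sl <- match(paste(yy, mm), paste(monthly$year, monthly$month))
        if (is.na(sl) || sl < 12) {
          stop("DHM needs 12 trailing months of coverage", call. = FALSE)
        }
        mo_sst <- monthly$values[cells[i, "row"], cells[i, "col"], (sl - 11):sl]
        hs_monthly[i, ] <- pmax(mo_sst - base_v[i], 0)
      }
      degree_heating_month(hs_monthly, thr)
    })

  dcw_val <- degree_cooling_week(sst_win, mmm_v)
  rec_month <- as.integer(format(as.Date(rec$date), "%m"))
  uv_v <- vapply(seq_len(m), function(i)
    fields$uv[cells[i, "row"], cells[i, "col"], rec_month[i]], numeric(1))
  k_v <- fields$k490[cbind(cells[, "row"], cells[, "col"])]
  s_mat <- current_speed(fields$u_current, fields$v_current)
  s_v <- s_mat[cbind(cells[, "row"], cells[, "col"])]

  index_col <- switch(spec$kind, dhw = "dhw", dhm = "dhm", dcw = "dcw",
                      weekly_sst = "sst_week", monthly_sst = "sst_month")
  out <- rec
  out[[index_col]] <- index_val
  out$c <- dcw_val
  out$u <- uv_v
  out$k <- k_v
  out$d <- rec$depth_m
  out$s <- s_v
  out$v <- sigma_v
  attr(out, "index_column") <- index_col
  attr(out, "excluded") <- excluded
  if (keep_windows) {
    if (spec$kind == "dhm") attr(out, "hs_monthly") <- hs_monthly
    else attr(out, "hs_windows") <- hs_win
    attr(out, "sigma_m") <- sigma_v
  }
  out
}

#' Pairwise-correlation collinearity screen
#'
#' Computes pairwise Pearson correlations among candidate covariates and,
#' for every pair with `|r|` above the cutoff, drops the lower-priority
#' member (priority order is configured; variables not listed rank below
#' all listed ones).  Iterates until no retained pair exceeds the cutoff.
#'
#' @param table covariate data.frame.
#' @param vars candidate column names (default: the standard covariate set
#'   present in the table).
#' @param cutoff absolute correlation threshold (default 0.7).
#' @param priority character vector, highest priority first (default keeps
#'   the thermal index over UV-B over the rest).
#' @return list: `retained` (character), `dropped` (character), `pairs`
#'   (data.frame of all pairs with `|r| > cutoff` and the drop decision),
#'   `correlations` (full matrix), `flagged_constant` (columns with
#'   undefined correlations).
#' @export
collinearity_screen <- function(table, vars = NULL, cutoff = 0.7,
                                priority = c(attr(table, "index_column"),
                                             "u", "c", "k", "v", "d", "s")) {
  if (is.null(vars)) {
    vars <- intersect(c(attr(table, "index_column") %||% character(),
                        "c", "u", "k", "d", "s", "v"), names(table))
  }
  if (nrow(table) < 3) stop("collinearity screen needs >= 3 rows", call. = FALSE)
  X <- table[vars]
  const <- vars[vapply(X, function(x) sd(x) == 0 || !is.finite(sd(x)),
                       logical(1))]
  usable <- setdiff(vars, const)
  R <- cor(X[usable])
  prio_rank <- function(v) {
    r <- match(v, priority)
    ifelse(is.na(r), length(priority) + 1L, r)
  }
  retained <- usable
  pairs <- data.frame(var1 = character(), var2 = character(), r = numeric(),
                      dropped = character(), stringsAsFactors = FALSE)
  repeat {
    Rk <- R[retained, retained, drop = FALSE]
    diag(Rk) <- 0
    if (length(retained) < 2 || max(abs(Rk)) <= cutoff) break
    ij <- which(abs(Rk) == max(abs(Rk)), arr.ind = TRUE)[1, ]
    a <- retained[ij[1]]; b <- retained[ij[2]]
    drop <- if (prio_rank(a) <= prio_rank(b)) b else a
    pairs <- rbind(pairs, data.frame(var1 = a, var2 = b, r = Rk[ij[1], ij[2]],
                                     dropped = drop))
    retained <- setdiff(retained, drop)
  }
  list(retained = retained, dropped = setdiff(usable, retained),
       pairs = pairs, correlations = R, flagged_constant = const)
}
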