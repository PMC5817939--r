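# Synthetic study generator: gridded SST with known seasonal/trend/anomaly
# structure, smooth covariate fields, typhoon tracks, and Bernoulli
# bleaching observations from a known logistic model.  Every downstream
# stage of the package is testable against this ground truth.

#' Define a synthetic study scenario
#'
#' Bundles every knob of the synthetic world.  Defaults emulate a
#' subtropical reef region (seasonal cycle peaking in mid August, a slow
#' warming trend, interannual variability of the summer maximum of 0.57 degC,
#' 668 point observations in the July-October bleaching season) with a
#' generating logistic model whose signs follow the usual ecology: heat
#' stress and UV increase bleaching odds, cooling, turbidity and depth
#' decrease them.
#'
#' @param grid_shape integer c(nlat, nlon) cell counts.
#' @param cell_size cell size in degrees.
#' @param origin c(lon, lat) of the first (south-west) cell center.
#' @param years inclusive year span c(first, last); span >= 2 required,
#'   >= 31 for climatology-era work.
#' @param seasonal_mean annual-mean SST, degC.
#' @param seasonal_amplitude amplitude of the annual cycle, degC.
#' @param seasonal_peak_doy day of year of the seasonal SST peak
#'   (default 227, mid August).
#' @param lat_gradient degC per degree of latitude northward (default -0.15,
#'   cooler poleward).
#' @param trend linear warming, degC per year.
#' @param noise_sd daily Gaussian noise SD, degC.
#' @param interannual_sd SD of the per-cell, per-year temperature offset,
#'   degC; this is the ground truth for the historical variability
#'   sigma_m of the annual maximum monthly SST.
#' @param anomaly_events list of heat-wave events, each a list with
#'   `start` (Date), `duration` (days), `peak` (degC), and optionally
#'   `center` c(lon, lat), `radius` (degrees, Gaussian footprint SD;
#'   `Inf` = uniform) and `shape` ("halfsine" or "plateau").
#' @param true_coefficients named vector: `intercept` plus one slope per
#'   covariate column used when drawing observations.
#' @param n_observations number of bleaching records to draw.
#' @param obs_months months observations may fall in (default July-October).
#' @param land_mask optional logical matrix `[nlat, nlon]`, TRUE = land (NA SST).
#' @param seed integer master seed; independent substreams are derived per
#'   generator so adding one generator never perturbs another.
#' @return a validated object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(grid_shape = c(10, 10),
                               cell_size = 0.1,
                               origin = c(lon = 127, lat = 26),
                               years = c(1985, 2016),
                               seasonal_mean = 25,
                               seasonal_amplitude = 4,
                               seasonal_peak_doy = 227,
                               lat_gradient = -0.15,
                               trend = 0.02,
                               noise_sd = 0.3,
                               interannual_sd = 0.57,
                               anomaly_events = list(),
                               true_coefficients = c(intercept = -4.2,
                                                     dhw = 0.773, c = -0.053,
                                                     u = 8.77, k = -19.2,
                                                     d = -0.03, s = 0, v = 0),
                               n_observations = 668,
                               obs_months = 7:10,
                               land_mask = NULL,
                               seed = 1L) {
  if (length(grid_shape) != 2L || any(grid_shape < 1)) {
    stop("'grid_shape' must be two positive cell counts", call. = FALSE)
  }
  if (length(years) != 2L || years[2] < years[1] + 1) {
    stop("'years' must span at least 2 calendar years", call. = FALSE)
  }
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(interannual_sd, "interannual_sd", min = 0)
  stopifnot_scalar_number(n_observations, "n_observations", min = 1)
  if (is.null(names(true_coefficients)) ||
      !"intercept" %in% names(true_coefficients)) {
    stop("'true_coefficients' must be named and include 'intercept'",
         call. = FALSE)
  }
  sc <- list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
             origin = origin, years = as.integer(years),
             seasonal_mean = seasonal_mean,
             seasonal_amplitude = seasonal_amplitude,
             seasonal_peak_doy = seasonal_peak_doy,
             lat_gradient = lat_gradient, trend = trend,
             noise_sd = noise_sd, interannual_sd = interannual_sd,
             anomaly_events = anomaly_events,
             true_coefficients = true_coefficients,
             n_observations = as.integer(n_observations),
             obs_months = obs_months, land_mask = land_mask,
             seed = as.integer(seed))
  class(sc) <- "synthetic_scenario"
  sc
}

scenario_axes <- function(scenario) {
  list(lat = scenario$origin[["lat"]] +
         (seq_len(scenario$grid_shape[1]) - 1) * scenario$cell_size,
       lon = scenario$origin[["lon"]] +
         (seq_len(scenario$grid_shape[2]) - 1) * scenario$cell_size)
}

#' Generate a daily SST cube from a scenario
#'
#' SST(cell, day) = seasonal mean (with a latitudinal gradient)
#' + seasonal_amplitude * cos(2 pi (doy - peak_doy) / 365.25)
#' + trend * (t - t0) + per-year interannual offset + heat-wave anomalies
#' + Gaussian noise.  Land-mask cells (if any) are NA on every day.
#'
#' @param scenario a [synthetic_scenario()].
#' @return an [sst_cube()].
#' @export
generate_sst <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ax <- scenario_axes(scenario)
  nlat <- scenario$grid_shape[1]; nlon <- scenario$grid_shape[2]
  dates <- seq(as.Date(sprintf("%d-01-01", scenario$years[1])),
               as.Date(sprintf("%d-12-31", scenario$years[2])), by = "day")
  nt <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  decyr <- decimal_year(dates)
  yr_idx <- as.integer(format(dates, "%Y")) - scenario$years[1] + 1L
  nyears <- scenario$years[2] - scenario$years[1] + 1L

  seasonal <- scenario$seasonal_amplitude *
    cos(2 * pi * (doy - scenario$seasonal_peak_doy) / 365.25)
  trend_t <- scenario$trend * (decyr - scenario$years[1])
  base_cell <- scenario$seasonal_mean +
    scenario$lat_gradient * (ax$lat - mean(ax$lat))   # per-lat row

  with_substream(substream_seed(scenario$seed, "sst"), {
    inter <- if (scenario$interannual_sd > 0) {
      array(rnorm(nlat * nlon * nyears, 0, scenario$interannual_sd),
            dim = c(nlat, nlon, nyears))
    } else {
      array(0, dim = c(nlat, nlon, nyears))
    }
    vals <- array(0, dim = c(nlat, nlon, nt))
    cell_base <- matrix(rep(base_cell, nlon), nrow = nlat)
    for (t in seq_len(nt)) {
      vals[, , t] <- cell_base + seasonal[t] + trend_t[t] + inter[, , yr_idx[t]]
    }
    for (ev in scenario$anomaly_events) {
      start <- as.Date(ev$start)
      dur <- as.integer(ev$duration)
      idx <- match(start + seq_len(dur) - 1L, dates)
      keep <- which(!is.na(idx))
      if (length(keep) == 0) next
      shape <- ev$shape %||% "halfsine"
      amp_t <- if (identical(shape, "plateau")) rep(ev$peak, dur)
               else ev$peak * sin(pi * (seq_len(dur) - 0.5) / dur)
      center <- ev$center %||% c(mean(ax$lon), mean(ax$lat))
      radius <- ev$radius %||% Inf
      if (is.finite(radius)) {
        dl <- outer(ax$lat - center[2], ax$lon - center[1],
                    function(a, b) a^2 + b^2)
        foot <- exp(-dl / (2 * radius^2))
      } else {
        foot <- matrix(1, nlat, nlon)
      }
      for (j in seq_along(keep)) {
        tt <- idx[keep[j]]
        vals[, , tt] <- vals[, , tt] + amp_t[keep[j]] * foot
      }
    }
    if (scenario$noise_sd > 0) {
      vals <- vals + array(rnorm(length(vals), 0, scenario$noise_sd), dim(vals))
    }
    if (!is.null(scenario$land_mask)) {
      land <- which(scenario$land_mask)
      for (t in seq_len(nt)) {
        slice <- vals[, , t]; slice[land] <- NA_real_; vals[, , t] <- slice
      }
    }
    sst_cube(vals, ax$lon, ax$lat, dates)
  })
}

# Smooth positive field with exact grid mean: mean * (1 + centered smooth
# perturbation).  Perturbation is a random-phase double harmonic, centered
# so the grid mean equals `mean` exactly.
smooth_field <- function(nlat, nlon, mean, rel_amp = 0.3) {
  if (rel_amp == 0) return(matrix(mean, nlat, nlon))
  ph <- runif(4, 0, 2 * pi)
  y <- seq_len(nlat) / nlat; x <- seq_len(nlon) / nlon
  pert <- outer(sin(2 * pi * y + ph[1]), cos(2 * pi * x + ph[2])) +
    0.5 * outer(cos(4 * pi * y + ph[3]), sin(4 * pi * x + ph[4]))
  pert <- pert - base::mean(pert)
  pert <- pert / max(abs(pert), 1e-12) * rel_amp
  mean * (1 + pert)
}

#' Generate smooth covariate fields
#'
#' Produces the non-thermal environmental layers: monthly UV-B irradiance
#' (W m-2, seasonal cycle peaking in July), diffuse attenuation K490 (m-1),
#' current velocity components (m s-1) and a depth field (m).  Fields are
#' smooth double-harmonic surfaces whose grid mean equals the requested
#' mean exactly; `constant` pins selected layers to a single value.
#'
#' @param scenario a [synthetic_scenario()].
#' @param uv_mean,k490_mean,current_mean,depth_mean field means
#'   (W m-2, m-1, m s-1, m).
#' @param rel_amp relative amplitude of the smooth spatial variation.
#' @param constant optional named list, e.g. `list(k490 = 0.05)`, forcing a
#'   layer to a constant.
#' @return list with `uv` (array `[nlat, nlon, 12]`), `k490`, `u_current`,
#'   `v_current`, `depth` (matrices), plus `lon`/`lat` axes.
#' @export
generate_covariates <- function(scenario, uv_mean = 0.45, k490_mean = 0.08,
                                current_mean = 0.2, depth_mean = 8,
                                rel_amp = 0.3, constant = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ax <- scenario_axes(scenario)
  nlat <- scenario$grid_shape[1]; nlon <- scenario$grid_shape[2]
  with_substream(substream_seed(scenario$seed, "covariates"), {
    const_or <- function(name, gen) {
      if (!is.null(constant[[name]])) {
        if (name == "uv") array(constant[[name]], c(nlat, nlon, 12))
        else matrix(constant[[name]], nlat, nlon)
      } else gen()
    }
    uv <- const_or("uv", function() {
      spat <- smooth_field(nlat, nlon, uv_mean, rel_amp)
      arr <- array(0, c(nlat, nlon, 12))
      for (m in 1:12) {
        # seasonal factor peaks in July, floors in January
        arr[, , m] <- spat * (1 + 0.5 * cos(2 * pi * (m - 7) / 12))
      }
      arr
    })
    k490 <- const_or("k490", function() smooth_field(nlat, nlon, k490_mean, rel_amp))
    u_cur <- const_or("u_current", function()
      smooth_field(nlat, nlon, current_mean, rel_amp) - current_mean / 2)
    v_cur <- const_or("v_current", function()
      smooth_field(nlat, nlon, current_mean, rel_amp) - current_mean / 2)
    depth <- const_or("depth", function() smooth_field(nlat, nlon, depth_mean, rel_amp))
    list(uv = uv, k490 = k490, u_current = u_cur, v_current = v_cur,
         depth = depth, lon = ax$lon, lat = ax$lat)
  })
}

#' Sample observation sites and dates
#'
#' Draws record locations uniformly over sea cells and dates uniformly over
#' the scenario's bleaching-season months, avoiding dates with fewer than
#' 84 prior days of SST coverage so trailing indices are always defined.
#'
#' @param scenario a [synthetic_scenario()].
#' @param depth_range uniform range for observer-reported depth (m).
#' @return data.frame: lon, lat, date, depth_m, cell row/col indices.
#' @export
sample_record_sites <- function(scenario, depth_range = c(1, 15)) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ax <- scenario_axes(scenario)
  n <- scenario$n_observations
  with_substream(substream_seed(scenario$seed, "sites"), {
    sea <- which(!(scenario$land_mask %||%
                     matrix(FALSE, scenario$grid_shape[1], scenario$grid_shape[2])))
    cells <- sea[sample.int(length(sea), n, replace = TRUE)]
    row <- ((cells - 1) %% scenario$grid_shape[1]) + 1L
    col <- ((cells - 1) %/% scenario$grid_shape[1]) + 1L
    yrs <- sample(seq(scenario$years[1], scenario$years[2]), n, replace = TRUE)
    mos <- sample(scenario$obs_months, n, replace = TRUE)
    dom <- sample.int(28L, n, replace = TRUE)
    date <- as.Date(sprintf("%d-%02d-%02d", yrs, mos, dom))
    # guarantee a full 84-day trailing window
    start <- as.Date(sprintf("%d-01-01", scenario$years[1]))
    date <- pmax(date, start + 84)
    data.frame(lon = ax$lon[col], lat = ax$lat[row], date = date,
               depth_m = runif(n, depth_range[1], depth_range[2]),
               cell_row = row, cell_col = col)
  })
}

#' Draw bleaching observations from the generating logistic model
#'
#' Each record's bleached flag is Bernoulli with
#' p = logistic(intercept + sum(slope_j * covariate_j)).  Severity labels
#' are assigned from the realized probability; a configurable fraction of
#' records is planted as small non-thermal bleaching events (flagged, for
#' QC-reclassification testing).
#'
#' @param scenario a [synthetic_scenario()]; supplies `true_coefficients`
#'   and the observation seed.
#' @param covariates data.frame with one row per planned record and one
#'   column per non-intercept coefficient name (extra columns such as
#'   lon/lat/date are carried through).
#' @param nonthermal_fraction fraction of records forced bleached and
#'   flagged non-thermal regardless of the model (default 0).
#' @return data.frame of bleaching records: the covariate columns plus
#'   `bleached`, `severity`, `nonthermal_flag`, `source`, and attribute
#'   `"true_probability"`.
#' @export
generate_observations <- function(scenario, covariates,
                                  nonthermal_fraction = 0) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  beta <- scenario$true_coefficients
  slopes <- beta[setdiff(names(beta), "intercept")]
  missing_cols <- setdiff(names(slopes), names(covariates))
  if (length(missing_cols) > 0) {
    stop("covariate table lacks columns for coefficients: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lp <- beta[["intercept"]] +
    as.matrix(covariates[names(slopes)]) %*% slopes
  p <- stats::plogis(as.vector(lp))
  with_substream(substream_seed(scenario$seed, "observations"), {
    bleached <- rbinom(length(p), 1L, p)
    severity <- ifelse(bleached == 1L,
                       sample(c("low", "medium", "high"), length(p),
                              replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                       "none")
    flag <- rep(FALSE, length(p))
    if (nonthermal_fraction > 0) {
      k <- max(1L, round(nonthermal_fraction * length(p)))
      pick <- sample.int(length(p), k)
      bleached[pick] <- 1L
      severity[pick] <- "low"
      flag[pick] <- TRUE
    }
    out <- covariates
    out$bleached <- bleached
    out$severity <- severity
    out$nonthermal_flag <- flag
    out$source <- "synthetic"
    attr(out, "true_probability") <- p
    out
  })
}

#' Generate synthetic typhoon tracks
#'
#' Straight-line 6-hourly tracks crossing the domain with a mid-track wind
#' maximum.  Statistical plumbing only, not storm physics.
#'
#' @param scenario a [synthetic_scenario()].
#' @param n_tracks number of tracks (0 allowed).
#' @param max_wind peak 10-min wind, m s-1.
#' @param n_points 6-hourly positions per track.
#' @param step_deg great-circle step per 6 h, degrees.
#' @return data.frame: track_id, time (POSIXct, UTC), lon, lat, max_wind_ms.
#' @export
generate_typhoon_tracks <- function(scenario, n_tracks = 3, max_wind = 35,
                                    n_points = 12, step_deg = 0.5) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ax <- scenario_axes(scenario)
  empty <- data.frame(track_id = integer(), time = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(), max_wind_ms = numeric())
  if (n_tracks == 0) return(empty)
  with_substream(substream_seed(scenario$seed, "typhoons"), {
    out <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      yr <- sample(seq(scenario$years[1], scenario$years[2]), 1)
      t0 <- as.POSIXct(sprintf("%d-%02d-%02d 00:00:00", yr,
                               sample(7:9, 1), sample.int(28, 1)), tz = "UTC")
      lon0 <- runif(1, min(ax$lon) - 1, max(ax$lon) + 1)
      lat0 <- min(ax$lat) - runif(1, 0.5, 2)
      heading <- runif(1, 60, 120) * pi / 180   # mostly northward
      k <- seq_len(n_points) - 1
      wind <- max_wind * sin(pi * (k + 0.5) / n_points)
      out[[i]] <- data.frame(
        track_id = i,
        time = t0 + k * 6 * 3600,
        lon = lon0 + k * step_deg * cos(heading - pi / 2),
        lat = lat0 + k * step_deg * sin(heading - pi / 2) + k * step_deg,
        max_wind_ms = wind)
    }
    do.call(rbind, out)
  })
}

#' Simulate HotSpot windows with a planted filtering threshold
#'
#' Benchmark generator for filtering-threshold recovery: each record's
#' 84-day HotSpot window mixes (i) sub-threshold "haze" days, uniform on
#' (0, alpha_true), whose accumulated mass is independent of the outcome,
#' and (ii) stress-event days, uniform on (alpha_true + 0.05, hs_max),
#' whose degree-heating-week sum drives the bleaching probability through
#' logistic(b0 + b1 * DHW).  A degree-heating-week computed with the
#' planted threshold therefore carries all of the signal; thresholds below
#' it admit pure noise and thresholds above it discard signal.
#'
#' @param n records to simulate.
#' @param alpha_true planted filtering threshold, degC.
#' @param b0,b1 generating logistic intercept and DHW slope.
#' @param haze_range HotSpot range of haze days (just below the threshold,
#'   so near-miss candidates admit maximal noise).
#' @param event_range HotSpot range of stress-event days (concentrated just
#'   above the threshold, so over-shooting candidates lose signal fast).
#' @param haze_rate expected fraction of window days that are haze days.
#' @param max_event_days upper bound of stress-event days per window.
#' @param seed integer seed.
#' @return list: `windows` (n x 84 HotSpot matrix), `dhw_true`
#'   (degree heating weeks at the planted threshold), `bleached` (0/1),
#'   `p` (generating probabilities).
#' @export
simulate_stress_windows <- function(n, alpha_true = 0.5, b0 = -3, b1 = 4,
                                    haze_range = c(0.5, 1) * alpha_true - 1e-6,
                                    event_range = c(alpha_true + 0.02,
                                                    2 * alpha_true),
                                    haze_rate = 0.4,
                                    max_event_days = 14, seed = 1) {
  with_substream(seed, {
    W <- matrix(0, n, 84)
    n_event <- sample.int(max_event_days + 1L, n, replace = TRUE) - 1L
    dhw_true <- numeric(n)
    for (i in seq_len(n)) {
      n_haze <- rbinom(1, 84, haze_rate)
      days <- sample.int(84, min(84, n_haze + n_event[i]))
      ev <- head(days, n_event[i])
      hz <- days[seq_along(days) > n_event[i]]
      W[i, ev] <- runif(length(ev), event_range[1], event_range[2])
      W[i, hz] <- runif(length(hz), haze_range[1], haze_range[2])
      dhw_true[i] <- sum(W[i, ev]) / 7
    }
    p <- stats::plogis(b0 + b1 * dhw_true)
    list(windows = W, dhw_true = dhw_true,
         bleached = rbinom(n, 1L, p), p = p)
  })
}
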