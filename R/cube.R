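# Gridded containers: daily SST cubes and monthly fields, plus the
# plain-text grid serialization used throughout the package.

#' Construct a daily SST cube
#'
#' A lightweight container for a lat x lon x time block of daily
#' sea-surface temperature (deg C).  Cells may be NA (land).
#'
#' @param values numeric array `[nlat, nlon, ndays]` in deg C.
#' @param lon,lat numeric vectors of cell-center coordinates (degrees).
#' @param dates `Date` vector, one per time slice, strictly increasing daily.
#' @return an object of class `sst_cube`.
#' @export
sst_cube <- function(values, lon, lat, dates) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3-d array [lat, lon, time]", call. = FALSE)
  }
  d <- dim(values)
  if (d[1] != length(lat) || d[2] != length(lon) || d[3] != length(dates)) {
    stop("dimension mismatch between 'values' and lon/lat/dates", call. = FALSE)
  }
  dates <- as.Date(dates)
  structure(list(values = values, lon = lon, lat = lat, dates = dates),
            class = "sst_cube")
}

#' @export
print.sst_cube <- function(x, ...) {
  cat(sprintf("<sst_cube> %d x %d cells, %d days (%s to %s)\n",
              length(x$lat), length(x$lon), length(x$dates),
              min(x$dates), max(x$dates)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  SST range: %.2f to %.2f degC\n", rng[1], rng[2]))
  invisible(x)
}

#' Construct a monthly field
#'
#' Per-cell, per-month values (typically monthly mean SST).  The time axis
#' is the (year, month) pair of each slice; `complete` flags months whose
#' day coverage met the aggregation tolerance.
#'
#' @param values numeric array `[nlat, nlon, nmonths]`.
#' @param lon,lat cell-center coordinates (degrees).
#' @param year,month integer vectors, one per slice.
#' @param complete logical vector, one per slice (default all `TRUE`).
#' @return an object of class `monthly_field`.
#' @export
monthly_field <- function(values, lon, lat, year, month, complete = NULL) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L) {
    stop("'values' must be a 3-d array [lat, lon, month]", call. = FALSE)
  }
  n <- d[3]
  if (length(year) != n || length(month) != n) {
    stop("year/month must have one entry per time slice", call. = FALSE)
  }
  structure(list(values = values, lon = lon, lat = lat,
                 year = as.integer(year), month = as.integer(month),
                 complete = complete %||% rep(TRUE, n)),
            class = "monthly_field")
}

#' @export
print.monthly_field <- function(x, ...) {
  cat(sprintf("<monthly_field> %d x %d cells, %d months (%d-%02d to %d-%02d)\n",
              length(x$lat), length(x$lon), length(x$year),
              x$year[1], x$month[1],
              x$year[length(x$year)], x$month[length(x$month)]))
  invisible(x)
}

#' Write / read a gridded field or cube as plain-text CSV
#'
#' Grids are stored in long format (`lat, lon, time, value`) preceded by
#' commented header lines carrying the axis metadata, so a write/read
#' round trip reproduces values and coordinates to representation
#' precision.  This text serialization is the package's native grid format.
#'
#' @param x an `sst_cube`, `monthly_field`, or plain matrix `[nlat, nlon]`.
#' @param path output file path.
#' @return `write_grid` returns `path` invisibly; `read_grid` returns an
#'   object of the class recorded in the file header.
#' @export
write_grid <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "sst_cube")) {
    writeLines(c("# class: sst_cube",
                 paste0("# lon: ", paste(format(x$lon, digits = 12), collapse = ",")),
                 paste0("# lat: ", paste(format(x$lat, digits = 12), collapse = ",")),
                 paste0("# dates: ", paste(as.character(x$dates), collapse = ","))),
               con)
    df <- data.frame(value = as.vector(x$values))
  } else if (inherits(x, "monthly_field")) {
    writeLines(c("# class: monthly_field",
                 paste0("# lon: ", paste(format(x$lon, digits = 12), collapse = ",")),
                 paste0("# lat: ", paste(format(x$lat, digits = 12), collapse = ",")),
                 paste0("# year: ", paste(x$year, collapse = ",")),
                 paste0("# month: ", paste(x$month, collapse = ",")),
                 paste0("# complete: ", paste(as.integer(x$complete), collapse = ","))),
               con)
    df <- data.frame(value = as.vector(x$values))
  } else if (is.matrix(x)) {
    lon <- attr(x, "lon") %||% seq_len(ncol(x))
    lat <- attr(x, "lat") %||% seq_len(nrow(x))
    writeLines(c("# class: matrix",
                 paste0("# lon: ", paste(format(lon, digits = 12), collapse = ",")),
                 paste0("# lat: ", paste(format(lat, digits = 12), collapse = ","))),
               con)
    df <- data.frame(value = as.vector(x))
  } else {
    stop("unsupported grid object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0) stop("not a grid file (missing metadata header): ", path,
                             call. = FALSE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    meta[[key]] <- strsplit(val, ",", fixed = TRUE)[[1]]
  }
  body <- read.csv(text = lines[!grepl("^#", lines)])
  lon <- as.numeric(meta$lon); lat <- as.numeric(meta$lat)
  cls <- meta$class
  if (identical(cls, "sst_cube")) {
    dates <- as.Date(meta$dates)
    arr <- array(body$value, dim = c(length(lat), length(lon), length(dates)))
    sst_cube(arr, lon, lat, dates)
  } else if (identical(cls, "monthly_field")) {
    yr <- as.integer(meta$year); mo <- as.integer(meta$month)
    arr <- array(body$value, dim = c(length(lat), length(lon), length(yr)))
    monthly_field(arr, lon, lat, yr, mo, as.logical(as.integer(meta$complete)))
  } else if (identical(cls, "matrix")) {
    m <- matrix(body$value, nrow = length(lat), ncol = length(lon))
    attr(m, "lon") <- lon; attr(m, "lat") <- lat
    m
  } else {
    stop("unknown grid class in header: ", cls, call. = FALSE)
  }
}
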