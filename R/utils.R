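# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Seeds the Mersenne-Twister stream, runs `expr`, and restores whatever
#' `.Random.seed` was in place before, so generator substreams do not
#' perturb each other or the caller.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_substream <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic substream offsets so adding a generator never shifts the
# draws of another (one stream per generator family).
.substream_offsets <- c(sst = 11L, covariates = 23L, observations = 37L,
                        typhoons = 53L, sites = 71L)

substream_seed <- function(seed, stream) {
  off <- .substream_offsets[[stream]]
  (as.integer(seed) * 101L + off) %% 2147483629L
}

#' Decimal year of a Date (month-midpoint convention for monthly data)
#' @keywords internal
#' @noRd
decimal_year <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  start <- as.Date(paste0(y, "-01-01"))
  len <- ifelse(((y %% 4 == 0) & (y %% 100 != 0)) | (y %% 400 == 0), 366, 365)
  y + as.numeric(dates - start) / len
}

# Decimal-year center of a month (m in 1..12): y + (m - 0.5)/12.
month_midpoint <- function(year, month) year + (month - 0.5) / 12

#' Great-circle distance matrix (km) between two sets of lon/lat points
#' @keywords internal
#' @noRd
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distm(cbind(lon1, lat1), cbind(lon2, lat2),
                   fun = geosphere::distHaversine) / 1000
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("'%s' must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}
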