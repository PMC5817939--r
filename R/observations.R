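# Bleaching observation records: parsing/validation, QC reclassification of
# non-thermal events, and Moran's I spatial autocorrelation of residuals.

required_record_columns <- c("lon", "lat", "date", "depth_m", "severity",
                             "bleached")

#' Parse and validate bleaching records from CSV
#'
#' Expected columns: `lon`, `lat`, `date` (ISO 8601), `depth_m`, `severity`
#' (`high`/`medium`/`low`/`none`/`NA`), `bleached` (0/1), optional
#' `nonthermal_flag` and `source`.  Rows violating the record invariants
#' (coordinate ranges, severity/bleached consistency, unparseable dates)
#' are rejected individually and reported with their line numbers in the
#' `"rejected"` attribute; a missing mandatory column aborts.
#'
#' @param path CSV file path.
#' @return data.frame of valid records, with attribute `"rejected"`
#'   (data.frame of line numbers and reasons).
#' @export
parse_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_record_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"nonthermal_flag" %in% names(raw)) raw$nonthermal_flag <- FALSE
  if (!"source" %in% names(raw)) raw$source <- NA_character_
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  reasons <- character(nrow(raw))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- why
  }
  bad(!is.finite(raw$lon) | raw$lon < -180 | raw$lon > 180, "lon out of [-180, 180]")
  bad(!is.finite(raw$lat) | raw$lat < -90 | raw$lat > 90, "lat out of [-90, 90]")
  bad(is.na(date), "unparseable date")
  bad(!raw$bleached %in% c(0, 1), "bleached must be 0 or 1")
  bad(!is.na(raw$severity) &
        !raw$severity %in% c("high", "medium", "low", "none"), "unknown severity")
  bad(!is.na(raw$severity) & raw$severity == "none" & raw$bleached == 1,
      "severity 'none' inconsistent with bleached = 1")
  ok <- reasons == ""
  out <- raw[ok, , drop = FALSE]
  out$date <- date[ok]
  out$bleached <- as.integer(out$bleached)
  out$nonthermal_flag <- as.logical(out$nonthermal_flag)
  rejected <- data.frame(line = which(!ok) + 1L,  # +1 for the header line
                         reason = reasons[!ok])
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " malformed record(s) rejected")
  }
  attr(out, "rejected") <- rejected
  out
}

#' QC reclassification of non-thermal bleaching
#'
#' Records flagged as small non-thermal bleaching events (microatolls,
#' disease, predation) are regarded as nonbleaching when the degree heating
#' week at the observation site and date is zero.  Never turns a
#' nonbleached record into a bleached one; idempotent.
#'
#' @param records data.frame with `bleached` and `nonthermal_flag`.
#' @param dhw_at_record DHW (degC-weeks) per record; must be non-missing
#'   for every flagged record.
#' @return the records with reclassified `bleached`, and attribute
#'   `"n_reclassified"`.
#' @export
qc_reclassify <- function(records, dhw_at_record) {
  if (length(dhw_at_record) != nrow(records)) {
    stop("one DHW value per record is required", call. = FALSE)
  }
  flagged <- records$nonthermal_flag %||% rep(FALSE, nrow(records))
  flagged[is.na(flagged)] <- FALSE
  if (any(flagged & !is.finite(dhw_at_record))) {
    stop("missing DHW for a flagged record", call. = FALSE)
  }
  hit <- flagged & dhw_at_record <= 0 & records$bleached == 1L
  records$bleached[hit] <- 0L
  records$severity[hit] <- "none"
  attr(records, "n_reclassified") <- sum(hit)
  records
}

#' Build a spatial weight matrix for Moran's I
#'
#' Inverse great-circle distance weights with an optional cutoff beyond
#' which weights are zero; zero diagonal; optionally row-standardized.
#'
#' @param lon,lat point coordinates.
#' @param cutoff_km zero weight beyond this distance (default `Inf`).
#' @param row_standardize divide each row by its sum (default TRUE).
#' @return an n x n weight matrix.
#' @export
inverse_distance_weights <- function(lon, lat, cutoff_km = Inf,
                                     row_standardize = TRUE) {
  D <- gc_dist_km(lon, lat, lon, lat)
  W <- 1 / pmax(D, 1e-6)
  W[D > cutoff_km] <- 0
  diag(W) <- 0
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  W
}

#' Moran's I with a permutation test
#'
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2`, z being mean-centered
#' residuals and W the total weight.  Significance comes from random
#' permutations of the residuals over the locations.  Constant residuals
#' make I undefined and are reported as such (NA statistic), never as zero.
#'
#' @param residuals numeric vector (model residuals), length >= 4.
#' @param weights n x n spatial weight matrix (e.g.
#'   [inverse_distance_weights()]); zero diagonal expected.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @return list: `I`, `expected` (-1/(n-1)), `p_value` (two-sided
#'   permutation p), `n_perm`, `permuted` (the null draws).
#' @export
morans_i <- function(residuals, weights, n_perm = 999, seed = 1) {
  n <- length(residuals)
  if (n < 4) stop("Moran's I needs >= 4 points", call. = FALSE)
  if (!all(dim(weights) == c(n, n))) {
    stop("weight matrix must be n x n", call. = FALSE)
  }
  if (sd(residuals) == 0) {
    return(list(I = NA_real_, expected = -1 / (n - 1), p_value = NA_real_,
                n_perm = 0L, permuted = numeric(0),
                note = "constant residuals: Moran's I undefined"))
  }
  W_tot <- sum(weights)
  stat <- function(z) {
    zc <- z - mean(z)
    (n / W_tot) * as.numeric(zc %*% weights %*% zc) / sum(zc^2)
  }
  I_obs <- stat(residuals)
  expected <- -1 / (n - 1)
  permuted <- with_substream(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(residuals)), numeric(1))
  })
  p <- (1 + sum(abs(permuted - expected) >= abs(I_obs - expected))) /
    (n_perm + 1)
  list(I = I_obs, expected = expected, p_value = p, n_perm = n_perm,
       permuted = permuted)
}
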