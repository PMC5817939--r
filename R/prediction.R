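# Grid-wide prediction: thermal-index grids, ensemble probability maps,
# multi-year bleaching frequency, and the UV-screening scenario.

#' Thermal index evaluated on the whole grid at a date
#'
#' Computes the trailing-window index (DHW/DCW by default) for every cell,
#' with the window ending on `date`.
#'
#' @param sst an [sst_cube()].
#' @param clim a [climatology_set()].
#' @param spec an [index_spec()] (daily kinds only).
#' @param date window end date.
#' @return matrix `[nlat, nlon]` of index values.
#' @export
index_grid <- function(sst, clim, spec, date) {
  idx <- match(as.Date(date), sst$dates)
  if (is.na(idx) || idx < 84) {
    stop("cube does not cover the 84-day window ending ", date, call. = FALSE)
  }
  win <- sst$values[, , (idx - 83):idx, drop = FALSE]
  baseline <- if (spec$baseline == "mmm_max") clim$mmm_max else clim$mmm
  if (spec$kind == "dcw") {
    cs <- sweep(-win, c(1, 2), clim$mmm, "+")       # MMM - SST
    return(apply(cs * (cs >= 0), c(1, 2), sum) / 7)
  }
  hs <- pmax(sweep(win, c(1, 2), baseline, "-"), 0)
  thr <- if (spec$filter_mode == "sigma_scaled_beta") spec$beta * clim$sigma_m
         else matrix(spec$alpha, nrow(baseline), ncol(baseline))
  keep <- sweep(hs, c(1, 2), thr, ">=")
  divisor <- if (spec$kind == "dhw") 7 else
    stop("index_grid supports daily kinds (dhw, dcw)", call. = FALSE)
  apply(hs * keep, c(1, 2), sum) / divisor
}

#' Warmest calendar month of each cell in a year
#'
#' @param monthly a [monthly_field()].
#' @param year target year.
#' @return integer matrix `[nlat, nlon]` of month numbers.
#' @export
warmest_month <- function(monthly, year) {
  sel <- which(monthly$year == year)
  if (length(sel) == 0) stop("year ", year, " not in monthly field", call. = FALSE)
  block <- monthly$values[, , sel, drop = FALSE]
  wm <- apply(block, c(1, 2), which.max)
  matrix(monthly$month[sel][wm], nrow(wm), ncol(wm))
}

#' Ensemble bleaching-probability map
#'
#' Applies every cross-validation model to the per-cell covariate layers
#' and averages the probabilities; the binary alert layer thresholds the
#' ensemble mean at the mean of the per-repeat optimized evaluation
#' thresholds (per-member binarization before voting is available via
#' `binarize = "vote"`).
#'
#' @param models a `cv_result` with kept models, or a list of
#'   `bleach_model`s.
#' @param layers named list of matrices, one per model variable (the
#'   thermal index layer under its column name, plus `c`, `u`, `k`, `d`,
#'   `s`, `v` as needed).
#' @param threshold evaluation threshold for the binary map; defaults to
#'   the cv_result's mean optimized threshold.
#' @param binarize `"mean"` (threshold the ensemble mean; default) or
#'   `"vote"` (binarize each member, then majority).
#' @param year,month optional labels carried in the result.
#' @return object of class `prediction_grid`: `probability`, `binary`,
#'   `member_range` (per-cell min/max over members), `threshold`.
#' @export
predict_grid <- function(models, layers, threshold = NULL,
                         binarize = c("mean", "vote"),
                         year = NA, month = NA) {
  binarize <- match.arg(binarize)
  if (inherits(models, "cv_result")) {
    threshold <- threshold %||% models$summary$mean_threshold
    models <- models$models
    if (is.null(models)) stop("cv_result was run with keep_models = FALSE",
                              call. = FALSE)
  }
  if (length(models) == 0) stop("empty model ensemble", call. = FALSE)
  if (is.null(threshold)) stop("an evaluation threshold is required",
                               call. = FALSE)
  vars <- unique(unlist(lapply(models, function(m) m$spec$variables)))
  missing_layers <- setdiff(vars, names(layers))
  if (length(missing_layers) > 0) {
    stop("missing covariate layer(s): ", paste(missing_layers, collapse = ", "),
         call. = FALSE)
  }
  dims <- dim(layers[[vars[1]]])
  tab <- as.data.frame(lapply(layers[vars], as.vector))
  member_p <- vapply(models, function(m) predict_probability(m, tab),
                     numeric(nrow(tab)))
  p_mean <- rowMeans(member_p)
  prob <- matrix(p_mean, dims[1], dims[2])
  binary <- if (binarize == "mean") {
    prob >= threshold
  } else {
    matrix(rowMeans(member_p >= threshold) > 0.5, dims[1], dims[2])
  }
  structure(list(probability = prob, binary = binary,
                 member_range = list(
                   min = matrix(apply(member_p, 1, min), dims[1], dims[2]),
                   max = matrix(apply(member_p, 1, max), dims[1], dims[2])),
                 threshold = threshold, year = year, month = month),
            class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf("<prediction_grid> %d x %d | prob %.2f-%.2f | %.0f%% cells in alert\n",
              nrow(x$probability), ncol(x$probability),
              min(x$probability), max(x$probability), 100 * mean(x$binary)))
  invisible(x)
}

#' Multi-year bleaching frequency
#'
#' Per cell, `100 * (years with a bleaching alert) / (years evaluated)`;
#' 100% means bleaching predicted in every year.
#'
#' @param binary_grids list of logical matrices (or `prediction_grid`s),
#'   one per year.
#' @return percentage matrix.
#' @export
bleaching_frequency <- function(binary_grids) {
  if (length(binary_grids) == 0) stop("no yearly grids supplied", call. = FALSE)
  mats <- lapply(binary_grids, function(g)
    if (inherits(g, "prediction_grid")) g$binary else g)
  100 * Reduce(`+`, mats) / length(mats)
}

#' UV-screening scenario specification
#'
#' Multiplicative changes emulating screening of sunlight with fishnets:
#' UV-B reduced to 60% and turbidity K490 raised to 140% by default.
#'
#' @param uv_factor UV-B multiplier (> 0; default 0.6).
#' @param turbidity_factor K490 multiplier (> 0; default 1.4).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(uv_factor = 0.6, turbidity_factor = 1.4) {
  if (uv_factor <= 0 || turbidity_factor <= 0) {
    stop("scenario factors must be positive", call. = FALSE)
  }
  structure(list(uv_factor = uv_factor, turbidity_factor = turbidity_factor),
            class = "scenario_spec")
}

#' Apply a management scenario to covariate layers
#'
#' Scales the UV-B layer(s) by `uv_factor` and the K490 layer by
#' `turbidity_factor`; every other layer is untouched.
#'
#' @param layers named list of covariate layers; UV-B under `u` or `uv`,
#'   turbidity under `k` or `k490`.
#' @param scenario a [scenario_spec()].
#' @return the modified layer list.
#' @export
apply_scenario <- function(layers, scenario = scenario_spec()) {
  stopifnot(inherits(scenario, "scenario_spec"))
  uv_names <- intersect(c("u", "uv"), names(layers))
  k_names <- intersect(c("k", "k490"), names(layers))
  if (length(uv_names) == 0 || length(k_names) == 0) {
    stop("layers must include UV-B ('u'/'uv') and turbidity ('k'/'k490')",
         call. = FALSE)
  }
  for (nm in uv_names) layers[[nm]] <- layers[[nm]] * scenario$uv_factor
  for (nm in k_names) layers[[nm]] <- layers[[nm]] * scenario$turbidity_factor
  layers
}
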