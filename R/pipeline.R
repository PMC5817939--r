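# Workbench: configuration, record I/O, the end-to-end pipeline, and the
# conditional reproduction entry point for a deposited field dataset.

#' Write / read bleaching records as CSV
#'
#' Columns: lon, lat, date (ISO 8601), depth_m, severity, bleached,
#' nonthermal_flag, source.  `read_records()` validates via
#' [parse_records()].
#'
#' @param records data.frame of records.
#' @param path CSV path.
#' @return `write_records` returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  keep <- intersect(c("lon", "lat", "date", "depth_m", "severity", "bleached",
                      "nonthermal_flag", "source"), names(records))
  write.csv(records[keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) parse_records(path)

#' Configure an end-to-end pipeline run
#'
#' Resolves every setting explicitly (the resolved configuration is dumped
#' into the run manifest, so no hidden defaults survive a run).
#'
#' @param scenario a [synthetic_scenario()] describing the input world, or
#'   `NULL` with `sst`/`fields`/`records` supplied in `inputs`.
#' @param index an [index_spec()] for the thermal index.
#' @param family `"glm"` or `"rf"`.
#' @param filter_mode `NULL` (fixed filter), `"alpha"` or `"beta"` for a
#'   joint filtering-threshold search.
#' @param precision filtering-threshold grid step.
#' @param repeats cross-validation repeats.
#' @param nonthermal_fraction fraction of planted non-thermal events.
#' @param screening a [scenario_spec()] for the UV-screening scenario.
#' @param predict_years years to map (default: the scenario's last 2 years).
#' @param seed master seed.
#' @param out_dir output directory (created if absent).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario, index = index_spec(), family = "glm",
                            filter_mode = NULL, precision = 0.05,
                            repeats = 10, nonthermal_fraction = 0.05,
                            screening = scenario_spec(),
                            predict_years = NULL, seed = 1,
                            out_dir = tempfile("reefbleach_run_")) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(index, "index_spec"))
  predict_years <- predict_years %||%
    seq(scenario$years[2] - 1, scenario$years[2])
  if (any(predict_years < scenario$years[1] | predict_years > scenario$years[2])) {
    stop("predict_years outside the scenario span", call. = FALSE)
  }
  structure(list(scenario = scenario, index = index, family = family,
                 filter_mode = filter_mode, precision = precision,
                 repeats = repeats, nonthermal_fraction = nonthermal_fraction,
                 screening = screening, predict_years = predict_years,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Assemble the per-cell prediction layers of one year, evaluating DHW/DCW
# in each cell's own warmest month (window ending on that month's last day).
prediction_layers <- function(sst, clim, monthly, fields, index, year) {
  wm <- warmest_month(monthly, year)
  months <- sort(unique(as.vector(wm)))
  nlat <- length(sst$lat); nlon <- length(sst$lon)
  idx_l <- matrix(NA_real_, nlat, nlon)
  dcw_l <- matrix(NA_real_, nlat, nlon)
  uv_l <- matrix(NA_real_, nlat, nlon)
  for (m in months) {
    end <- seq(as.Date(sprintf("%d-%02d-01", year, m)),
               by = "month", length.out = 2)[2] - 1
    gi <- index_grid(sst, clim, index, end)
    gd <- index_grid(sst, clim, index_spec("dcw"), end)
    sel <- wm == m
    idx_l[sel] <- gi[sel]
    dcw_l[sel] <- gd[sel]
    uv_m <- fields$uv[, , m]
    uv_l[sel] <- uv_m[sel]
  }
  layers <- list(idx_l, c = dcw_l, u = uv_l, k = fields$k490,
                 d = fields$depth,
                 s = current_speed(fields$u_current, fields$v_current),
                 v = clim$sigma_m)
  names(layers)[1] <- switch(index$kind, dhw = "dhw", dhm = "dhm",
                             weekly_sst = "sst_week", monthly_sst = "sst_month",
                             dcw = "dcw")
  layers
}

#' Run the full bleaching-prediction pipeline
#'
#' Executes the five analysis steps in order: (1) QC reclassification of
#' non-thermal bleaching; (2) Moran's I check of spatial autocorrelation in
#' baseline-model residuals; (3) collinearity screen; (4) variable (and
#' optionally filtering-threshold) optimization under repeated 70/30
#' cross-validation; (5) grid-wide probability and bleaching-frequency maps
#' for the configured years, plus the UV-screening scenario.  Every
#' artifact is written under the configured output directory and listed
#' with its MD5 hash in the run manifest.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, an object of class `pipeline_run` with all stage
#'   outputs and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$scenario

  # inputs
  sst <- generate_sst(sc)
  fields <- generate_covariates(sc)
  monthly <- monthly_aggregate(sst)
  clim <- climatology_set(monthly)
  sites <- sample_record_sites(sc)
  table0 <- extract_at_records(sst, clim, fields, sites, config$index)
  records <- generate_observations(sc, table0,
                                   nonthermal_fraction = config$nonthermal_fraction)

  # Step 1: QC reclassification (non-thermal events with zero DHW)
  index_col <- attr(table0, "index_column")
  dhw_for_qc <- if (index_col == "dhw") records[[index_col]] else {
    extract_at_records(sst, clim, fields, sites, index_spec("dhw"),
                       keep_windows = FALSE)$dhw
  }
  records <- qc_reclassify(records, dhw_for_qc)
  table <- records
  for (a in c("index_column", "hs_windows", "hs_monthly", "sigma_m")) {
    attr(table, a) <- attr(table0, a)
  }

  # Step 2: Moran's I of baseline-model residuals
  base_model <- fit_glm(table, model_spec("glm", variables = index_col))
  resid <- table$bleached - predict_probability(base_model, table)
  W <- inverse_distance_weights(table$lon, table$lat)
  moran <- morans_i(resid, W, n_perm = 199, seed = config$seed)

  # Step 3: collinearity screen
  collin <- collinearity_screen(table)

  # Step 4: optimization
  optional <- intersect(c("v", "k", "d", "s"), collin$retained)
  if (length(optional) == 0) optional <- c("v", "k", "d", "s")
  search <- variable_combination_search(
    table, family = config$family, optional = optional,
    filter_mode = config$filter_mode, precision = config$precision,
    repeats = config$repeats, seed = config$seed)
  best_vars <- c(index_col, "c", "u", search$best_combination)
  final_table <- if (!is.null(config$filter_mode)) {
    thr <- if (config$filter_mode == "beta")
      search$best_threshold * attr(table, "sigma_m") else search$best_threshold
    rebuild_index(table, thr)
  } else table
  final_cv <- repeated_split_cv(final_table,
                                model_spec(config$family, variables = best_vars),
                                repeats = config$repeats, seed = config$seed)
  final_model <- fit_model(final_table,
                           model_spec(config$family, variables = best_vars))
  overdisp <- overdispersion_check(final_model)

  # Step 5: spatial prediction + UV-screening scenario
  maps <- list(); maps_screened <- list()
  for (y in config$predict_years) {
    layers <- prediction_layers(sst, clim, monthly, fields, config$index, y)
    maps[[as.character(y)]] <-
      predict_grid(final_cv, layers, year = y)
    maps_screened[[as.character(y)]] <-
      predict_grid(final_cv, apply_scenario(layers, config$screening), year = y)
  }
  freq <- bleaching_frequency(maps)
  freq_screened <- bleaching_frequency(maps_screened)

  # artifacts
  paths <- list(
    records = file.path(config$out_dir, "records.csv"),
    table = file.path(config$out_dir, "covariate_table.csv"),
    collinearity = file.path(config$out_dir, "collinearity_pairs.csv"),
    trace = file.path(config$out_dir, "search_trace.csv"),
    summary = file.path(config$out_dir, "summary.json"),
    frequency = file.path(config$out_dir, "bleaching_frequency.csv"),
    frequency_screened = file.path(config$out_dir,
                                   "bleaching_frequency_screened.csv"))
  write_records(records, paths$records)
  write.csv(as.data.frame(table), paths$table, row.names = FALSE)
  write.csv(collin$pairs, paths$collinearity, row.names = FALSE)
  write.csv(search$trace, paths$trace, row.names = FALSE)
  attr(freq, "lon") <- sst$lon; attr(freq, "lat") <- sst$lat
  attr(freq_screened, "lon") <- sst$lon; attr(freq_screened, "lat") <- sst$lat
  write_grid(freq, paths$frequency)
  write_grid(freq_screened, paths$frequency_screened)
  summary_obj <- list(
    n_records = nrow(records),
    n_bleached = sum(records$bleached),
    n_reclassified = attr(records, "n_reclassified"),
    morans_i = moran$I, morans_p = moran$p_value,
    collinearity_dropped = collin$dropped,
    best_combination = search$best_combination,
    best_filter = search$best_threshold,
    mean_tss = final_cv$summary$mean_tss, se_tss = final_cv$summary$se_tss,
    mean_threshold = final_cv$summary$mean_threshold,
    se_threshold = final_cv$summary$se_threshold,
    overdispersion = overdisp$ratio,
    formula = if (config$family == "glm") model_formula(final_model) else NULL)
  jsonlite::write_json(summary_obj, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    seed = config$seed,
    config = list(family = config$family, filter_mode = config$filter_mode,
                  precision = config$precision, repeats = config$repeats,
                  index_kind = config$index$kind,
                  index_baseline = config$index$baseline,
                  predict_years = config$predict_years,
                  scenario_seed = sc$seed,
                  n_observations = sc$n_observations,
                  uv_factor = config$screening$uv_factor,
                  turbidity_factor = config$screening$turbidity_factor),
    artifacts = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    summary = summary_obj)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(list(
    manifest = manifest, records = records, table = table, clim = clim,
    moran = moran, collinearity = collin, search = search,
    final_cv = final_cv, final_model = final_model,
    maps = maps, maps_screened = maps_screened,
    frequency = freq, frequency_screened = freq_screened,
    out_dir = config$out_dir), class = "pipeline_run"))
}

#' Reproduce the analysis on a deposited observation/covariate table
#'
#' Runs quality control counts and the repeated cross-validation model
#' comparison on a field dataset with pre-computed covariates (columns:
#' `lon`, `lat`, `date`, `bleached`, thermal index `dhw`, and the
#' covariates `c`, `u`, `k`, `d`, `s`, `v`).  This is the entry point for
#' checking reported field-data performance; it requires the deposited CSV
#' to be available locally.
#'
#' @param path CSV path of the deposited table.
#' @param repeats cross-validation repeats (default 10).
#' @param seed integer seed.
#' @return list: record counts, GLM and RF combination-search results.
#' @export
reproduce_field_study <- function(path, repeats = 10, seed = 1) {
  if (!file.exists(path)) {
    stop("deposited observation/covariate table not found at '", path,
         "'; supply the study's source-data CSV to run this reproduction",
         call. = FALSE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("bleached", "dhw", "c", "u", "k", "d", "s", "v")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("deposited table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  attr(tab, "index_column") <- "dhw"
  glm_search <- variable_combination_search(tab, family = "glm",
                                            repeats = repeats, seed = seed)
  rf_search <- variable_combination_search(tab, family = "rf",
                                           repeats = repeats, seed = seed)
  list(n_records = nrow(tab),
       n_bleached = sum(tab$bleached == 1),
       n_nonbleached = sum(tab$bleached == 0),
       glm = glm_search, rf = rf_search,
       best_tss = max(glm_search$best_summary$mean_tss,
                      rf_search$best_summary$mean_tss))
}
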