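# Evaluation metrics, TPR+TNR threshold maximization, repeated 70/30
# cross-validation, and the filtering-threshold and variable-combination
# searches.

#' Confusion counts and evaluation metrics at a probability threshold
#'
#' A row is predicted bleached iff its probability is at or above the
#' threshold.  Metrics: overall accuracy ACC, true positive rate TPR
#' (sensitivity), true negative rate TNR (specificity), and the true skill
#' statistic TSS = TPR + TNR - 1.  With single-class labels the undefined
#' rate is returned NA and flagged in `note`.
#'
#' @param probabilities predicted probabilities in [0, 1].
#' @param labels 0/1 observed outcomes.
#' @param threshold probability cutoff.
#' @return list: `counts` (tp, fp, tn, fn), `metrics` (acc, tpr, tnr, tss,
#'   threshold), and `note` when a rate is undefined.
#' @export
evaluate_at_threshold <- function(probabilities, labels, threshold) {
  stopifnot(length(probabilities) == length(labels))
  pred <- probabilities >= threshold
  pos <- labels == 1
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  note <- if (is.na(tpr) || is.na(tnr)) "single-class labels: rate undefined"
          else NULL
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       metrics = c(acc = (tp + tn) / length(labels),
                   tpr = tpr, tnr = tnr, tss = tpr + tnr - 1,
                   threshold = threshold),
       note = note)
}

#' Optimize the evaluation threshold by TPR + TNR maximization
#'
#' Scans the unique predicted probabilities as candidate thresholds and
#' returns the one maximizing TPR + TNR (equivalently TSS); ties are broken
#' toward the smallest candidate, which maximizes TPR.
#'
#' @param probabilities predicted probabilities.
#' @param labels 0/1 observed outcomes (both classes required).
#' @return list: `threshold`, `metrics` (at the optimum), `candidates`,
#'   `tss_profile` (TSS at every candidate).
#' @export
optimize_evaluation_threshold <- function(probabilities, labels) {
  if (length(unique(labels)) < 2) {
    stop("threshold optimization requires both classes", call. = FALSE)
  }
  cand <- sort(unique(probabilities))
  # counting via suffix sums over the ascending ordering
  o <- order(probabilities)
  p_sorted <- probabilities[o]
  l_sorted <- labels[o]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  # candidates are drawn from the probabilities, so the first index with
  # p >= cand[i] is the first exact occurrence in the ascending order
  first_ge <- match(cand, p_sorted)
  suffix_pos <- rev(cumsum(rev(l_sorted == 1)))
  suffix_pos <- c(suffix_pos, 0L)
  tp <- suffix_pos[first_ge]
  n_ge <- length(labels) - first_ge + 1L
  fp <- n_ge - tp
  tpr <- tp / n_pos
  tnr <- (n_neg - fp) / n_neg
  tss <- tpr + tnr - 1
  best <- which(tss == max(tss))[1]   # candidates ascend: first max = smallest
  ev <- evaluate_at_threshold(probabilities, labels, cand[best])
  list(threshold = cand[best], metrics = ev$metrics, candidates = cand,
       tss_profile = tss)
}

# Pre-draw train/test partitions, re-drawing (up to max_resample times) any
# split leaving a single class in either part.
make_splits <- function(labels, repeats, test_fraction, seed,
                        stratify = FALSE, max_resample = 100) {
  n <- length(labels)
  n_test <- round(test_fraction * n)
  with_substream(seed, {
    lapply(seq_len(repeats), function(r) {
      for (try in seq_len(max_resample)) {
        test <- if (stratify) {
          pos <- which(labels == 1); neg <- which(labels == 0)
          c(sample(pos, round(test_fraction * length(pos))),
            sample(neg, round(test_fraction * length(neg))))
        } else {
          sample.int(n, n_test)
        }
        if (length(unique(labels[test])) == 2 &&
            length(unique(labels[-test])) == 2) {
          return(sort(test))
        }
      }
      stop("could not draw a split with both classes in train and test",
           call. = FALSE)
    })
  })
}

#' Repeated random 70/30 cross-validation
#'
#' For each of `repeats` random partitions: fit on the training 70%,
#' optimize the evaluation threshold on the training predictions, and score
#' the held-out 30% at that threshold.  Summaries are the mean and
#' standard error across repeats.  Splits leaving one class empty are
#' re-drawn (logged via the split generator); optimizing the threshold on
#' the test predictions instead is available as a compatibility switch.
#'
#' @param table covariate table with `bleached`.
#' @param spec a [model_spec()].
#' @param repeats number of random partitions (default 10).
#' @param test_fraction held-out fraction (default 0.3).
#' @param seed integer seed driving the partitions.
#' @param threshold_on `"train"` (default; no leakage) or `"test"`.
#' @param stratify preserve class balance in the split (default FALSE,
#'   plain random sampling).
#' @param keep_models retain the fitted per-repeat models (needed for
#'   ensemble prediction; default TRUE).
#' @param splits optional pre-drawn list of test-index vectors.
#' @return object of class `cv_result`: `per_repeat` data.frame (threshold
#'   and test ACC/TPR/TNR/TSS per repeat), `summary` (mean and SE of test
#'   TSS and of the evaluation threshold), `models` (if kept), `spec`.
#' @export
repeated_split_cv <- function(table, spec, repeats = 10, test_fraction = 0.3,
                              seed = 1, threshold_on = c("train", "test"),
                              stratify = FALSE, keep_models = TRUE,
                              splits = NULL) {
  threshold_on <- match.arg(threshold_on)
  labels <- table$bleached
  splits <- splits %||% make_splits(labels, repeats, test_fraction, seed,
                                    stratify)
  models <- if (keep_models) vector("list", length(splits)) else NULL
  rows <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    test <- splits[[r]]
    train_tab <- table[-test, , drop = FALSE]
    test_tab <- table[test, , drop = FALSE]
    model <- fit_model(train_tab, spec)
    p_train <- predict_probability(model, train_tab)
    p_test <- predict_probability(model, test_tab)
    thr <- if (threshold_on == "train") {
      optimize_evaluation_threshold(p_train, train_tab$bleached)$threshold
    } else {
      optimize_evaluation_threshold(p_test, test_tab$bleached)$threshold
    }
    ev <- evaluate_at_threshold(p_test, test_tab$bleached, thr)
    if (keep_models) models[[r]] <- model
    rows[[r]] <- data.frame(repeat_id = r, threshold = thr,
                            acc = ev$metrics[["acc"]], tpr = ev$metrics[["tpr"]],
                            tnr = ev$metrics[["tnr"]], tss = ev$metrics[["tss"]],
                            n_test = length(test))
  }
  per_repeat <- do.call(rbind, rows)
  se <- function(x) sd(x) / sqrt(length(x))
  structure(list(
    per_repeat = per_repeat,
    summary = list(mean_tss = mean(per_repeat$tss), se_tss = se(per_repeat$tss),
                   mean_acc = mean(per_repeat$acc),
                   mean_tpr = mean(per_repeat$tpr),
                   mean_tnr = mean(per_repeat$tnr),
                   mean_threshold = mean(per_repeat$threshold),
                   se_threshold = se(per_repeat$threshold)),
    models = models, spec = spec, repeats = length(splits)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> %d repeats | mean TSS %.3f (SE %.3f) | eval threshold %.3f +/- %.3f\n",
              x$repeats, s$mean_tss, s$se_tss, s$mean_threshold, s$se_threshold))
  invisible(x)
}

#' Candidate grid for the filtering-threshold search
#'
#' Integer-stepped grids (values `i / 100` at the default 0.01 precision)
#' over the constant-threshold bounds [0, 1.5] degC (151 candidates) or the
#' sigma_m-multiplier bounds [0.1, 2.5] (241 candidates).
#'
#' @param mode `"alpha"` or `"beta"`.
#' @param precision grid step (default 0.01).
#' @return numeric vector of candidate thresholds.
#' @export
threshold_grid <- function(mode = c("alpha", "beta"), precision = 0.01) {
  mode <- match.arg(mode)
  bounds <- if (mode == "alpha") c(0, 1.5) else c(0.1, 2.5)
  steps <- round(bounds / precision)
  if (steps[2] <= steps[1]) stop("empty threshold grid", call. = FALSE)
  seq(steps[1], steps[2]) * precision
}

# Rebuild the thermal index column of a cached table for one candidate
# threshold.  `thr` may be per-row (sigma-scaled filtering).
rebuild_index <- function(table, thr) {
  W <- attr(table, "hs_windows")
  M <- attr(table, "hs_monthly")
  col <- attr(table, "index_column")
  if (!is.null(W)) {
    table[[col]] <- rowSums(W * (W >= thr)) / 7
  } else if (!is.null(M)) {
    table[[col]] <- rowSums(M * (M >= thr))
  } else {
    stop("table carries no cached HotSpot windows; re-extract with keep_windows = TRUE",
         call. = FALSE)
  }
  table
}

#' Search the HotSpot filtering threshold by cross-validated TSS
#'
#' For every candidate on the grid the thermal index is recomputed from the
#' cached per-record HotSpot windows (constant alpha, or per-record
#' beta * sigma_m) and scored by [repeated_split_cv()]; identical splits
#' are reused across candidates so candidates differ only in the index.
#' The candidate maximizing mean test TSS wins; ties go to the smallest.
#'
#' @param table covariate table from [extract_at_records()] with cached
#'   windows (`keep_windows = TRUE`).
#' @param spec a [model_spec()]; its variables must include the table's
#'   index column.
#' @param mode `"alpha"` (constant, degC) or `"beta"` (sigma_m multiplier).
#' @param precision grid step (default 0.01).
#' @param repeats,test_fraction,seed,threshold_on passed to
#'   [repeated_split_cv()].
#' @return object of class `search_result`: `best_threshold`,
#'   `best_summary`, `per_candidate` (candidate, mean/SE TSS, mean/SE
#'   evaluation threshold), `trace` (one row per candidate x repeat),
#'   `mode`, `grid`.
#' @export
filtering_threshold_search <- function(table, spec, mode = c("alpha", "beta"),
                                       precision = 0.01, repeats = 10,
                                       test_fraction = 0.3, seed = 1,
                                       threshold_on = "train") {
  mode <- match.arg(mode)
  grid <- threshold_grid(mode, precision)
  sigma_v <- attr(table, "sigma_m")
  if (mode == "beta" && is.null(sigma_v)) {
    stop("beta mode needs the cached per-record sigma_m", call. = FALSE)
  }
  splits <- make_splits(table$bleached, repeats, test_fraction, seed)
  trace <- vector("list", length(grid))
  per_cand <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    thr <- if (mode == "alpha") grid[g] else grid[g] * sigma_v
    tab_g <- rebuild_index(table, thr)
    cv <- repeated_split_cv(tab_g, spec, repeats = repeats,
                            test_fraction = test_fraction, seed = seed,
                            threshold_on = threshold_on, keep_models = FALSE,
                            splits = splits)
    trace[[g]] <- cbind(candidate = grid[g], cv$per_repeat)
    per_cand[[g]] <- data.frame(candidate = grid[g],
                                mean_tss = cv$summary$mean_tss,
                                se_tss = cv$summary$se_tss,
                                mean_threshold = cv$summary$mean_threshold,
                                se_threshold = cv$summary$se_threshold)
  }
  per_candidate <- do.call(rbind, per_cand)
  best <- which(per_candidate$mean_tss == max(per_candidate$mean_tss))[1]
  structure(list(mode = mode, grid = grid,
                 best_threshold = per_candidate$candidate[best],
                 best_summary = per_cand[[best]],
                 per_candidate = per_candidate,
                 trace = do.call(rbind, trace)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s | best %s = %.2f | mean TSS %.3f\n",
              x$mode %||% "combination",
              if (identical(x$mode, "beta")) "beta" else "alpha",
              x$best_threshold, max(x$per_candidate$mean_tss)))
  invisible(x)
}

#' Plot a TSS-vs-threshold search profile
#'
#' @param x a `search_result` from [filtering_threshold_search()].
#' @param ... passed to [plot()].
#' @export
plot.search_result <- function(x, ...) {
  pc <- x$per_candidate
  plot(pc$candidate, pc$mean_tss, type = "l",
       xlab = if (identical(x$mode, "beta")) expression(beta) else
         expression(alpha ~ "(degC)"),
       ylab = "mean test TSS", ...)
  graphics::abline(v = x$best_threshold, lty = 2)
  invisible(x)
}

all_nonempty_subsets <- function(vars) {
  unlist(lapply(seq_along(vars), function(k)
    utils::combn(vars, k, simplify = FALSE)), recursive = FALSE)
}

#' Search the optimal variable combination (optionally jointly with the
#' filtering threshold)
#'
#' Evaluates the 15 non-empty subsets of the four optional covariates
#' (historical variability `v`, turbidity `k`, depth `d`, current speed
#' `s`), each added to the thermal index plus the always-included core
#' (degree cooling week `c` and UV-B `u`).  In joint mode every
#' combination is crossed with the full filtering-threshold grid, giving
#' the `repeats x 15 x |grid|` factorial.  The empty subset (index + core
#' only) is computed for transparency and reported separately.
#'
#' @param table covariate table (cached windows required in joint mode).
#' @param family `"glm"`, `"rf"` or `"stub"`.
#' @param core always-included covariates (default `c("c", "u")`).
#' @param optional optional covariates (default `c("v", "k", "d", "s")`).
#' @param filter_mode `NULL` (no threshold search) or `"alpha"` / `"beta"`.
#' @param precision,repeats,test_fraction,seed,threshold_on as in
#'   [filtering_threshold_search()].
#' @param rf_trees,rf_seed forest settings when `family = "rf"`.
#' @param parsimony `"max"` (default: the combination with the highest mean
#'   test TSS wins outright) or `"one_se"` (among combinations within one
#'   standard error of the maximum, the smallest subset wins -- the usual
#'   one-SE parsimony rule; useful because extra uninformative covariates
#'   change test TSS only within its sampling noise).
#' @return object of class `search_result`: `best_combination` (character),
#'   `best_threshold` (joint mode), `per_combination`, `trace` (one row per
#'   combination x candidate x repeat in joint mode), `empty_combination`.
#' @export
variable_combination_search <- function(table, family = "glm",
                                        core = c("c", "u"),
                                        optional = c("v", "k", "d", "s"),
                                        filter_mode = NULL, precision = 0.01,
                                        repeats = 10, test_fraction = 0.3,
                                        seed = 1, threshold_on = "train",
                                        rf_trees = 500, rf_seed = 1,
                                        parsimony = c("max", "one_se")) {
  parsimony <- match.arg(parsimony)
  index_col <- attr(table, "index_column") %||% "dhw"
  missing_cols <- setdiff(c(core, optional), names(table))
  if (length(missing_cols) > 0) {
    stop("table lacks optional/core column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  combos <- all_nonempty_subsets(optional)
  run_one <- function(extra) {
    vars <- c(index_col, core, extra)
    spec <- model_spec(family, variables = vars, rf_trees = rf_trees,
                       rf_seed = rf_seed)
    if (is.null(filter_mode)) {
      cv <- repeated_split_cv(table, spec, repeats = repeats,
                              test_fraction = test_fraction, seed = seed,
                              threshold_on = threshold_on, keep_models = FALSE)
      list(mean_tss = cv$summary$mean_tss, se_tss = cv$summary$se_tss,
           mean_threshold = cv$summary$mean_threshold,
           se_threshold = cv$summary$se_threshold,
           best_filter = NA_real_,
           trace = cbind(candidate = NA_real_, cv$per_repeat))
    } else {
      fs <- filtering_threshold_search(table, spec, mode = filter_mode,
                                       precision = precision,
                                       repeats = repeats,
                                       test_fraction = test_fraction,
                                       seed = seed, threshold_on = threshold_on)
      list(mean_tss = fs$best_summary$mean_tss,
           se_tss = fs$best_summary$se_tss,
           mean_threshold = fs$best_summary$mean_threshold,
           se_threshold = fs$best_summary$se_threshold,
           best_filter = fs$best_threshold,
           trace = fs$trace)
    }
  }
  res <- lapply(combos, run_one)
  label <- vapply(combos, paste, character(1), collapse = "+")
  per_combination <- data.frame(
    combination = label,
    mean_tss = vapply(res, `[[`, numeric(1), "mean_tss"),
    se_tss = vapply(res, `[[`, numeric(1), "se_tss"),
    best_filter = vapply(res, `[[`, numeric(1), "best_filter"),
    mean_threshold = vapply(res, `[[`, numeric(1), "mean_threshold"),
    se_threshold = vapply(res, `[[`, numeric(1), "se_threshold"))
  trace <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(combination = label[i], res[[i]]$trace)))
  empty <- run_one(character(0))
  best <- which(per_combination$mean_tss == max(per_combination$mean_tss))[1]
  if (parsimony == "one_se") {
    floor_tss <- per_combination$mean_tss[best] - per_combination$se_tss[best]
    eligible <- which(per_combination$mean_tss >= floor_tss)
    sizes <- lengths(combos)[eligible]
    best <- eligible[order(sizes, -per_combination$mean_tss[eligible])][1]
  }
  structure(list(mode = if (is.null(filter_mode)) "combination" else filter_mode,
                 best_combination = combos[[best]],
                 best_threshold = per_combination$best_filter[best],
                 best_summary = per_combination[best, ],
                 per_combination = per_combination,
                 per_candidate = data.frame(
                   candidate = seq_along(combos),
                   mean_tss = per_combination$mean_tss),
                 trace = trace,
                 empty_combination = empty[c("mean_tss", "se_tss",
                                             "mean_threshold", "best_filter")]),
            class = "search_result")
}
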