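# Bleaching models: binomial-logit GLM and random-forest regression on the
# 0/1 response, probability prediction, variable importance, and the
# overdispersion check.

#' Specify a bleaching model
#'
#' @param family `"glm"` (binomial-logit), `"rf"` (random-forest regression
#'   on the 0/1 response) or `"stub"` (constant-probability placeholder
#'   used to exercise search plumbing at zero fitting cost).
#' @param variables explanatory column names, e.g. `c("dhw", "c", "u")`.
#'   Multivariate reef models conventionally always include the two most
#'   influential covariates, degree cooling week `c` and UV-B `u`.
#' @param index_spec optional [index_spec()] describing the thermal index
#'   the table was built with (carried for provenance).
#' @param rf_trees,rf_mtry random-forest settings: tree count (default 500)
#'   and per-split candidate count (default `max(1, floor(p / 3))`, the
#'   regression default).
#' @param rf_seed seed for forest construction.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("glm", "rf", "stub"), variables,
                       index_spec = NULL, rf_trees = 500, rf_mtry = NULL,
                       rf_seed = 1) {
  family <- match.arg(family)
  if (length(variables) < 1) stop("at least one explanatory variable required",
                                  call. = FALSE)
  structure(list(family = family, variables = variables,
                 index_spec = index_spec, rf_trees = rf_trees,
                 rf_mtry = rf_mtry, rf_seed = rf_seed),
            class = "model_spec")
}

check_columns <- function(table, spec) {
  missing_cols <- setdiff(spec$variables, names(table))
  if (length(missing_cols) > 0) {
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
}

#' Fit a bleaching model
#'
#' Dispatches on the spec's family: [fit_glm()] or [fit_rf()].
#'
#' @param table covariate table with a 0/1 `bleached` column.
#' @param spec a [model_spec()].
#' @return a `bleach_model`.
#' @export
fit_model <- function(table, spec) {
  switch(spec$family,
         glm = fit_glm(table, spec),
         rf = fit_rf(table, spec),
         stub = {
           structure(list(spec = spec, family = "stub",
                          p_hat = mean(table$bleached),
                          n = nrow(table)),
                     class = "bleach_model")
         })
}

#' Binomial-logit bleaching model
#'
#' Maximum-likelihood fit of `bleached ~ variables` with binomial errors
#' and a logit link.  Perfect separation is detected (fitted probabilities
#' numerically 0/1) and flagged as non-convergent rather than silently
#' accepted.
#'
#' @param table covariate table with `bleached` in {0, 1}.
#' @param spec a [model_spec()] with `family = "glm"`.
#' @return a `bleach_model`: coefficients, residual deviance per residual
#'   degree of freedom, convergence flag and the underlying [stats::glm] fit.
#' @export
fit_glm <- function(table, spec) {
  check_columns(table, spec)
  if (nrow(table) < 10 * (length(spec$variables) + 1)) {
    stop("too few rows for the number of parameters (need >= 10 per parameter)",
         call. = FALSE)
  }
  fml <- stats::as.formula(paste("bleached ~",
                                 paste(spec$variables, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial("logit"), data = table))
  eps <- 1e-8
  separated <- any(fit$fitted.values < eps) && any(fit$fitted.values > 1 - eps) &&
    fit$deviance < eps
  structure(list(spec = spec, family = "glm", fit = fit,
                 coefficients = coef(fit),
                 residual_deviance_per_df = fit$deviance / fit$df.residual,
                 converged = fit$converged && !separated,
                 separated = separated, n = nrow(table)),
            class = "bleach_model")
}

#' Random-forest bleaching model
#'
#' Regression forest on the 0/1 response (standard settings: 500 trees,
#' `mtry = floor(p/3)`), so predictions are ensemble means in [0, 1].
#'
#' @inheritParams fit_glm
#' @param spec a [model_spec()] with `family = "rf"`.
#' @return a `bleach_model` wrapping the [randomForest::randomForest] fit.
#' @export
fit_rf <- function(table, spec) {
  check_columns(table, spec)
  y <- table$bleached
  if (length(unique(y)) < 2) {
    stop("degenerate single-class response; cannot fit a forest",
         call. = FALSE)
  }
  x <- table[spec$variables]
  mtry <- spec$rf_mtry %||% max(1L, floor(length(spec$variables) / 3))
  fit <- with_substream(spec$rf_seed, {
    # regression on the 0/1 response is deliberate (ensemble-mean
    # probabilities), so the "are you sure" warning is muted
    suppressWarnings(
      randomForest::randomForest(x = x, y = as.numeric(y),
                                 ntree = spec$rf_trees, mtry = mtry))
  })
  structure(list(spec = spec, family = "rf", fit = fit, n = nrow(table)),
            class = "bleach_model")
}

#' Predict bleaching probabilities
#'
#' GLM: `logistic(linear predictor)`; RF: ensemble-mean vote clamped to
#' [0, 1]; stub: the stored constant.
#'
#' @param model a `bleach_model`.
#' @param table covariate table with the model's variables.
#' @return per-row probability in [0, 1].
#' @export
predict_probability <- function(model, table) {
  stopifnot(inherits(model, "bleach_model"))
  if (model$family == "stub") return(rep(model$p_hat, nrow(table)))
  check_columns(table, model$spec)
  p <- switch(model$family,
              glm = if (is.null(model$fit)) {
                # coefficient-only model (e.g. rebuilt from a reported formula)
                b <- model$coefficients
                X <- cbind(1, as.matrix(table[model$spec$variables]))
                stats::plogis(as.vector(X %*% b))
              } else {
                predict(model$fit, newdata = table, type = "response")
              },
              rf = predict(model$fit, newdata = table[model$spec$variables]))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf("<bleach_model> %s, n = %d\n", x$family, x$n))
  if (x$family == "glm") cat("  ", model_formula(x), "\n")
  invisible(x)
}

#' Build a coefficient-only logit model
#'
#' Reconstructs a usable bleaching model from reported coefficients (for
#' applying a published `logistic(a + b*x + ...)` formula to new data).
#'
#' @param coefficients named numeric vector: intercept first, then one
#'   slope per variable (names are the covariate columns).
#' @return a `bleach_model` usable with [predict_probability()].
#' @export
glm_from_coefficients <- function(coefficients) {
  vars <- names(coefficients)[-1]
  structure(list(spec = model_spec("glm", variables = vars),
                 family = "glm", fit = NULL, coefficients = coefficients,
                 converged = TRUE, n = NA_integer_),
            class = "bleach_model")
}

#' Plain-text formula of a fitted GLM
#'
#' Serializes the fitted binomial-logit model in the conventional
#' `logistic(a + b1*x1 + ...)` reporting style.
#'
#' @param model a `bleach_model` with `family = "glm"`.
#' @param digits significant digits (default 3).
#' @return a single string.
#' @export
model_formula <- function(model, digits = 3) {
  stopifnot(model$family == "glm")
  b <- model$coefficients
  terms <- signif(b[-1], digits)
  rhs <- paste0(ifelse(terms >= 0, " + ", " - "), abs(terms), "*",
                names(terms), collapse = "")
  paste0("logistic(", signif(b[1], digits), rhs, ")")
}

#' Relative variable importance
#'
#' GLM: the sum of Akaike weights of each variable across the all-subsets
#' model set (2^p candidate GLMs over the given variables).  RF:
#' permutation importance (%IncMSE) from a forest grown on all variables.
#' Both profiles are rescaled so the top variable scores 100%.
#'
#' @param table covariate table with `bleached`.
#' @param variables candidate explanatory columns (>= 2).
#' @param family `"glm"` or `"rf"`.
#' @param rf_trees,rf_seed forest settings for the RF route.
#' @return named numeric vector of importances, max = 100.
#' @export
variable_importance <- function(table, variables, family = c("glm", "rf"),
                                rf_trees = 500, rf_seed = 1) {
  family <- match.arg(family)
  if (length(variables) < 2) stop("need >= 2 candidate variables", call. = FALSE)
  check_columns(table, list(variables = variables))
  if (family == "glm") {
    p <- length(variables)
    subsets <- lapply(0:(2^p - 1), function(mask) {
      variables[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
    })
    aics <- vapply(subsets, function(vs) {
      rhs <- if (length(vs) == 0) "1" else paste(vs, collapse = " + ")
      fml <- stats::as.formula(paste("bleached ~", rhs))
      AIC(suppressWarnings(glm(fml, family = binomial("logit"), data = table)))
    }, numeric(1))
    delta <- aics - min(aics)
    w <- exp(-delta / 2)
    w <- w / sum(w)
    imp <- vapply(variables, function(v) {
      sum(w[vapply(subsets, function(vs) v %in% vs, logical(1))])
    }, numeric(1))
  } else {
    fit <- with_substream(rf_seed, {
      suppressWarnings(
        randomForest::randomForest(x = table[variables],
                                   y = as.numeric(table$bleached),
                                   ntree = rf_trees, importance = TRUE))
    })
    imp <- randomForest::importance(fit, type = 1)[, 1]
    imp <- pmax(imp, 0)
    names(imp) <- variables
  }
  100 * imp / max(imp)
}

#' Overdispersion check for a binomial GLM
#'
#' Residual deviance per residual degree of freedom; the model satisfies
#' the binomial assumption when the ratio is below 1.5.
#'
#' @param model a `bleach_model`.
#' @return list: `ratio`, `pass`, `applicable` (FALSE for non-GLM models).
#' @export
overdispersion_check <- function(model) {
  stopifnot(inherits(model, "bleach_model"))
  if (model$family != "glm") {
    return(list(ratio = NA_real_, pass = NA, applicable = FALSE))
  }
  ratio <- model$residual_deviance_per_df
  list(ratio = ratio, pass = ratio < 1.5, applicable = TRUE)
}
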