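sim_table <- function(n, beta, seed = 1) {
  set.seed(seed)
  tab <- data.frame(dhw = runif(n, 0, 6), c = rnorm(n), u = runif(n),
                    k = runif(n, 0.02, 0.15))
  lp <- beta[1] + as.matrix(tab[names(beta)[-1]]) %*% beta[-1]
  tab$bleached <- rbinom(n, 1, plogis(as.vector(lp)))
  tab
}

test_that("the binomial-logit fit recovers generating coefficients", {
  tab <- sim_table(2000, c(intercept = -2.5, dhw = 0.9), seed = 3)
  m <- fit_glm(tab, model_spec("glm", "dhw"))
  expect_lt(abs(m$coefficients[["dhw"]] - 0.9), 0.15)
  expect_true(m$converged)
  expect_lt(m$residual_deviance_per_df, 1.5)
})

test_that("null slopes stay insignificant at the nominal rate", {
  hits <- vapply(1:100, function(s) {
    set.seed(300 + s)
    tab <- data.frame(dhw = runif(500, 0, 6))
    tab$bleached <- rbinom(500, 1, 0.4)
    m <- fit_glm(tab, model_spec("glm", "dhw"))
    z <- coef(summary(m$fit))["dhw", "z value"]
    abs(z) < 1.96
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate fits are reported, not silently accepted", {
  # perfectly separated data
  tab <- data.frame(dhw = c(rep(0, 30), rep(5, 30)),
                    bleached = c(rep(0L, 30), rep(1L, 30)))
  m <- fit_glm(tab, model_spec("glm", "dhw"))
  expect_true(m$separated)
  expect_false(m$converged)

  # single-class response rejected by the forest
  tab1 <- data.frame(dhw = runif(60), bleached = 1L)
  expect_error(fit_rf(tab1, model_spec("rf", "dhw")), "single-class")
  # too few rows per parameter
  tab$c <- rnorm(nrow(tab))
  expect_error(fit_glm(tab[1:15, ], model_spec("glm", c("dhw", "c"))),
               "too few rows")
})

test_that("predicted probabilities follow the logistic formula", {
  m <- glm_from_coefficients(c(intercept = -2.56, dhw = 0.891))
  expect_equal(predict_probability(m, data.frame(dhw = 0)), plogis(-2.56))
  expect_equal(plogis(-2.56), 0.0717, tolerance = 2e-3)
  # the linear predictor crosses zero at 2.56 / 0.891
  expect_equal(predict_probability(m, data.frame(dhw = 2.56 / 0.891)), 0.5)
  expect_error(predict_probability(m, data.frame(x = 1)), "lacks column")

  # monotone in each covariate with the sign of its coefficient
  m2 <- glm_from_coefficients(c(intercept = 0, dhw = 0.8, k = -15))
  p_up <- predict_probability(m2, data.frame(dhw = c(1, 2), k = 0.05))
  expect_lt(p_up[1], p_up[2])
  p_dn <- predict_probability(m2, data.frame(dhw = 1, k = c(0.05, 0.1)))
  expect_gt(p_dn[1], p_dn[2])
})

test_that("the serialized formula reports the fitted coefficients", {
  tab <- sim_table(600, c(intercept = -2, dhw = 0.8), seed = 5)
  m <- fit_glm(tab, model_spec("glm", "dhw"))
  expect_match(model_formula(m), "^logistic\\(-?[0-9.]+ [+-] [0-9.]+\\*dhw\\)$")
})

test_that("the forest is deterministic under its seed and stays in [0, 1]", {
  tab <- sim_table(300, c(intercept = -1, dhw = 0.7), seed = 7)
  spec <- model_spec("rf", "dhw", rf_trees = 100, rf_seed = 99)
  m1 <- fit_rf(tab, spec)
  m2 <- fit_rf(tab, spec)
  p1 <- predict_probability(m1, tab)
  expect_identical(p1, predict_probability(m2, tab))
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("the forest beats the linear model on an interaction response", {
  set.seed(10)
  n <- 600
  tab <- data.frame(dhw = runif(n, -1, 1), c = runif(n, -1, 1),
                    u = runif(n), k = runif(n))
  # XOR-like response: invisible to a linear logit
  tab$bleached <- rbinom(n, 1, plogis(4 * tab$dhw * tab$c))
  vars <- c("dhw", "c")
  rf <- fit_rf(tab, model_spec("rf", vars, rf_trees = 200, rf_seed = 1))
  gl <- fit_glm(tab, model_spec("glm", vars))
  tss_of <- function(m) {
    p <- predict_probability(m, tab)
    optimize_evaluation_threshold(p, tab$bleached)$metrics[["tss"]]
  }
  expect_gte(tss_of(rf), tss_of(gl))
})

test_that("variable importance finds the dominant predictor", {
  tab <- sim_table(800, c(intercept = -1.5, dhw = 1.2), seed = 11)
  for (fam in c("glm", "rf")) {
    imp <- variable_importance(tab, c("dhw", "c", "u", "k"), family = fam,
                               rf_trees = 200)
    expect_equal(max(imp), 100)
    expect_equal(names(which.max(imp)), "dhw")
    # permutation importance pushes pure noise toward zero; Akaike-weight
    # inclusion mass for a null predictor stays near exp(-1), so the GLM
    # bound is looser
    expect_true(all(imp[c("c", "u", "k")] < if (fam == "rf") 50 else 70))
  }
  # duplicated predictors share importance symmetrically (GLM route)
  tab$dup <- tab$dhw
  imp2 <- variable_importance(tab, c("dhw", "dup"), family = "glm")
  expect_lt(abs(imp2[["dhw"]] - imp2[["dup"]]), 1)
  expect_error(variable_importance(tab, "dhw"), ">= 2")
})

test_that("the overdispersion check applies the 1.5 rule", {
  fake <- function(r) structure(list(family = "glm",
                                     residual_deviance_per_df = r),
                                class = "bleach_model")
  expect_true(overdispersion_check(fake(1.49))$pass)
  expect_false(overdispersion_check(fake(1.51))$pass)
  expect_false(overdispersion_check(
    structure(list(family = "rf"), class = "bleach_model"))$applicable)

  # well-specified binomial data passes nearly always
  passes <- vapply(1:20, function(s) {
    tab <- sim_table(400, c(intercept = -1, dhw = 0.6), seed = 600 + s)
    overdispersion_check(fit_glm(tab, model_spec("glm", "dhw")))$pass
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})
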