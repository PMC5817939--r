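test_that("confusion counts and metrics match brute-force counting", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    p <- runif(n)
    y <- rbinom(n, 1, 0.4)
    t <- runif(1)
    ev <- evaluate_at_threshold(p, y, t)
    expect_identical(ev$counts, oracle_confusion(p, y, t))
    m <- ev$metrics
    expect_equal(m[["tss"]], m[["tpr"]] + m[["tnr"]] - 1)
    expect_true(all(m[c("acc", "tpr", "tnr")] >= 0 &
                      m[c("acc", "tpr", "tnr")] <= 1))
  }
})

test_that("the printed skill arithmetic holds: TPR 0.90 + TNR 0.89 - 1 = 0.79", {
  # construct predictions realizing exactly these rates
  y <- c(rep(1, 100), rep(0, 100))
  p <- c(rep(0.9, 90), rep(0.1, 10), rep(0.1, 89), rep(0.9, 11))
  m <- evaluate_at_threshold(p, y, 0.5)$metrics
  expect_equal(m[["tpr"]], 0.90)
  expect_equal(m[["tnr"]], 0.89)
  expect_equal(m[["tss"]], 0.79)
})

test_that("degenerate thresholds and single-class labels are handled explicitly", {
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  m <- evaluate_at_threshold(p, y, 0)$metrics
  expect_equal(m[["tpr"]], 1)
  expect_equal(m[["tnr"]], 0)
  expect_equal(m[["tss"]], 0)
  ev <- evaluate_at_threshold(p, rep(1, 50), 0.5)
  expect_true(is.na(ev$metrics[["tnr"]]))
  expect_match(ev$note, "single-class")
})

test_that("threshold optimization equals the exhaustive oracle", {
  got <- optimize_evaluation_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(got$threshold, 0.6)
  expect_equal(got$metrics[["tss"]], 1)

  set.seed(2)
  for (i in 1:100) {
    n <- sample(10:120, 1)
    p <- round(runif(n), sample(1:3, 1))   # ties on purpose
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    got <- optimize_evaluation_threshold(p, y)
    want <- oracle_best_threshold(p, y)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$metrics[["tss"]], want$tss, tolerance = 1e-12)
  }

  # all probabilities equal: that value, zero skill
  same <- optimize_evaluation_threshold(rep(0.3, 20), rep(c(0, 1), 10))
  expect_equal(same$threshold, 0.3)
  expect_equal(same$metrics[["tss"]], 0)
  expect_error(optimize_evaluation_threshold(runif(5), rep(1, 5)),
               "both classes")
})

test_that("TSS is invariant under joint label/rule complementation", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(80); y <- rbinom(80, 1, 0.5)
    t <- runif(1)
    a <- evaluate_at_threshold(p, y, t)$metrics[["tss"]]
    b <- evaluate_at_threshold(1 - p, 1 - y, 1 - t)$metrics[["tss"]]
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("repeated splits are deterministic and sized like the study", {
  labels <- rbinom(668, 1, 228 / 668)
  splits <- reefbleach:::make_splits(labels, 10, 0.3, seed = 4)
  expect_true(all(lengths(splits) %in% c(200, 201)))
  splits2 <- reefbleach:::make_splits(labels, 10, 0.3, seed = 4)
  expect_identical(splits, splits2)

  tab <- data.frame(dhw = runif(300, 0, 6))
  tab$bleached <- rbinom(300, 1, plogis(-2 + 0.8 * tab$dhw))
  cv1 <- repeated_split_cv(tab, model_spec("glm", "dhw"), seed = 5)
  cv2 <- repeated_split_cv(tab, model_spec("glm", "dhw"), seed = 5)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  expect_equal(cv1$summary$se_tss, sd(cv1$per_repeat$tss) / sqrt(10))
})

test_that("cross-validated TSS approaches the known optimum of the generator", {
  set.seed(6)
  n <- 1500
  x <- runif(n, -1, 1)
  p_true <- plogis(6 * x)
  tab <- data.frame(dhw = x, bleached = rbinom(n, 1, p_true))
  cv <- repeated_split_cv(tab, model_spec("glm", "dhw"), seed = 7)
  # oracle: population TSS of thresholding the true probability, computed
  # on an independent large draw from the same generator
  xo <- runif(2e5, -1, 1)
  yo <- rbinom(2e5, 1, plogis(6 * xo))
  best <- optimize_evaluation_threshold(plogis(6 * xo), yo)
  expect_lt(abs(cv$summary$mean_tss - best$metrics[["tss"]]), 0.1)
})

test_that("the candidate grids have the documented cardinalities", {
  expect_length(threshold_grid("alpha"), 151)
  expect_length(threshold_grid("beta"), 241)
  expect_equal(threshold_grid("alpha")[1:3], c(0, 0.01, 0.02))
  expect_equal(range(threshold_grid("beta")), c(0.1, 2.5))
  expect_length(threshold_grid("alpha", precision = 0.05), 31)
  expect_error(threshold_grid("alpha", precision = 10), "empty")
})

test_that("the filtering-threshold search recovers a planted threshold", {
  sim <- simulate_stress_windows(800, alpha_true = 0.5, seed = 123)
  tab <- data.frame(bleached = sim$bleached, dhw = 0)
  attr(tab, "hs_windows") <- sim$windows
  attr(tab, "index_column") <- "dhw"
  fs <- filtering_threshold_search(tab, model_spec("glm", "dhw"),
                                   mode = "alpha", precision = 0.05, seed = 1)
  expect_lt(abs(fs$best_threshold - 0.5), 0.2)
  # the winner dominates the whole trace by construction
  expect_true(all(fs$per_candidate$mean_tss <=
                    max(fs$per_candidate$mean_tss)))
  expect_equal(nrow(fs$trace), 31 * 10)
})

test_that("a null response yields a flat profile with no sharp optimum", {
  set.seed(31)
  W <- matrix(pmax(rnorm(200 * 84, 0.3, 0.5), 0), 200, 84)
  tab <- data.frame(bleached = rbinom(200, 1, 0.4), dhw = 0)
  attr(tab, "hs_windows") <- W
  attr(tab, "index_column") <- "dhw"
  fs <- filtering_threshold_search(tab, model_spec("glm", "dhw"),
                                   mode = "alpha", precision = 0.25, seed = 2)
  # every candidate's skill stays within Monte-Carlo noise of zero; no
  # candidate stands out as a sharp optimum
  expect_lt(max(abs(fs$per_candidate$mean_tss)), 0.2)
})

test_that("sigma-scaled search needs the cached sigma_m", {
  tab <- data.frame(bleached = rbinom(50, 1, 0.5), dhw = runif(50))
  attr(tab, "hs_windows") <- matrix(runif(50 * 84), 50, 84)
  attr(tab, "index_column") <- "dhw"
  expect_error(filtering_threshold_search(tab, model_spec("stub", "dhw"),
                                          mode = "beta"), "sigma_m")
})

test_that("the combination search enumerates 15 subsets and finds planted support", {
  set.seed(41)
  n <- 500
  tab <- data.frame(dhw = pmax(rnorm(n, 1.5, 1.5), 0), c = rnorm(n),
                    u = rnorm(n), k = rnorm(n), v = rnorm(n), d = rnorm(n),
                    s = rnorm(n))
  p <- plogis(-1.2 + 0.8 * tab$dhw - 0.8 * tab$c + 0.9 * tab$u - 2 * tab$k)
  tab$bleached <- rbinom(n, 1, p)
  attr(tab, "index_column") <- "dhw"
  vs <- variable_combination_search(tab, family = "glm", repeats = 5, seed = 3)
  expect_equal(nrow(vs$per_combination), 15)
  expect_true("k" %in% vs$best_combination)
  # the winner's mean TSS dominates every other combination
  expect_true(all(vs$per_combination$mean_tss <= max(vs$per_combination$mean_tss)))
  # the transparency run of the empty subset is reported separately
  expect_true(is.finite(vs$empty_combination$mean_tss))
  # one-SE parsimony never selects a larger set than the outright max
  vs_se <- variable_combination_search(tab, family = "glm", repeats = 5,
                                       seed = 3, parsimony = "one_se")
  expect_lte(length(vs_se$best_combination), length(vs$best_combination))
  expect_true("k" %in% vs_se$best_combination)
  expect_error(variable_combination_search(tab[, -4], family = "glm"),
               "lacks")
})

test_that("joint search traces have the repeats x combinations x grid shape", {
  set.seed(51)
  n <- 24
  tab <- data.frame(bleached = rep(0:1, n / 2), c = rnorm(n), u = rnorm(n),
                    v = rnorm(n), k = rnorm(n), d = rnorm(n), s = rnorm(n),
                    dhw = 0)
  attr(tab, "hs_windows") <- matrix(runif(n * 84, 0, 2), n, 84)
  attr(tab, "index_column") <- "dhw"
  vs <- variable_combination_search(tab, family = "stub",
                                    filter_mode = "alpha", precision = 0.5,
                                    repeats = 2, seed = 4)
  expect_equal(nrow(vs$trace), 2 * 15 * length(threshold_grid("alpha", 0.5)))
})
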