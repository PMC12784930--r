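test_that("train_regressor honours the contract across families", {
  set.seed(10)
  X <- data.frame(x1 = runif(40), x2 = runif(40))
  y_const <- rep(5, 40)
  for (fam in c("et", "rf", "gbm")) {
    m <- train_regressor(preset_config(fam, seed = 1), X, y_const)
    expect_equal(unname(predict(m, X)), y_const, tolerance = 1e-12, info = fam)
  }
  y <- X$x1 * 10 + X$x2
  for (fam in c("et", "rf", "gbm", "ann")) {
    cfgm <- preset_config(fam, seed = 3)
    m1 <- train_regressor(cfgm, X, y)
    m2 <- train_regressor(cfgm, X, y)
    expect_identical(predict(m1, X), predict(m2, X), info = fam)
  }
  expect_error(train_regressor(preset_config("et"), X[0, ], numeric(0)),
               "at least 2")
  Xna <- X; Xna$x1[3] <- NA
  expect_error(train_regressor(preset_config("et"), Xna, y), "missing values")
})

test_that("extra-trees preset recovers a noiseless growth surface", {
  fx <- gompertz_fixture(200)
  st <- fit_transform_state(fx$X)
  Z <- apply_transform(fx$X, st)
  tr <- 1:160
  m <- train_regressor(preset_config("et", seed = 1), Z[tr, ], fx$y[tr])
  metrics <- evaluate(predict(m, Z[-tr, ]), fx$y[-tr])
  expect_gt(metrics$R2, 0.99)
})

test_that("evaluate computes MSE, MAE, RMSE, R2", {
  obs <- c(785, 1009, 1425, 1825, 2134, 2350, 2490)
  perfect <- evaluate(obs, obs)
  expect_equal(perfect$MSE, 0); expect_equal(perfect$MAE, 0)
  expect_equal(perfect$RMSE, 0); expect_equal(perfect$R2, 1)

  at_mean <- evaluate(rep(mean(obs), 7), obs)
  expect_equal(at_mean$R2, 0)

  shifted <- evaluate(obs + 100, obs)
  expect_equal(shifted$MAE, 100)
  expect_equal(shifted$RMSE, 100)
  expect_equal(shifted$R2, 1 - 7 * 100^2 / sum((obs - mean(obs))^2))

  set.seed(2)
  p <- rnorm(30); o <- rnorm(30)
  m <- evaluate(p, o)
  expect_equal(m$RMSE^2, m$MSE, tolerance = 1e-12)
  expect_lte(m$MAE, m$RMSE)

  expect_warning(zv <- evaluate(c(1, 2), c(3, 3)), "zero variance")
  expect_true(is.na(zv$R2))
  expect_error(evaluate(1:3, 1:4), "equal length")
})

test_that("impurity_reduction matches direct variance computation", {
  expect_equal(impurity_reduction(c(0, 0, 10, 10), list(c(0, 0), c(10, 10))), 25)
  expect_equal(impurity_reduction(c(1, 2, 3), list(c(1, 2, 3))), 0)  # no-op
  expect_equal(impurity_reduction(rep(4, 6), list(rep(4, 2), rep(4, 4))), 0)
  expect_error(impurity_reduction(c(1, 2, 3), list(c(1, 2), c(5))),
               "partition")
  # variance impurity reduction is non-negative for any genuine partition
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(12)
    cut <- sample(2:10, 1)
    expect_gte(impurity_reduction(y, list(y[1:cut], y[(cut + 1):12])), -1e-12)
  }
})

test_that("mc_shapley ignores dummy features and respects symmetry", {
  set.seed(4)
  bg <- data.frame(x1 = rnorm(25), x2 = rnorm(25), x3 = rnorm(25))
  xe <- data.frame(x1 = 1.5, x2 = -0.5, x3 = 2)
  att <- mc_shapley(function(d) d$x1, bg, xe, n_permutations = 50, seed = 1)
  expect_equal(unname(att$values[1, c("x2", "x3")]), c(0, 0))
  expect_equal(unname(att$values[1, "x1"]), 1.5 - mean(bg$x1),
               tolerance = 1e-12)

  # symmetry: f = x1 + x2 with an exchangeable background for features 1, 2
  bg_sym <- data.frame(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1), x3 = c(2, 3, 4))
  att2 <- mc_shapley(function(d) d$x1 + d$x2, bg_sym,
                     data.frame(x1 = 2, x2 = 2, x3 = 0),
                     n_permutations = 200, seed = 2)
  expect_equal(unname(att2$values[1, "x1"]), unname(att2$values[1, "x2"]),
               tolerance = 1e-9)
  expect_error(mc_shapley(function(d) d$x1, bg[0, ], xe), "empty")
})

test_that("mc_shapley satisfies local accuracy per sample", {
  set.seed(5)
  bg <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  xe <- data.frame(a = rnorm(4), b = rnorm(4), c = rnorm(4))
  f <- function(d) d$a * d$b + exp(d$c / 3)
  att <- mc_shapley(f, bg, xe, n_permutations = 30, seed = 6)
  # per-permutation telescoping makes this exact, not just asymptotic
  expect_equal(unname(rowSums(att$values)), f(xe) - att$baseline,
               tolerance = 1e-10)
})

test_that("mc_shapley matches the exhaustive oracle within 1%", {
  set.seed(7)
  bg <- data.frame(x1 = rnorm(12), x2 = runif(12), x3 = rnorm(12, 2))
  x_row <- data.frame(x1 = 1.2, x2 = 0.8, x3 = 3.1)
  f <- function(d) d$x1 * d$x2 + 2 * d$x3 + 0.5 * d$x1^2
  exact <- exact_shapley(f, bg, x_row)
  att <- mc_shapley(f, bg, x_row, n_permutations = 2000, seed = 8)
  scale <- max(abs(exact))
  expect_true(all(abs(att$values[1, ] - exact) <= 0.01 * scale))
  # attribution summary ranks features by descending mean |SHAP|
  expect_true(all(diff(att$summary$mean_abs_shap) <= 0))
})

test_that("pipeline metrics are stable under input rescaling end-to-end", {
  fx <- gompertz_fixture(120, seed = 9)
  wm <- cbind(fx$X, y_g_per_bird = fx$y,
              batch_id = rep(c("B01", "B02"), each = 60),
              date = format(as.Date("2024-11-05") + rep(0:59, 2)))
  sp <- temporal_split(wm)
  fit_eval <- function(d) {
    m <- fit_weight_model(d[sp$train, ], preset_config("et", seed = 1))
    evaluate(predict(m, d[sp$test, ]), d$y_g_per_bird[sp$test])
  }
  base <- fit_eval(wm)
  rescaled <- wm
  rescaled$temp_mean_c <- rescaled$temp_mean_c * 1000  # strictly monotone map
  again <- fit_eval(rescaled)
  expect_equal(base$RMSE, again$RMSE, tolerance = 1e-6)
})

test_that("models and pipelines round-trip through JSON artifacts", {
  fx <- gompertz_fixture(60, seed = 11)
  st <- fit_transform_state(fx$X)
  Z <- apply_transform(fx$X, st)
  path <- tempfile(fileext = ".json")
  for (fam in c("et", "gbm", "ann")) {
    cfgm <- preset_config(fam, seed = 2)
    if (fam != "ann") cfgm$n_trees <- 25L
    m <- train_regressor(cfgm, Z, fx$y)
    save_model(m, path)
    m2 <- load_model(path)
    expect_equal(predict(m2, Z), predict(m, Z), tolerance = 1e-12, info = fam)
  }
  wm <- cbind(fx$X, y_g_per_bird = fx$y)
  pl <- fit_weight_model(wm, preset_config("et", seed = 3))
  save_model(pl, path)
  pl2 <- load_model(path)
  expect_equal(predict(pl2, wm), predict(pl, wm), tolerance = 1e-12)
  unlink(path)
})

test_that("env_only_attribution uses exactly the 5 environmental features", {
  cfg <- synthetic_config(n_batches = 1, n_days = 25,
                          breeds = c("Guzao", "Huangjin"), seed = 12)
  d <- gen_dataset(cfg)
  wm <- build_weight_matrix(d$records, d$env)
  att <- env_only_attribution(wm, n_permutations = 10, seed = 1,
                              n_explain = 5)
  expect_setequal(names(att), c("Guzao", "Huangjin", "breed_balanced"))
  expect_setequal(att$breed_balanced$feature,
                  c("temp_mean_c", "rh_mean_pct", "co_max_ppm", "h2s_max_ppm",
                    "nh3_max_ppm"))
  expect_true(all(att$breed_balanced$mean_abs_shap >= 0))
})
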