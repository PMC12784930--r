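loose_cfg <- function(...) schedule_config(daily_min = 0, daily_max = 1e7,
                                           max_rel_change = 1, gain_clip = NULL,
                                           ...)

test_that("allocate_profile normalizes and conserves the total", {
  expect_equal(allocate_profile(400, c(1, 1, 1, 1)), rep(100, 4))
  expect_equal(allocate_profile(60, c(1, 2, 3)), c(10, 20, 30))
  f1 <- allocate_profile(123.4, c(0.2, 0.5, 0.9))
  expect_equal(sum(f1), 123.4)                    # exact by construction
  expect_equal(allocate_profile(2 * 123.4, c(0.2, 0.5, 0.9)), 2 * f1,
               tolerance = 1e-12)                 # linearity in the total
  expect_error(allocate_profile(10, c(0, 0)), "all zero")
  expect_error(allocate_profile(10, c(-1, 2)), "non-negative")
})

test_that("allocate_arithmetic scales the progression to the total", {
  expect_equal(allocate_arithmetic(60, 3, a = 1, d = 1), c(10, 20, 30))
  expect_equal(allocate_arithmetic(90, 3, a = 5, d = 0), rep(30, 3))
  set.seed(1)
  for (i in 1:15) {
    n <- sample(2:60, 1); tot <- runif(1, 100, 9000)
    r <- allocate_arithmetic(tot, n, a = runif(1, 0.5, 3))
    expect_lt(abs(sum(r) - tot) / tot, 1e-9)
    expect_true(all(diff(r) >= 0))
  }
  expect_error(allocate_arithmetic(60, 4, a = 1, d = -1), "day 2")
})

test_that("enforce_constraints projects into bounds and band, conserving mass", {
  cfg <- schedule_config(daily_min = 50, daily_max = 200,
                         max_rel_change = 0.10)
  ok <- c(100, 105, 110)
  expect_equal(enforce_constraints(ok, cfg), ok)    # feasible plans untouched

  bumpy <- c(100, 150, 100)
  out <- enforce_constraints(bumpy, cfg)
  expect_true(plan_feasible(out, cfg))
  expect_equal(sum(out), sum(bumpy), tolerance = 1e-6 * sum(bumpy))

  # inactive constraints: wide band and loose bounds leave the plan alone
  cfg_loose <- schedule_config(daily_min = 0, daily_max = 1e6,
                               max_rel_change = 1)
  expect_equal(enforce_constraints(bumpy, cfg_loose), bumpy, tolerance = 1e-12)

  expect_error(enforce_constraints(c(10, 10), cfg), "infeasible")
})

test_that("enforce_constraints is idempotent and robust over random plans", {
  cfg <- schedule_config(daily_min = 20, daily_max = 250,
                         max_rel_change = 0.10)
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    plan <- runif(n, 30, 200)
    out1 <- enforce_constraints(plan, cfg)
    expect_true(plan_feasible(out1, cfg))
    expect_equal(sum(out1), sum(plan), tolerance = 1e-6 * sum(plan))
    out2 <- enforce_constraints(out1, cfg)
    expect_equal(out2, out1, tolerance = 1e-9)     # idempotence
  }
})

test_that("simulate_trajectory propagates clipped gains", {
  rations <- c(100, 120, 140)
  env <- const_env(3)
  mw <- stub_weight_model(anchor = 500, rate = 0.3)

  # clip disabled: raw model outputs, terminal = w_start + rate * total
  raw <- simulate_trajectory(rations, env, 1:3, mw, loose_cfg(), w_start = 500)
  expect_equal(raw[3], 500 + 0.3 * sum(rations), tolerance = 1e-12)

  # non-negative gain clip forces a monotone trajectory out of a dipping model
  dip <- function(d) c(600, 550, 700)
  cfg_clip <- schedule_config(gain_clip = c(0, Inf), daily_min = 0,
                              daily_max = 1e6, max_rel_change = 1)
  y <- simulate_trajectory(rations, env, 1:3, dip, cfg_clip, w_start = 500)
  expect_true(all(diff(y) >= 0))

  # upper clip caps daily gain at the band
  cfg_cap <- schedule_config(gain_clip = c(0, 30))
  y2 <- simulate_trajectory(rations, env, 1:3, mw, cfg_cap, w_start = 500)
  expect_true(all(diff(c(500, y2)) <= 30 + 1e-12))

  expect_error(simulate_trajectory(rations, const_env(2), 1:3, mw,
                                   loose_cfg(), 500), "one row per")
})

test_that("update_interval_total is the proportional correction", {
  expect_equal(update_interval_total(4000, 2500, 2500), 4000)   # fixed point
  expect_equal(update_interval_total(4000, 1250, 2500), 8000)   # doubling
  expect_error(update_interval_total(4000, 0, 2500), "positive")
  # under a linear through-origin response one update lands on target:
  # w_end = c * F  =>  F' = F * T / (cF) = T / c  =>  w_end' = T
  c_resp <- 0.37; F0 <- 3000; target <- 2000
  F1 <- update_interval_total(F0, c_resp * F0, target)
  expect_equal(c_resp * F1, target, tolerance = 1e-12)
})

test_that("run_schedule converges with stub models in <= 2 iterations", {
  # linear through-origin terminal response: second simulation hits exactly
  mw_lin <- function(d) 0.4 * cumsum(d$feed_per_bird_g)
  spec <- interval_spec(785, 2500, 20)
  res <- run_schedule(spec, function(d) 3000, mw_lin, const_env(20),
                      loose_cfg(), start_age = 46)
  expect_true(res$converged)
  expect_lte(res$iterations, 2L)
  expect_lte(abs(res$terminal_error), 10)
  expect_equal(length(res$terminal_weights), res$iterations)

  # tolerance boundary: start within epsilon/2 of target -> one evaluation
  mw_id <- function(d) rep(2495, nrow(d))
  spec2 <- interval_spec(2495, 2500, 5)
  res2 <- run_schedule(spec2, function(d) 100, mw_id, const_env(5),
                       loose_cfg(), start_age = 0)
  expect_true(res2$converged)
  expect_equal(res2$iterations, 1L)
})

test_that("closed loop matches an independent fixed-point oracle on concave responses", {
  # terminal response w_end = w0 + c * sqrt(F); oracle iterates Eq-style
  # proportional updates outside the scheduler code path
  w0 <- 785; target <- 2500; n <- 54
  for (c_resp in c(6, 15, 30, 60)) {
    mw <- local({
      cc <- c_resp
      function(d) {
        cum <- cumsum(d$feed_per_bird_g)
        w0 + cc * sqrt(cum)
      }
    })
    F0 <- 4000
    res <- run_schedule(interval_spec(w0, target, n),
                        function(d) F0, mw, const_env(n),
                        loose_cfg(), start_age = 46)
    # oracle: plain fixed-point iteration on the closed-form response
    Fj <- F0; last <- NA
    for (j in 1:20) {
      wend <- w0 + c_resp * sqrt(Fj)
      last <- wend
      if (abs(wend - target) <= 10) break
      Fj <- Fj * target / wend
    }
    expect_true(res$converged, info = paste("c =", c_resp))
    expect_lte(res$iterations, 20L)
    expect_lte(abs(res$terminal_error), 10)
    expect_equal(res$total, Fj, tolerance = 1e-6, info = paste("c =", c_resp))
    expect_equal(res$iterations, j, info = paste("c =", c_resp))
  }
})

test_that("mass conservation and shape preservation hold through the loop", {
  mw <- stub_weight_model(600, 0.25)
  spec <- interval_spec(600, 1800, 30)
  cfg <- schedule_config(daily_min = 0, daily_max = 1e6, max_rel_change = 1,
                         gain_clip = NULL)
  res <- run_schedule(spec, function(d) 2500, mw, const_env(30), cfg,
                      start_age = 10)
  r <- res$plan$per_bird_ration_g
  expect_equal(sum(r), res$total, tolerance = 1e-6 * res$total)
  # proportional reallocation preserves the allocation shape
  shape0 <- allocate_arithmetic(1, 30)
  expect_equal(r / sum(r), shape0 / sum(shape0), tolerance = 1e-9)
  # FCR recomputed independently from the raw plan
  expect_equal(res$fcr, sum(r) / (1800 - 600), tolerance = 1e-12)
})

test_that("forecast_interval_feed floors non-positive predictions", {
  spec <- interval_spec(785, 2500, 54)
  expect_equal(forecast_interval_feed(spec, function(d) 5000), 5000)
  cfg <- schedule_config(daily_min = 10)
  expect_warning(out <- forecast_interval_feed(spec, function(d) -3, cfg),
                 "flooring")
  expect_equal(out, 10 * 54)
  # the validation case is a legal input to a fitted model
  fx <- gompertz_fixture(80, seed = 13)
  iv <- data.frame(w_start_g = runif(80, 400, 1500),
                   w_target_g = runif(80, 1600, 2600),
                   d_remain = sample(10:60, 80, TRUE))
  iv$total_feed_g <- 3.3 * (iv$w_target_g - iv$w_start_g)
  mf <- fit_feed_model(iv, preset_config("et", seed = 1))
  pred <- forecast_interval_feed(spec, mf)
  expect_true(is.finite(pred) && pred > 0)
})

test_that("a feed model trained on linear-rule data recovers interior totals", {
  # truth: total = c * (w_target - w_start); ET should predict within 5%
  set.seed(14)
  n <- 400
  iv <- data.frame(w_start_g = runif(n, 400, 1400),
                   w_target_g = runif(n, 1500, 2600),
                   d_remain = sample(10:60, n, TRUE))
  iv$total_feed_g <- 3.2 * (iv$w_target_g - iv$w_start_g)
  mf <- fit_feed_model(iv, preset_config("et", seed = 2))
  probe <- data.frame(w_start_g = c(700, 900, 1100),
                      w_target_g = c(1800, 2100, 2400),
                      d_remain = c(40, 45, 50))
  truth <- 3.2 * (probe$w_target_g - probe$w_start_g)
  expect_true(all(abs(predict(mf, probe) - truth) / truth < 0.05))
})

test_that("compute_fcr reproduces the regimen table arithmetic", {
  expect_equal(round(compute_fcr(rep(5578.08 / 54, 54), 785, 2490), 2), 3.27)
  expect_equal(round(compute_fcr(c(7506.75), 972.5, 3167.25), 2), 3.42)
  expect_equal(compute_fcr(c(500, 500), 1000, 2000), 1.0)
  expect_error(compute_fcr(c(100), 900, 900), "undefined")
})

test_that("env_climatology averages the trailing window", {
  h <- const_env(10)
  h$temp_mean_c <- 20:29
  fc <- env_climatology(h, n_days = 4, window = 7)
  expect_equal(nrow(fc), 4)
  expect_equal(fc$temp_mean_c, rep(mean(23:29), 4))
  expect_error(env_climatology(h[0, ], 3), "no complete")
})
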