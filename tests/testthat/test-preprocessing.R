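test_that("compute_age counts whole calendar days from batch start", {
  expect_identical(compute_age("2024-11-05", "2024-11-05"), 0L)
  expect_identical(compute_age("2024-12-21", "2024-11-05"), 46L)
  expect_identical(compute_age("2025-01-20", "2024-11-05"), 76L)
  expect_error(compute_age("2024-11-04", "2024-11-05"), "negative age")
  expect_error(compute_age("notadate", "2024-11-05"), "parseable")
})

test_that("per_bird_feed divides cage feed by bird count", {
  expect_equal(per_bird_feed(400, 4), 100)
  expect_equal(per_bird_feed(0, 4), 0)
  # interval-total consistency: a cage total re-divides to the per-bird total
  expect_equal(per_bird_feed(5578.08 * 4, 4), 5578.08)
  expect_error(per_bird_feed(400, 0), "zero birds")
})

make_samples <- function(hours, base = "2024-11-05", temp = 25, rh = 60,
                         co = 0.1, h2s = 0.2, nh3 = 0.3) {
  data.frame(
    timestamp = format(as.POSIXct(base, tz = "UTC") + hours * 3600,
                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    temp_c = temp, rh_pct = rh, co_ppm = co, h2s_ppm = h2s, nh3_ppm = nh3)
}

test_that("summarize_env aggregates the 24-h pre-weighing window", {
  wt <- as.POSIXct("2024-11-05 08:00:00", tz = "UTC")
  s1 <- make_samples(7)
  expect_equal(summarize_env(s1, wt)[1, 1:5],
               data.frame(temp_mean_c = 25, rh_mean_pct = 60, co_max_ppm = 0.1,
                          h2s_max_ppm = 0.2, nh3_max_ppm = 0.3)[1, ])

  s2 <- make_samples(c(1, 2, 3), temp = c(20, 30, 25),
                     nh3 = c(0.5, 4.0, 1.0))
  out <- summarize_env(s2, wt)
  expect_equal(out$temp_mean_c, 25)
  expect_equal(out$nh3_max_ppm, 4.0)
})

test_that("summarize_env window is half-open at exactly 24 h", {
  wt <- as.POSIXct("2024-11-05 08:00:00", tz = "UTC")
  # 24 h + 1 s before weighing: excluded; exactly at weighing time: included
  s <- rbind(make_samples(8 - 24 - 1 / 3600, temp = 99),
             make_samples(8, temp = 21))
  out <- summarize_env(s, wt)
  expect_equal(out$n_samples, 1L)
  expect_equal(out$temp_mean_c, 21)
  expect_warning(out2 <- summarize_env(make_samples(30), wt), "no environmental")
  expect_true(is.na(out2$temp_mean_c))
  expect_identical(out2$n_samples, 0L)
})

test_that("transform state scales, imputes and inverts per the formula", {
  train <- data.frame(a = c(1, 2, 3), b = c(0, 5, 10), c = c(1, NA, 3),
                      lab = c("x", "x", "y"))
  st <- fit_transform_state(train, numeric_features = c("a", "b", "c"),
                            categorical_features = "lab")
  expect_equal(st$numeric$a[c("min", "max", "mean")],
               list(min = 1, max = 3, mean = 2))
  expect_equal(st$numeric$c$mean, 2)  # mean of observed values only
  expect_equal(st$categorical$lab, "x")

  z <- apply_transform(train, st)
  expect_equal(z$a[1], 0)                       # training minimum -> 0
  expect_equal(z$b[3], 10 / (10 + 1e-8))        # maximum -> just under 1
  expect_equal(z$c[2], (2 - 1) / (3 - 1 + 1e-8))  # imputed with the mean

  # constant feature: epsilon prevents division by zero, value maps to 0
  st2 <- fit_transform_state(data.frame(k = c(5, 5, 5)))
  expect_equal(apply_transform(data.frame(k = 5), st2)$k, 0)

  # round trip within 1e-9 relative for non-missing values
  back <- invert_transform(z, st)
  expect_equal(back$a, train$a, tolerance = 1e-9)
  expect_equal(back$b, train$b, tolerance = 1e-9)

  expect_error(fit_transform_state(data.frame(v = c(NA_real_, NA_real_))),
               "no observed training values")
})

test_that("scaling is order-preserving and supports z-scoring", {
  set.seed(1)
  train <- data.frame(x = rnorm(50))
  st <- fit_transform_state(train)
  x <- sort(rnorm(20))
  z <- apply_transform(data.frame(x = x), st)$x
  expect_true(all(diff(z) >= 0))
  stz <- fit_transform_state(train, method = "zscore")
  zz <- apply_transform(train, stz)$x
  expect_equal(mean(zz), 0, tolerance = 1e-6)
  expect_equal(sd(zz), 1, tolerance = 1e-6)
})

test_that("temporal_split takes the last ceil(n/10) records per batch", {
  r231 <- batch_records(c(77, 77, 77))
  sp <- temporal_split(r231)
  expect_equal(length(sp$train), 207)
  expect_equal(length(sp$test), 24)

  sp10 <- temporal_split(batch_records(10))
  expect_equal(lengths(sp10[c("train", "test")]), c(train = 9L, test = 1L))
  sp5 <- temporal_split(batch_records(5))
  expect_equal(lengths(sp5[c("train", "test")]), c(train = 4L, test = 1L))

  # within every batch the split respects time
  r <- batch_records(c(20, 13))
  sp2 <- temporal_split(r)
  for (b in unique(r$batch_id)) {
    tr <- sp2$train[r$batch_id[sp2$train] == b]
    te <- sp2$test[r$batch_id[sp2$test] == b]
    expect_true(max(r$date[tr]) < min(r$date[te]))
  }
  expect_length(intersect(sp2$train, sp2$test), 0)

  expect_warning(sp1 <- temporal_split(batch_records(1)), "fewer than 2")
  expect_equal(length(sp1$test), 0)
})

test_that("blocked_cv_folds yields contiguous temporal blocks", {
  r <- batch_records(10)
  f <- blocked_cv_folds(r, k = 5, repeats = 1)
  expect_equal(as.vector(table(f[, 1])), rep(2L, 5))
  expect_true(all(diff(f[order(r$date), 1]) >= 0))  # contiguous blocks

  # partition property over batches and repeats, blocks contiguous in time
  r2 <- batch_records(c(23, 31))
  f2 <- blocked_cv_folds(r2, k = 5, repeats = 3, seed = 4)
  for (rep_i in 1:3) {
    expect_false(anyNA(f2[, rep_i]))
    for (b in unique(r2$batch_id)) {
      idx <- which(r2$batch_id == b)
      fb <- f2[idx[order(r2$date[idx])], rep_i]
      expect_setequal(unique(fb), 1:5)
      expect_true(all(diff(fb) %in% c(0L, 1L)))  # contiguity scan
    }
  }
  # repeats shift boundaries deterministically
  f2b <- blocked_cv_folds(r2, k = 5, repeats = 3, seed = 4)
  expect_identical(f2, f2b)
  expect_false(identical(f2[, 1], f2[, 2]))
  expect_error(blocked_cv_folds(batch_records(3), k = 5), "exceeds")
})

test_that("build_interval_examples sums feed over the half-open interval", {
  wm <- data.frame(cage_id = "c", age_days = 0:1,
                   feed_per_bird_g = c(0, 100), y_g_per_bird = c(500, 600))
  iv <- build_interval_examples(wm, min_len = 1)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$w_start_g, 500)
  expect_equal(iv$w_target_g, 600)
  expect_equal(iv$d_remain, 1)
  expect_equal(iv$total_feed_g, 100)

  # non-monotone pair skipped and counted; zero-length intervals excluded
  wm2 <- data.frame(cage_id = "c", age_days = 0:2,
                    feed_per_bird_g = c(0, 50, 60),
                    y_g_per_bird = c(500, 480, 700))
  iv2 <- build_interval_examples(wm2, min_len = 1)
  expect_equal(attr(iv2, "skipped"), 1L)
  expect_true(all(iv2$d_remain >= 1))
  expect_true(all(iv2$w_target_g > iv2$w_start_g))
})

test_that("the 54-day validation interval rebuilds its printed feed total", {
  # validation intake series: 57->145 g/day profile scaled to the recorded
  # 5578.08 g total over the 54 fed days, weights rising 785 -> 2490 g
  fed <- gen_intake_profile(54, 57, 145)
  fed <- fed * (5578.08 / sum(fed))
  wm <- data.frame(cage_id = "guzao",
                   age_days = 46:100,
                   feed_per_bird_g = c(0, fed),
                   y_g_per_bird = seq(785, 2490, length.out = 55))
  iv <- build_interval_examples(wm, min_len = 54)
  full <- iv[iv$d_remain == 54, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$w_start_g, 785)
  expect_equal(full$w_target_g, 2490)
  expect_equal(full$total_feed_g, 5578.08, tolerance = 1e-9)
})

test_that("build_weight_matrix joins records with env summaries leakage-free", {
  cfg <- synthetic_config(n_batches = 2, n_days = 12, breeds = "Guzao",
                          seed = 21)
  d <- gen_dataset(cfg)
  wm <- build_weight_matrix(d$records, d$env)
  expect_equal(nrow(wm), 24)
  expect_identical(names(wm)[5:11], weight_feature_names())
  expect_true(all(is.finite(wm$y_g_per_bird)))
  expect_equal(wm$age_days[1:3], 0:2)

  # leakage invariant: state fitted on training rows is identical whether or
  # not test rows exist in the surrounding table
  sp <- temporal_split(wm)
  st_full <- fit_transform_state(wm[sp$train, ],
                                 numeric_features = weight_feature_names())
  st_isolated <- fit_transform_state(wm[sort(sp$train), ],
                                     numeric_features = weight_feature_names())
  expect_identical(st_full, st_isolated)
  st_with_test <- fit_transform_state(wm,
                                      numeric_features = weight_feature_names())
  expect_false(identical(st_full, st_with_test))
})
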