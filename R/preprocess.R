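# Leakage-safe preprocessing: age computation, per-bird feed, 24-h
# environmental aggregation, train-only imputation + scaling, batch-wise
# temporal split, blocked CV folds, and construction of the training pairs for
# the daily-weight and interval-feed models.

#' Canonical feature names
#'
#' The daily live-weight model uses exactly these 7 features in this order:
#' age (days), mean temperature, mean relative humidity, per-bird feed
#' allowance (g/day), and the daily maxima of CO, H2S and NH3 (ppm), all
#' aggregated over the 24 h preceding the morning weighing. The interval
#' total-feed model uses start weight, target weight and remaining days.
#'
#' @return Character vector of column names.
#' @export
weight_feature_names <- function() {
  c("age_days", "temp_mean_c", "rh_mean_pct", "feed_per_bird_g",
    "co_max_ppm", "h2s_max_ppm", "nh3_max_ppm")
}

#' @rdname weight_feature_names
#' @export
feed_feature_names <- function() c("w_start_g", "w_target_g", "d_remain")

#' Rearing age in whole days
#'
#' Day-level difference between the record date and the batch start date
#' (day 0 = batch start).
#'
#' @param t ISO-8601 date(s) of the record.
#' @param t_batch0 ISO-8601 batch start date (recycled).
#' @return Integer vector of ages in days.
#' @export
#' @examples
#' compute_age("2024-12-21", "2024-11-05")  # 46
compute_age <- function(t, t_batch0) {
  d <- parse_iso_date(t, "t")
  d0 <- parse_iso_date(t_batch0, "t_batch0")
  age <- as.integer(d - d0)
  if (any(age < 0))
    stop("record date precedes batch start date (negative age)", call. = FALSE)
  age
}

#' Average daily feed allowance per bird
#'
#' @param feed_g Total cage feed on the day, grams, >= 0.
#' @param n_birds Birds in the cage, >= 1.
#' @return Grams per bird per day.
#' @export
per_bird_feed <- function(feed_g, n_birds) {
  if (any(!is.finite(n_birds)) || any(n_birds < 1))
    stop("`n_birds` must be >= 1: cannot divide feed among zero birds",
         call. = FALSE)
  if (any(feed_g < 0, na.rm = TRUE))
    stop("`feed_g` must be non-negative", call. = FALSE)
  feed_g / n_birds
}

parse_iso_time <- function(x, name = "timestamp") {
  t <- as.POSIXct(as.character(x), format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- is.na(t)
  if (any(bad)) {  # fall back to space-separated datetimes
    t2 <- as.POSIXct(as.character(x[bad]), tz = "UTC")
    t[bad] <- t2
  }
  if (anyNA(t))
    stop(sprintf("`%s` contains unparseable timestamps", name), call. = FALSE)
  t
}

#' Aggregate sensor samples over the 24-h pre-weighing window
#'
#' Means of temperature and relative humidity and maxima of CO, H2S and NH3
#' over the half-open window `(weighing_time - 24 h, weighing_time]`. Samples
#' outside the window are ignored. An empty window yields a row of `NA`
#' (missing-summary marker, imputed downstream) with a warning.
#'
#' @param samples Data frame with `timestamp`, `temp_c`, `rh_pct`, `co_ppm`,
#'   `h2s_ppm`, `nh3_ppm`.
#' @param weighing_time POSIXct (or ISO-8601 string) end of the window.
#' @return One-row data frame `temp_mean_c`, `rh_mean_pct`, `co_max_ppm`,
#'   `h2s_max_ppm`, `nh3_max_ppm`, `n_samples`.
#' @export
summarize_env <- function(samples, weighing_time) {
  wt <- if (inherits(weighing_time, "POSIXct")) weighing_time
        else parse_iso_time(weighing_time, "weighing_time")
  ts <- parse_iso_time(samples$timestamp)
  keep <- ts > (wt - 86400) & ts <= wt
  if (!any(keep)) {
    warning("no environmental samples in the 24 h window ending ",
            format(wt, "%Y-%m-%dT%H:%M:%SZ"), "; emitting missing summary",
            call. = FALSE)
    return(data.frame(temp_mean_c = NA_real_, rh_mean_pct = NA_real_,
                      co_max_ppm = NA_real_, h2s_max_ppm = NA_real_,
                      nh3_max_ppm = NA_real_, n_samples = 0L))
  }
  s <- samples[keep, , drop = FALSE]
  data.frame(temp_mean_c = mean(s$temp_c), rh_mean_pct = mean(s$rh_pct),
             co_max_ppm = max(s$co_ppm), h2s_max_ppm = max(s$h2s_ppm),
             nh3_max_ppm = max(s$nh3_ppm), n_samples = sum(keep))
}

#' Fit imputation + scaling parameters on training rows only
#'
#' Stores, per numeric feature, the training minimum, maximum, mean and (for
#' z-scoring) standard deviation, and per categorical feature the training
#' mode. Nothing outside `train` ever influences the state, which is what
#' makes downstream evaluation leakage-free.
#'
#' @param train Data frame of training rows.
#' @param numeric_features Character vector of numeric feature columns
#'   (default: all numeric columns).
#' @param categorical_features Character vector of categorical columns
#'   (default: none).
#' @param epsilon Small positive constant added to the denominator so a
#'   constant feature scales to 0 instead of dividing by zero.
#' @param method `"minmax"` (default) maps to `[0, 1)`; `"zscore"`
#'   standardizes by training moments (used for the feedforward net).
#' @return An object of class `fp_transform_state`.
#' @export
fit_transform_state <- function(train, numeric_features = NULL,
                                categorical_features = character(),
                                epsilon = 1e-8, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  check_scalar_number(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  if (is.null(numeric_features))
    numeric_features <- names(train)[vapply(train, is.numeric, logical(1))]
  num <- lapply(numeric_features, function(j) {
    x <- train[[j]]
    if (is.null(x)) stop("feature `", j, "` not present in training data",
                         call. = FALSE)
    x <- x[is.finite(x)]
    if (!length(x))
      stop("feature `", j, "` has no observed training values; cannot fit ",
           "imputation or scaling", call. = FALSE)
    list(min = min(x), max = max(x), mean = mean(x),
         sd = stats::sd(x))
  })
  names(num) <- numeric_features
  cat_ <- lapply(categorical_features, function(j) {
    x <- train[[j]]
    x <- x[!is.na(x)]
    if (!length(x))
      stop("categorical feature `", j, "` has no observed training values",
           call. = FALSE)
    tab <- table(x)
    names(tab)[which.max(tab)]  # mode; ties broken by first level
  })
  names(cat_) <- categorical_features
  structure(list(numeric = num, categorical = cat_, epsilon = epsilon,
                 method = method),
            class = "fp_transform_state")
}

#' Impute and scale a feature table with a fitted state
#'
#' Missing numeric values are replaced by the stored training mean (mode for
#' categoricals), then numeric features are min-max scaled,
#' `z = (x - min) / (max - min + epsilon)`, or z-scored when the state was
#' fitted with `method = "zscore"`.
#'
#' @param x Data frame of rows to transform (training or new data).
#' @param state A [fit_transform_state()] result.
#' @return Data frame with transformed numeric columns; other columns pass
#'   through untouched.
#' @export
apply_transform <- function(x, state) {
  stopifnot(inherits(state, "fp_transform_state"))
  for (j in names(state$numeric)) {
    p <- state$numeric[[j]]
    v <- x[[j]]
    v[!is.finite(v)] <- p$mean
    x[[j]] <- if (state$method == "minmax")
      (v - p$min) / (p$max - p$min + state$epsilon)
    else
      (v - p$mean) / (p$sd + state$epsilon)
  }
  for (j in names(state$categorical)) {
    v <- x[[j]]
    v[is.na(v)] <- state$categorical[[j]]
    x[[j]] <- v
  }
  x
}

#' Invert the numeric scaling of [apply_transform()]
#'
#' @param z Data frame of transformed rows.
#' @param state The state used to transform them.
#' @return Data frame on the original scale (imputed values stay imputed).
#' @export
invert_transform <- function(z, state) {
  stopifnot(inherits(state, "fp_transform_state"))
  for (j in names(state$numeric)) {
    p <- state$numeric[[j]]
    z[[j]] <- if (state$method == "minmax")
      z[[j]] * (p$max - p$min + state$epsilon) + p$min
    else
      z[[j]] * (p$sd + state$epsilon) + p$mean
  }
  z
}

#' Batch-wise temporal train/test split
#'
#' Within each batch the records are ordered by date and the last
#' `ceil(test_frac * n_batch)` form the test subset, so every test day is
#' later than every training day of its batch. 231 records in 3 batches of
#' 77 give 207 train / 24 test at the default 9:1 ratio.
#'
#' @param records Data frame with batch and date columns.
#' @param test_frac Test fraction, default 0.1.
#' @param batch_col,date_col Column names.
#' @return Object of class `fp_split`: list with integer row indices `train`
#'   and `test` into `records`.
#' @export
temporal_split <- function(records, test_frac = 0.1, batch_col = "batch_id",
                           date_col = "date") {
  check_scalar_number(test_frac, "test_frac", lower = 0, upper = 1)
  dates <- parse_iso_date(records[[date_col]], date_col)
  train <- integer(); test <- integer()
  for (b in unique(records[[batch_col]])) {
    idx <- which(records[[batch_col]] == b)
    idx <- idx[order(dates[idx])]
    n <- length(idx)
    if (n < 2L) {
      warning("batch ", b, " has fewer than 2 records; placed wholly in train",
              call. = FALSE)
      train <- c(train, idx)
      next
    }
    n_test <- ceiling(test_frac * n)
    train <- c(train, idx[seq_len(n - n_test)])
    test <- c(test, idx[seq(n - n_test + 1L, n)])
  }
  structure(list(train = train, test = test, test_frac = test_frac),
            class = "fp_split")
}

#' Repeated blocked cross-validation folds
#'
#' Within each batch, temporally ordered records are cut into `k` contiguous
#' blocks; block `i` goes to fold `i`. Each repeat shifts the interior cut
#' points by a seed-derived offset, so repeats see different (but still
#' contiguous, leakage-free) validation blocks. No record appears in two
#' folds of one repeat.
#'
#' @param records Data frame of training records.
#' @param k Number of folds, >= 2.
#' @param repeats Number of repeats, >= 1.
#' @param seed Integer seed controlling the repeat offsets.
#' @param batch_col,date_col Column names.
#' @return Integer matrix `nrow(records) x repeats`; entry (i, r) is the fold
#'   of record i in repeat r.
#' @export
blocked_cv_folds <- function(records, k = 5L, repeats = 1L, seed = 1L,
                             batch_col = "batch_id", date_col = "date") {
  k <- check_count(k, "k", min = 2L)
  repeats <- check_count(repeats, "repeats", min = 1L)
  dates <- parse_iso_date(records[[date_col]], date_col)
  folds <- matrix(NA_integer_, nrow(records), repeats)
  for (b in unique(records[[batch_col]])) {
    idx <- which(records[[batch_col]] == b)
    idx <- idx[order(dates[idx])]
    n <- length(idx)
    if (k > n)
      stop("k = ", k, " exceeds the ", n, " records of batch ", b,
           call. = FALSE)
    base_cuts <- round(seq_len(k - 1L) * n / k)
    max_shift <- max(0L, floor(n / k / 2) - 1L)
    for (r in seq_len(repeats)) {
      off <- if (r == 1L || max_shift == 0L) 0L else
        with_seed(derive_seed(seed, b, r),
                  sample.int(max_shift, 1L))
      cuts <- pmin(n - 1L, base_cuts + off)
      cuts <- unique(cuts)
      folds[idx, r] <- findInterval(seq_len(n) - 1L, cuts) + 1L
    }
  }
  folds
}

#' Assemble the daily live-weight model matrix
#'
#' Joins daily cage records with 24-h environmental summaries into the 7
#' canonical features plus the target `y_g_per_bird = cage weight / birds`.
#' Net feed is offered minus refusals minus spillage; age counts from each
#' batch's earliest record date (day 0).
#'
#' @param records Daily cage-record table (see [write_daily_records()]).
#' @param env Environmental sample table (see [write_env_samples()]).
#' @param weighing_hour Clock time of the fixed morning weighing, "HH:MM".
#' @return Data frame: metadata (`date`, `batch_id`, `cage_id`, `breed`),
#'   the [weight_feature_names()] columns, and `y_g_per_bird`.
#' @export
build_weight_matrix <- function(records, env, weighing_hour = "08:00") {
  net <- records$feed_offered_g - records$feed_refused_g - records$feed_spilled_g
  f <- per_bird_feed(pmax(net, 0), records$n_birds)
  y <- records$cage_weight_g / records$n_birds

  starts <- tapply(records$date, records$batch_id, min)
  age <- compute_age(records$date, unname(starts[records$batch_id]))

  ts_all <- parse_iso_time(env$timestamp)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    wt <- as.POSIXct(paste0(records$date[i], " ", weighing_hour, ":00"),
                     tz = "UTC")
    sub <- env$cage_id == records$cage_id[i] &
      ts_all > (wt - 86400) & ts_all <= wt
    out[[i]] <- if (any(sub)) {
      s <- env[sub, , drop = FALSE]
      data.frame(temp_mean_c = mean(s$temp_c), rh_mean_pct = mean(s$rh_pct),
                 co_max_ppm = max(s$co_ppm), h2s_max_ppm = max(s$h2s_ppm),
                 nh3_max_ppm = max(s$nh3_ppm))
    } else {
      data.frame(temp_mean_c = NA_real_, rh_mean_pct = NA_real_,
                 co_max_ppm = NA_real_, h2s_max_ppm = NA_real_,
                 nh3_max_ppm = NA_real_)
    }
  }
  envsum <- do.call(rbind, out)
  n_missing <- sum(is.na(envsum$temp_mean_c))
  if (n_missing > 0)
    warning(n_missing, " record day(s) had no environmental samples in the ",
            "24 h window; features left missing for train-mean imputation",
            call. = FALSE)
  cbind(records[c("date", "batch_id", "cage_id", "breed")],
        data.frame(age_days = age),
        envsum[c("temp_mean_c", "rh_mean_pct")],
        data.frame(feed_per_bird_g = f),
        envsum[c("co_max_ppm", "h2s_max_ppm", "nh3_max_ppm")],
        data.frame(y_g_per_bird = y))
}

#' Build interval training pairs for the total-feed model
#'
#' For every cage, every ordered day pair (s, e) with interval length
#' `e - s` between `min_len` and `max_len` (stepping `stride` days) yields one
#' example: start weight `y_s`, target weight `y_e`, remaining days `e - s`,
#' and target total feed = sum of per-bird feed over days s+1..e. Pairs with
#' non-increasing weight are skipped and counted in the `skipped` attribute.
#'
#' @param wm Weight model matrix from [build_weight_matrix()] (needs
#'   `cage_id`, `age_days`, `feed_per_bird_g`, `y_g_per_bird`).
#' @param min_len,max_len Interval length bounds in days (default 7 to all).
#' @param stride Step between successive start days and lengths, >= 1.
#' @return Data frame `w_start_g`, `w_target_g`, `d_remain`, `total_feed_g`
#'   (plus `cage_id`), with attribute `skipped`.
#' @export
build_interval_examples <- function(wm, min_len = 7L, max_len = Inf,
                                    stride = 1L) {
  min_len <- check_count(min_len, "min_len", min = 1L)
  stride <- check_count(stride, "stride", min = 1L)
  res <- list(); skipped <- 0L
  for (cg in unique(wm$cage_id)) {
    d <- wm[wm$cage_id == cg, , drop = FALSE]
    d <- d[order(d$age_days), , drop = FALSE]
    n <- nrow(d)
    cf <- cumsum(d$feed_per_bird_g)
    for (s in seq(1L, n, by = stride)) {
      if (s + min_len > n) next
      ends <- seq(s + min_len, min(n, s + max_len), by = stride)
      ends <- ends[ends <= n]
      if (!length(ends)) next
      ok <- d$y_g_per_bird[ends] > d$y_g_per_bird[s]
      skipped <- skipped + sum(!ok)
      ends <- ends[ok]
      if (!length(ends)) next
      res[[length(res) + 1L]] <- data.frame(
        cage_id = cg,
        w_start_g = d$y_g_per_bird[s],
        w_target_g = d$y_g_per_bird[ends],
        d_remain = d$age_days[ends] - d$age_days[s],
        total_feed_g = cf[ends] - cf[s]
      )
    }
  }
  out <- if (length(res)) do.call(rbind, c(res, make.row.names = FALSE)) else
    data.frame(cage_id = character(), w_start_g = numeric(),
               w_target_g = numeric(), d_remain = numeric(),
               total_feed_g = numeric())
  attr(out, "skipped") <- skipped
  out
}
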