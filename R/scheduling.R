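# Closed-loop ration scheduling: forecast the interval feed total, shape it
# into a constrained daily ration plan, simulate the weight trajectory with
# the daily body-weight model, and correct the interval total proportionally
# until the simulated terminal weight hits the target.

#' Interval specification
#'
#' @param w_start Current per-bird live weight, g, > 0.
#' @param w_target Target per-bird live weight, g, > `w_start`.
#' @param d_remain Remaining rearing days, >= 1.
#' @return Object of class `fp_interval_spec`.
#' @export
interval_spec <- function(w_start, w_target, d_remain) {
  check_scalar_number(w_start, "w_start", lower = 0, strict_lower = TRUE)
  check_scalar_number(w_target, "w_target", lower = w_start,
                      strict_lower = TRUE)
  d_remain <- check_count(d_remain, "d_remain", min = 1L)
  structure(list(w_start = w_start, w_target = w_target, d_remain = d_remain),
            class = "fp_interval_spec")
}

#' Scheduler configuration
#'
#' @param tolerance Terminal-error tolerance epsilon, g (default 10).
#' @param max_iter Iteration cap J_max (default 20).
#' @param daily_min,daily_max Per-bird daily ration bounds, g.
#' @param max_rel_change Maximum relative day-to-day ration change
#'   (default 0.10, i.e. +/-10% of the previous day).
#' @param gain_clip Length-2 daily-gain clip band in g/day applied during
#'   trajectory simulation (default `c(0, 80)`); `NULL` disables clipping.
#' @return Object of class `fp_schedule_config`.
#' @export
schedule_config <- function(tolerance = 10, max_iter = 20L,
                            daily_min = 10, daily_max = 250,
                            max_rel_change = 0.10, gain_clip = c(0, 80)) {
  check_scalar_number(tolerance, "tolerance", lower = 0, strict_lower = TRUE)
  max_iter <- check_count(max_iter, "max_iter", min = 1L)
  check_scalar_number(daily_min, "daily_min", lower = 0)
  check_scalar_number(daily_max, "daily_max", lower = daily_min)
  check_scalar_number(max_rel_change, "max_rel_change", lower = 0,
                      strict_lower = TRUE, upper = 1)
  if (!is.null(gain_clip)) {
    stopifnot(is.numeric(gain_clip), length(gain_clip) == 2L,
              gain_clip[1] <= gain_clip[2])
  }
  structure(list(tolerance = tolerance, max_iter = max_iter,
                 daily_min = daily_min, daily_max = daily_max,
                 max_rel_change = max_rel_change, gain_clip = gain_clip),
            class = "fp_schedule_config")
}

#' Forecast the per-bird interval feed total
#'
#' Evaluates the total-feed model on (start weight, target weight, remaining
#' days). A non-positive prediction is flagged and floored at
#' `daily_min * d_remain`.
#'
#' @param spec [interval_spec()].
#' @param feed_model Fitted feed model (`fp_pipeline`/`fp_regressor`) or a
#'   function of a 1-row data frame with [feed_feature_names()] columns.
#' @param cfg [schedule_config()] supplying the floor.
#' @return Positive scalar, g per bird over the interval.
#' @export
forecast_interval_feed <- function(spec, feed_model, cfg = schedule_config()) {
  stopifnot(inherits(spec, "fp_interval_spec"))
  row <- data.frame(w_start_g = spec$w_start, w_target_g = spec$w_target,
                    d_remain = spec$d_remain)
  f <- if (is.function(feed_model)) feed_model else
    function(d) stats::predict(feed_model, d)
  pred <- as.numeric(f(row))
  if (!is.finite(pred))
    stop("feed model returned a non-finite total", call. = FALSE)
  floor_total <- cfg$daily_min * spec$d_remain
  if (pred <= 0) {
    warning("feed model predicted a non-positive interval total (", round(pred, 2),
            " g); flooring at daily_min * d_remain = ", floor_total, " g",
            call. = FALSE)
    pred <- max(floor_total, 1e-6)
  }
  pred
}

#' Allocate an interval total across days by a historical profile
#'
#' Normalizes the non-negative profile weights to sum to one and multiplies
#' by the interval total; the last day absorbs floating-point residual so the
#' sum is exact.
#'
#' @param total Interval feed total, g per bird.
#' @param profile Non-negative unnormalized daily weights, at least one > 0.
#' @return Numeric vector of daily rations summing to `total`.
#' @export
allocate_profile <- function(total, profile) {
  check_scalar_number(total, "total", lower = 0, strict_lower = TRUE)
  if (any(profile < 0)) stop("profile weights must be non-negative",
                             call. = FALSE)
  s <- sum(profile)
  if (s <= 0) stop("profile weights are all zero; cannot normalize",
                   call. = FALSE)
  f <- total * profile / s
  n <- length(f)
  f[n] <- total - sum(f[-n])
  f
}

#' Allocate an interval total across days by an arithmetic progression
#'
#' Raw terms `a + (m - 1) * d` for day positions m = 1..n_days, rescaled so
#' their sum equals the interval total. Every raw term must be positive.
#'
#' @param total Interval feed total, g per bird.
#' @param n_days Interval length.
#' @param a First term (g), default 1 (only the shape matters).
#' @param d Common difference (g/day); default doubles the ration across the
#'   interval (`a / (n_days - 1)`).
#' @return Numeric vector of daily rations summing to `total`.
#' @export
allocate_arithmetic <- function(total, n_days, a = 1,
                                d = if (n_days > 1) a / (n_days - 1) else 0) {
  n_days <- check_count(n_days, "n_days", min = 1L)
  raw <- a + (seq_len(n_days) - 1) * d
  bad <- which(raw <= 0)
  if (length(bad))
    stop("arithmetic profile is non-positive on day ", bad[1],
         " (a = ", a, ", d = ", d, ")", call. = FALSE)
  allocate_profile(total, raw)
}

#' Enforce ration bounds and the day-to-day change band
#'
#' Alternating projection: clip rations into `[daily_min, daily_max]`, run a
#' forward then backward pass clipping each consecutive relative step into
#' `[1 - band, 1 + band]`, rescale to restore the interval total, and repeat
#' until all constraints hold to 1e-6 relative (at most 50 rounds). The
#' interval total is conserved.
#'
#' @param rations Positive daily rations, g per bird.
#' @param cfg [schedule_config()].
#' @return Feasible daily rations with the same sum.
#' @export
enforce_constraints <- function(rations, cfg = schedule_config()) {
  total <- sum(rations)
  n <- length(rations)
  if (total <= 0) stop("plan total must be positive", call. = FALSE)
  if (cfg$daily_min * n > total + 1e-9)
    stop("infeasible: interval total ", round(total, 3),
         " g is below daily_min * n_days = ", cfg$daily_min * n, " g",
         call. = FALSE)
  if (cfg$daily_max * n < total - 1e-9)
    stop("infeasible: interval total ", round(total, 3),
         " g exceeds daily_max * n_days = ", cfg$daily_max * n, " g",
         call. = FALSE)
  band <- cfg$max_rel_change
  tol <- 1e-6
  feasible <- function(f) {
    all(f >= cfg$daily_min - tol * total) &&
      all(f <= cfg$daily_max + tol * total) &&
      (n == 1L || all(abs(f[-1] / f[-n] - 1) <= band + tol))
  }
  f <- rations
  for (round in seq_len(50L)) {
    f <- pmin(pmax(f, cfg$daily_min), cfg$daily_max)
    if (n > 1L) {
      for (i in 2:n)  # forward pass: respect band wrt previous day
        f[i] <- min(max(f[i], f[i - 1] * (1 - band)), f[i - 1] * (1 + band))
      for (i in (n - 1):1)  # backward pass: respect band wrt next day
        f[i] <- min(max(f[i], f[i + 1] / (1 + band)), f[i + 1] / (1 - band))
    }
    f <- f * (total / sum(f))
    if (feasible(f)) return(f)
  }
  viol_min <- any(f < cfg$daily_min - tol * total)
  viol_max <- any(f > cfg$daily_max + tol * total)
  stop("constraint enforcement did not converge; binding constraint: ",
       if (viol_min) "daily_min" else if (viol_max) "daily_max"
       else "day-to-day change band", call. = FALSE)
}

#' Simulate the daily weight trajectory under a ration plan
#'
#' Evaluates the daily body-weight model for each interval day on (age,
#' environmental forecast, planned ration). When a gain clip band is
#' configured, the day's gain relative to the previous simulated weight is
#' clipped into the band and the clipped weight propagates forward; with
#' `gain_clip = NULL` the raw model outputs are returned.
#'
#' @param rations Daily per-bird rations, g.
#' @param env Data frame with one row per interval day: `temp_mean_c`,
#'   `rh_mean_pct`, `co_max_ppm`, `h2s_max_ppm`, `nh3_max_ppm`.
#' @param ages Integer ages (days) of the interval days.
#' @param weight_model Fitted weight model or function of a data frame with
#'   [weight_feature_names()] columns.
#' @param cfg [schedule_config()].
#' @param w_start Per-bird weight at interval start, g (anchors the first
#'   day's gain).
#' @return Numeric vector of simulated per-bird weights, one per day.
#' @export
simulate_trajectory <- function(rations, env, ages, weight_model,
                                cfg = schedule_config(), w_start) {
  n <- length(rations)
  if (nrow(env) != n)
    stop("environmental forecast must have one row per interval day (",
         n, " needed, ", nrow(env), " given)", call. = FALSE)
  if (length(ages) != n)
    stop("`ages` must have one entry per interval day", call. = FALSE)
  X <- data.frame(age_days = ages,
                  temp_mean_c = env$temp_mean_c,
                  rh_mean_pct = env$rh_mean_pct,
                  feed_per_bird_g = rations,
                  co_max_ppm = env$co_max_ppm,
                  h2s_max_ppm = env$h2s_max_ppm,
                  nh3_max_ppm = env$nh3_max_ppm)
  f <- if (is.function(weight_model)) weight_model else
    function(d) stats::predict(weight_model, d)
  raw <- as.numeric(f(X))
  if (length(raw) != n)
    stop("weight model must return one prediction per day", call. = FALSE)
  if (is.null(cfg$gain_clip)) return(raw)
  out <- numeric(n)
  prev <- w_start
  for (i in seq_len(n)) {
    gain <- min(max(raw[i] - prev, cfg$gain_clip[1]), cfg$gain_clip[2])
    out[i] <- prev + gain
    prev <- out[i]
  }
  out
}

#' Proportional update of the interval feed total
#'
#' `F_new = F * w_target / w_end`: if the simulated terminal weight fell
#' short, feed more in proportion; if it overshot, feed less.
#'
#' @param total Current interval feed total, g.
#' @param w_end Simulated terminal weight, g, > 0.
#' @param w_target Target terminal weight, g.
#' @return Updated total.
#' @export
update_interval_total <- function(total, w_end, w_target) {
  if (!is.finite(w_end) || w_end <= 0)
    stop("simulated terminal weight must be positive", call. = FALSE)
  total * w_target / w_end
}

#' Run the closed-loop feeding schedule
#'
#' Forecast the interval total with the feed model, allocate it across days
#' (historical profile if given, else arithmetic progression), enforce the
#' ration bounds and +/-10% day-to-day band, simulate the weight trajectory
#' with the weight model, and update the total proportionally until the
#' terminal error is within tolerance or the iteration cap is reached.
#' Reallocation after each update rescales every day by the same factor
#' (shape-preserving) and re-enforces the constraints.
#'
#' @param spec [interval_spec()].
#' @param feed_model,weight_model Fitted models or prediction functions (see
#'   [forecast_interval_feed()], [simulate_trajectory()]).
#' @param env Environmental forecast, one row per interval day.
#' @param cfg [schedule_config()].
#' @param profile Optional historical intake profile (unnormalized weights,
#'   one per day); when `NULL` an arithmetic progression is used.
#' @param start_age Age in days at interval start; interval days are
#'   `start_age + 1 .. start_age + d_remain`.
#' @param a,d Arithmetic-progression parameters (see [allocate_arithmetic()]).
#' @param n_birds Cage size used for the cage-level ration column.
#' @return Object of class `fp_schedule_result`: `plan` (data frame
#'   `age_days`, `per_bird_ration_g`, `cage_ration_g`, `predicted_weight_g`),
#'   `total` (final interval total), `trajectory`, `terminal_weights` (one per
#'   iteration), `iterations`, `terminal_error`, `converged`, and `fcr`
#'   (planned interval FCR against the target).
#' @export
run_schedule <- function(spec, feed_model, weight_model, env,
                         cfg = schedule_config(), profile = NULL,
                         start_age = 0L, a = 1, d = NULL, n_birds = 4L) {
  stopifnot(inherits(spec, "fp_interval_spec"),
            inherits(cfg, "fp_schedule_config"))
  n <- spec$d_remain
  ages <- start_age + seq_len(n)
  if (nrow(env) != n)
    stop("environmental forecast must cover all ", n, " interval days",
         call. = FALSE)

  total <- forecast_interval_feed(spec, feed_model, cfg)
  rations <- if (!is.null(profile)) {
    if (length(profile) != n)
      stop("profile must have one weight per interval day", call. = FALSE)
    allocate_profile(total, profile)
  } else if (is.null(d)) {
    allocate_arithmetic(total, n, a = a)
  } else {
    allocate_arithmetic(total, n, a = a, d = d)
  }
  rations <- enforce_constraints(rations, cfg)

  terminal <- numeric(0)
  best <- NULL
  converged <- FALSE
  j <- 0L
  while (j < cfg$max_iter) {
    j <- j + 1L
    traj <- simulate_trajectory(rations, env, ages, weight_model, cfg,
                                w_start = spec$w_start)
    w_end <- traj[n]
    terminal <- c(terminal, w_end)
    err <- w_end - spec$w_target
    if (is.null(best) || abs(err) < abs(best$err))
      best <- list(rations = rations, traj = traj, err = err, total = sum(rations))
    if (abs(err) <= cfg$tolerance) {
      converged <- TRUE
      break
    }
    new_total <- update_interval_total(sum(rations), w_end, spec$w_target)
    # keep the update inside the operationally feasible range; an unreachable
    # target then parks the loop at the bound instead of erroring
    new_total <- min(max(new_total, cfg$daily_min * n), cfg$daily_max * n)
    rations <- rations * (new_total / sum(rations))
    rations <- enforce_constraints(rations, cfg)
  }
  plan <- data.frame(age_days = ages,
                     per_bird_ration_g = best$rations,
                     cage_ration_g = best$rations * n_birds,
                     predicted_weight_g = best$traj)
  structure(list(plan = plan, total = best$total, trajectory = best$traj,
                 terminal_weights = terminal, iterations = j,
                 terminal_error = best$err, converged = converged,
                 fcr = compute_fcr(best$rations, spec$w_start, spec$w_target),
                 spec = spec, config = cfg),
            class = "fp_schedule_result")
}

#' @export
print.fp_schedule_result <- function(x, ...) {
  cat(sprintf(
    "feeding schedule: %d days, %.2f -> %.2f g target\n  interval total %.2f g/bird | iterations %d | terminal error %+.2f g (%s)\n  planned FCR %.2f\n",
    nrow(x$plan), x$spec$w_start, x$spec$w_target, x$total, x$iterations,
    x$terminal_error, if (x$converged) "converged" else "not converged",
    round(x$fcr, 2)))
  invisible(x)
}

#' Interval feed conversion ratio
#'
#' Total feed over the interval divided by the body-weight gain.
#'
#' @param rations Daily per-bird rations over the interval, g.
#' @param w_start,w_end Per-bird weights at interval start and end, g,
#'   `w_end > w_start`.
#' @return FCR (dimensionless; report to 2 decimals in summaries).
#' @export
#' @examples
#' compute_fcr(rep(5578.08 / 54, 54), 785, 2490)  # 3.27
compute_fcr <- function(rations, w_start, w_end) {
  if (!is.finite(w_end) || !is.finite(w_start) || w_end <= w_start)
    stop("FCR undefined: terminal weight must exceed start weight",
         call. = FALSE)
  sum(rations) / (w_end - w_start)
}

#' Climatology environmental forecast
#'
#' Mean of the trailing `window` observed days per variable, replicated over
#' the interval days - the default forecast policy when no forecast table is
#' supplied.
#'
#' @param env_history Data frame of observed daily summaries with the 5
#'   environmental columns (most recent rows last).
#' @param n_days Interval length to forecast.
#' @param window Trailing days averaged (default 7).
#' @return Data frame with `n_days` identical rows.
#' @export
env_climatology <- function(env_history, n_days, window = 7L) {
  cols <- c("temp_mean_c", "rh_mean_pct", "co_max_ppm", "h2s_max_ppm",
            "nh3_max_ppm")
  h <- utils::tail(env_history[stats::complete.cases(env_history[cols]), cols],
                   window)
  if (!nrow(h)) stop("no complete environmental history to average",
                     call. = FALSE)
  means <- colMeans(h)
  out <- as.data.frame(as.list(means))[rep(1L, n_days), , drop = FALSE]
  rownames(out) <- NULL
  out
}
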