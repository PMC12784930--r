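# Synthetic cage-rearing data generator.
#
# Emulates the statistical structure of a small native-chicken cage trial:
# sigmoidal (Gompertz) cage-mean growth to a 2.0-3.3 kg mature weight,
# daily-cyclic environmental traces whose per-day gas maxima fall in stated
# ranges (NH3 ~0.3-4.0 ppm, H2S ~0.2-4.5 ppm), and a monotone per-bird intake
# profile (~57 -> 145 g/day). Everything is deterministic given a seed, so the
# downstream preprocessing / modeling / scheduling stages are testable without
# any farm data.

#' Gompertz growth parameters for one cage
#'
#' The cage-mean live weight on day `t` is modelled as
#' `A * exp(-b * exp(-k * t))` plus independent Gaussian observation noise.
#' `A` is the asymptotic mature weight (g), `b` a dimensionless shape
#' parameter setting the hatch weight `A * exp(-b)`, and `k` the maturation
#' rate (1/day).
#'
#' @param asymptote_A Asymptotic mature weight in grams, > 0.
#' @param shape_b Dimensionless shape parameter, > 0.
#' @param rate_k Maturation rate in 1/day, > 0.
#' @param obs_noise_sd Observation noise standard deviation in grams, >= 0.
#' @param birds_per_cage Birds housed per cage, >= 1.
#' @return An object of class `fp_growth_params`.
#' @export
#' @examples
#' gp <- growth_params(3000, 4, 0.05)
#' gen_cage_trajectory(gp, n_days = 5, seed = 1)
growth_params <- function(asymptote_A, shape_b, rate_k,
                          obs_noise_sd = 0, birds_per_cage = 4L) {
  check_scalar_number(asymptote_A, "asymptote_A", lower = 0, strict_lower = TRUE)
  check_scalar_number(shape_b, "shape_b", lower = 0, strict_lower = TRUE)
  check_scalar_number(rate_k, "rate_k", lower = 0, strict_lower = TRUE)
  check_scalar_number(obs_noise_sd, "obs_noise_sd", lower = 0)
  birds_per_cage <- check_count(birds_per_cage, "birds_per_cage", min = 1L)
  structure(list(asymptote_A = asymptote_A, shape_b = shape_b, rate_k = rate_k,
                 obs_noise_sd = obs_noise_sd, birds_per_cage = birds_per_cage),
            class = "fp_growth_params")
}

#' Default growth presets for the three native breeds
#'
#' Mature weights reflect the breeds' typical market classes (Guzao males
#' lightest, Red Junglefowl males heaviest and most variable). All values are
#' overridable by passing your own [growth_params()] list to [gen_dataset()].
#'
#' @return Named list of `fp_growth_params`.
#' @export
breed_presets <- function() {
  list(
    Guzao         = growth_params(2600, 4.2, 0.036, obs_noise_sd = 15),
    Huangjin      = growth_params(3000, 4.2, 0.036, obs_noise_sd = 15),
    RedJunglefowl = growth_params(3300, 4.2, 0.038, obs_noise_sd = 30)
  )
}

#' Environmental generator configuration
#'
#' Temperature and relative humidity follow a sinusoidal daily cycle around
#' their means; each gas trace is a positive daily cycle scaled so that its
#' per-day maximum is drawn uniformly inside the configured range. Defaults
#' reproduce the observed gas exposure ranges of a well-ventilated house
#' (daily NH3 maxima 0.3-4.0 ppm, H2S maxima 0.2-4.5 ppm, CO near zero).
#'
#' @param temp_mean,temp_amp Daily mean and cycle amplitude of temperature, degrees C.
#' @param rh_mean,rh_amp Daily mean and cycle amplitude of relative humidity, percent.
#' @param co_max_range,h2s_max_range,nh3_max_range Length-2 numeric ranges
#'   (ppm) from which each day's maximum concentration is drawn.
#' @param samples_per_day Sensor samples per day, >= 1 (default hourly).
#' @return An object of class `fp_env_ranges`.
#' @export
env_ranges <- function(temp_mean = 26, temp_amp = 3,
                       rh_mean = 70, rh_amp = 8,
                       co_max_range = c(0.02, 0.8),
                       h2s_max_range = c(0.2, 4.5),
                       nh3_max_range = c(0.3, 4.0),
                       samples_per_day = 24L) {
  for (nm in c("co_max_range", "h2s_max_range", "nh3_max_range")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 2L || anyNA(r))
      stop(sprintf("`%s` must be a numeric range of length 2", nm), call. = FALSE)
    if (any(r < 0))
      stop(sprintf("`%s` endpoints must be non-negative", nm), call. = FALSE)
    if (r[1] > r[2])
      stop(sprintf("`%s` lower bound exceeds upper bound", nm), call. = FALSE)
  }
  check_scalar_number(rh_mean, "rh_mean", lower = 0, upper = 100)
  samples_per_day <- check_count(samples_per_day, "samples_per_day", min = 1L)
  structure(list(temp_mean = temp_mean, temp_amp = temp_amp,
                 rh_mean = rh_mean, rh_amp = rh_amp,
                 co_max_range = co_max_range, h2s_max_range = h2s_max_range,
                 nh3_max_range = nh3_max_range,
                 samples_per_day = samples_per_day),
            class = "fp_env_ranges")
}

#' Synthetic dataset configuration
#'
#' Defaults emulate the study scale: 3 batches x 77 rearing days per breed
#' (231 daily cage-level records per breed) for three breeds.
#'
#' @param n_batches Number of rearing batches per breed.
#' @param n_days Rearing days recorded per batch, >= 2.
#' @param breeds Character vector of breed labels.
#' @param batch_start_dates ISO-8601 start date per batch (distinct); default
#'   consecutive cycles 84 days apart starting 2024-11-05.
#' @param seed Integer master seed.
#' @return An object of class `fp_synth_config`.
#' @export
synthetic_config <- function(n_batches = 3L, n_days = 77L,
                             breeds = c("Guzao", "Huangjin", "RedJunglefowl"),
                             batch_start_dates = NULL, seed = 20241105L) {
  n_batches <- check_count(n_batches, "n_batches", min = 1L)
  n_days <- check_count(n_days, "n_days", min = 2L)
  if (is.null(batch_start_dates))
    batch_start_dates <- format(as.Date("2024-11-05") + 84L * (seq_len(n_batches) - 1L))
  batch_start_dates <- parse_iso_date(batch_start_dates, "batch_start_dates")
  if (length(batch_start_dates) != n_batches)
    stop("`batch_start_dates` must supply one date per batch", call. = FALSE)
  if (anyDuplicated(batch_start_dates))
    stop("`batch_start_dates` must be distinct per batch", call. = FALSE)
  structure(list(n_batches = n_batches, n_days = n_days,
                 breeds = as.character(breeds),
                 batch_start_dates = batch_start_dates,
                 seed = as.integer(seed)),
            class = "fp_synth_config")
}

#' Gompertz mean curve
#'
#' @param t Age in days (vectorized).
#' @param params [growth_params()] object.
#' @return Expected cage-mean weight in grams.
#' @export
gompertz_weight <- function(t, params) {
  stopifnot(inherits(params, "fp_growth_params"))
  params$asymptote_A * exp(-params$shape_b * exp(-params$rate_k * t))
}

#' Simulate one cage's daily mean-weight trajectory
#'
#' Day-indexed from age 0. The expected value follows the Gompertz curve;
#' observation noise is additive Gaussian at cage level. The day-0 draw is
#' bounded (+/-4% uniform) so that initial weights of replicate cages fall
#' within +/-5% of their common mean, mirroring the intake-check applied when
#' birds are assigned to cages.
#'
#' @param params [growth_params()] object.
#' @param n_days Number of daily records, >= 1.
#' @param seed Integer seed; identical inputs give identical output.
#' @return Numeric vector of length `n_days`, grams.
#' @export
gen_cage_trajectory <- function(params, n_days, seed) {
  stopifnot(inherits(params, "fp_growth_params"))
  n_days <- check_count(n_days, "n_days", min = 1L)
  mu <- gompertz_weight(seq_len(n_days) - 1, params)
  with_seed(seed, {
    w <- mu + stats::rnorm(n_days, sd = params$obs_noise_sd)
    if (params$obs_noise_sd > 0)
      w[1] <- mu[1] * (1 + stats::runif(1, -0.04, 0.04))
    pmax(w, 1)
  })
}

#' Simulate a timestamped environmental sensor stream
#'
#' `samples_per_day` records per day. Temperature and RH are sinusoidal daily
#' cycles with Gaussian jitter; each gas is a strictly positive daily cycle
#' rescaled so its per-day maximum equals a uniform draw from the configured
#' max range (so daily maxima always fall inside that range, and daily means
#' never exceed them).
#'
#' @param ranges [env_ranges()] object.
#' @param n_days Days to simulate, >= 1.
#' @param seed Integer seed.
#' @param cage_id Cage identifier recorded on every sample.
#' @param start_date ISO-8601 date of day 0.
#' @return Data frame with columns `timestamp`, `cage_id`, `temp_c`, `rh_pct`,
#'   `co_ppm`, `h2s_ppm`, `nh3_ppm`.
#' @export
gen_env_series <- function(ranges, n_days, seed, cage_id = "C1",
                           start_date = "2024-11-05") {
  stopifnot(inherits(ranges, "fp_env_ranges"))
  n_days <- check_count(n_days, "n_days", min = 1L)
  day0 <- parse_iso_date(start_date, "start_date")
  s <- ranges$samples_per_day
  hours <- (seq_len(s) - 1) * 24 / s
  phase <- 2 * pi * (hours - 15) / 24  # afternoon peak

  gas_day <- function(max_range, day_seed) {
    with_seed(day_seed, {
      daymax <- stats::runif(1, max_range[1], max_range[2])
      raw <- 0.55 + 0.45 * sin(phase) + abs(stats::rnorm(s, sd = 0.05))
      raw * (daymax / max(raw))
    })
  }

  out <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    sd_base <- derive_seed(seed, cage_id, d)
    tr <- with_seed(derive_seed(sd_base, "t"),
                    ranges$temp_mean + ranges$temp_amp * sin(phase) +
                      stats::rnorm(s, sd = 0.3))
    rh <- with_seed(derive_seed(sd_base, "rh"),
                    pmin(100, pmax(0, ranges$rh_mean - ranges$rh_amp * sin(phase) +
                                        stats::rnorm(s, sd = 1))))
    ts <- as.POSIXct(day0, tz = "UTC") + (d - 1) * 86400 + hours * 3600
    out[[d]] <- data.frame(
      timestamp = format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      cage_id = cage_id,
      temp_c = round(tr, 3),
      rh_pct = round(rh, 3),
      co_ppm = round(gas_day(ranges$co_max_range, derive_seed(sd_base, "co")), 5),
      h2s_ppm = round(gas_day(ranges$h2s_max_range, derive_seed(sd_base, "h2s")), 5),
      nh3_ppm = round(gas_day(ranges$nh3_max_range, derive_seed(sd_base, "nh3")), 5),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Monotone per-bird intake profile
#'
#' Unnormalized daily intake weights rising from `start_g` to `end_g`
#' (defaults reproduce the ~57 -> 145 g/day ramp of a grower phase). The
#' `shape` exponent bends the ramp (1 = linear, > 1 = late acceleration)
#' while keeping it monotone non-decreasing.
#'
#' @param n_days Profile length, >= 1.
#' @param start_g,end_g Positive endpoints in g/day, `start_g <= end_g`.
#' @param shape Positive curvature exponent, default 1 (linear).
#' @return Numeric vector of length `n_days`.
#' @export
gen_intake_profile <- function(n_days, start_g = 57, end_g = 145, shape = 1) {
  n_days <- check_count(n_days, "n_days", min = 1L)
  check_scalar_number(start_g, "start_g", lower = 0, strict_lower = TRUE)
  check_scalar_number(end_g, "end_g", lower = 0, strict_lower = TRUE)
  check_scalar_number(shape, "shape", lower = 0, strict_lower = TRUE)
  if (end_g < start_g)
    stop("`end_g` must be >= `start_g` for a non-decreasing profile", call. = FALSE)
  if (n_days == 1L) return(start_g)
  u <- (seq_len(n_days) - 1) / (n_days - 1)
  start_g + (end_g - start_g) * u^shape
}

#' Generate a full synthetic cage-rearing dataset
#'
#' One cage per breed per batch. Per breed the daily-record count is
#' `n_batches * n_days` (3 x 77 = 231 under defaults). Per-bird intake
#' follows [gen_intake_profile()] rescaled so the interval feed conversion
#' ratio (total intake / weight gain) equals `fcr_target`, tying intake to
#' growth the way a fixed commercial diet does. Offered feed exceeds intake
#' by the configured refusal and spillage fractions.
#'
#' @param config [synthetic_config()] object.
#' @param growth Named list of [growth_params()], one per breed in
#'   `config$breeds` (default [breed_presets()]).
#' @param env [env_ranges()] object.
#' @param fcr_target Interval FCR the intake profile is scaled to (default 3.3,
#'   the mid-range of a native-chicken grower phase). `NULL` keeps the raw
#'   57-145 g profile.
#' @param refusal_frac,spill_frac Fractions of offered feed refused / spilled.
#' @return List with elements `records` (daily cage records) and `env`
#'   (sensor samples), both plain data frames as documented in
#'   [write_daily_records()] / [write_env_samples()].
#' @export
#' @examples
#' cfg <- synthetic_config(n_batches = 1, n_days = 10, breeds = "Guzao", seed = 7)
#' d <- gen_dataset(cfg)
#' nrow(d$records)  # 10
gen_dataset <- function(config, growth = breed_presets(), env = env_ranges(),
                        fcr_target = 3.3, refusal_frac = 0.03,
                        spill_frac = 0.02) {
  stopifnot(inherits(config, "fp_synth_config"), inherits(env, "fp_env_ranges"))
  missing_breeds <- setdiff(config$breeds, names(growth))
  if (length(missing_breeds))
    stop("no growth parameters supplied for breed(s): ",
         paste(missing_breeds, collapse = ", "), call. = FALSE)

  rec_list <- list(); env_list <- list()
  for (breed in config$breeds) {
    gp <- growth[[breed]]
    stopifnot(inherits(gp, "fp_growth_params"))
    for (b in seq_len(config$n_batches)) {
      cage <- sprintf("%s-B%d", breed, b)
      batch <- sprintf("B%02d", b)
      start <- config$batch_start_dates[b]
      sd_cage <- derive_seed(config$seed, breed, b)
      traj <- gen_cage_trajectory(gp, config$n_days, sd_cage)

      profile <- gen_intake_profile(config$n_days)
      if (!is.null(fcr_target)) {
        gain <- gompertz_weight(config$n_days - 1, gp) - gompertz_weight(0, gp)
        profile <- profile * (fcr_target * gain / sum(profile))
      }
      consumed_cage <- profile * gp$birds_per_cage
      offered <- consumed_cage / (1 - refusal_frac - spill_frac)
      refused <- offered * refusal_frac
      spilled <- offered * spill_frac

      rec_list[[cage]] <- data.frame(
        date = format(start + seq_len(config$n_days) - 1L),
        batch_id = batch,
        cage_id = cage,
        breed = breed,
        n_birds = gp$birds_per_cage,
        feed_offered_g = round(offered, 2),
        feed_refused_g = round(refused, 2),
        feed_spilled_g = round(spilled, 2),
        cage_weight_g = round(traj * gp$birds_per_cage, 1),
        stringsAsFactors = FALSE
      )
      env_list[[cage]] <- gen_env_series(env, config$n_days,
                                         seed = derive_seed(sd_cage, "env"),
                                         cage_id = cage,
                                         start_date = format(start))
    }
  }
  list(records = do.call(rbind, c(rec_list, make.row.names = FALSE)),
       env = do.call(rbind, c(env_list, make.row.names = FALSE)))
}

# Table IO --------------------------------------------------------------------

#' Read and write the daily cage-record table
#'
#' Plain comma-delimited text with ISO-8601 dates; columns `date`, `batch_id`,
#' `cage_id`, `breed`, `n_birds`, `feed_offered_g`, `feed_refused_g`,
#' `feed_spilled_g`, `cage_weight_g`. Writing then re-reading round-trips the
#' table exactly.
#'
#' @param x Data frame of daily records.
#' @param path File path.
#' @return `read_daily_records` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_daily_records <- function(x, path) {
  need <- c("date", "batch_id", "cage_id", "breed", "n_birds",
            "feed_offered_g", "feed_refused_g", "feed_spilled_g",
            "cage_weight_g")
  if (!all(need %in% names(x)))
    stop("daily record table missing column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  utils::write.csv(x[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily_records
#' @export
read_daily_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(date = "character", batch_id = "character",
                                 cage_id = "character", breed = "character"))
}

#' Read and write the environmental sample table
#'
#' Columns `timestamp` (ISO-8601), `cage_id`, `temp_c`, `rh_pct`, `co_ppm`,
#' `h2s_ppm`, `nh3_ppm`.
#'
#' @param x Data frame of sensor samples.
#' @param path File path.
#' @return `read_env_samples` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_env_samples <- function(x, path) {
  need <- c("timestamp", "cage_id", "temp_c", "rh_pct", "co_ppm", "h2s_ppm",
            "nh3_ppm")
  if (!all(need %in% names(x)))
    stop("environment table missing column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  utils::write.csv(x[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_env_samples
#' @export
read_env_samples <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(timestamp = "character", cage_id = "character"))
}
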