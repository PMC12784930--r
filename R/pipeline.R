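# End-to-end orchestration and command-line entry points:
# simulate -> preprocess -> train -> (explain) -> schedule -> economics,
# with a fixed seed, a deterministic artifact tree and a machine-readable
# run manifest.

#' Default run configuration
#'
#' A single key-value hierarchy mirroring the module configs 1:1; CLI flags
#' override file values. `simulate = NULL` with `records`/`env` paths set
#' consumes existing tables instead of simulating.
#'
#' @param seed Master seed recorded in all outputs.
#' @param breed Breed whose models drive the schedule.
#' @param model Learner preset for both models (`"et"`, `"rf"`, `"gbm"`,
#'   `"ann"`).
#' @return Nested list.
#' @export
default_run_config <- function(seed = 1L, breed = "Guzao", model = "et") {
  list(
    seed = seed,
    breed = breed,
    model = model,
    records = NULL, env = NULL,
    simulate = list(n_batches = 3L, n_days = 77L,
                    breeds = c("Guzao", "Huangjin", "RedJunglefowl")),
    preprocess = list(weighing_hour = "08:00", interval_min_len = 7L,
                      interval_max_len = 60L, interval_stride = 2L),
    schedule = list(start_weight = 620, target_weight = 1700,
                    start_day = 30L, target_day = 70L,
                    tolerance = 10, max_iter = 20L,
                    daily_min = 10, daily_max = 250, max_rel_change = 0.10),
    economics = list(adlib_intake_g = 7506.75, adlib_gain_g = 2194.75,
                     feed_price = 14, n_birds_commercial = 1000L)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

read_run_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file does not exist: ", path, call. = FALSE)
  merge_config(default_run_config(),
               jsonlite::read_json(path, simplifyVector = TRUE))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[fowlplan] %-10s %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Simulates (or loads) the daily-record and environmental tables, builds the
#' leakage-safe model matrices, trains the daily-weight and interval-feed
#' models for the configured breed, generates the closed-loop feeding
#' schedule, evaluates it economically against the ad libitum reference, and
#' writes a deterministic artifact tree (`data/`, `matrices/`, `models/`,
#' `schedule/`, `report/`) plus `manifest.json` recording inputs, seed,
#' config hash, package version and metrics. On any stage failure the partial
#' artifacts are retained next to a `FAILED` marker file.
#'
#' @param config Run configuration: a list (see [default_run_config()]) or a
#'   path to a JSON file.
#' @param out_dir Output directory (created; default `config$out_dir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  for (p in c("records", "env"))
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop("configured input path does not exist: ", config[[p]],
           call. = FALSE)
  dirs <- file.path(out_dir, c("data", "matrices", "models", "schedule",
                               "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  manifest <- list(seed = config$seed, config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("fowlplan")),
                   r_version = R.version.string, stages = list())

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(c(name, conditionMessage(e)), fail_marker)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    res
  }

  # --- simulate / load --------------------------------------------------
  dat <- run_stage("simulate", {
    if (!is.null(config$records)) {
      rec <- read_daily_records(config$records)
      env <- read_env_samples(config$env)
      stage_log("simulate", "loaded %d records, %d env samples",
                nrow(rec), nrow(env))
      list(records = rec, env = env)
    } else {
      sc <- config$simulate
      d <- gen_dataset(synthetic_config(n_batches = sc$n_batches,
                                        n_days = sc$n_days,
                                        breeds = sc$breeds,
                                        seed = config$seed))
      stage_log("simulate", "generated %d records, %d env samples",
                nrow(d$records), nrow(d$env))
      d
    }
  })
  write_daily_records(dat$records, file.path(out_dir, "data", "daily_records.csv"))
  write_env_samples(dat$env, file.path(out_dir, "data", "env_samples.csv"))

  # --- preprocess -------------------------------------------------------
  pp <- config$preprocess
  mats <- run_stage("preprocess", {
    wm <- build_weight_matrix(dat$records, dat$env,
                              weighing_hour = pp$weighing_hour)
    split <- temporal_split(wm)
    iv <- build_interval_examples(wm[split$train, , drop = FALSE],
                                  min_len = pp$interval_min_len,
                                  max_len = pp$interval_max_len,
                                  stride = pp$interval_stride)
    skipped <- attr(iv, "skipped")
    if (skipped > 0)
      warning("skipped ", skipped, " non-monotone interval pair(s)",
              call. = FALSE)
    stage_log("preprocess", "matrix %d rows (%d train / %d test), %d interval examples",
              nrow(wm), length(split$train), length(split$test), nrow(iv))
    list(wm = wm, split = split, iv = iv)
  })
  utils::write.csv(mats$wm, file.path(out_dir, "matrices", "weight_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(mats$iv, file.path(out_dir, "matrices", "interval_examples.csv"),
                   row.names = FALSE)

  # --- train ------------------------------------------------------------
  models <- run_stage("train", {
    wm_b <- mats$wm[mats$wm$breed == config$breed, , drop = FALSE]
    if (!nrow(wm_b))
      stop("no records for configured breed `", config$breed, "`")
    split_b <- temporal_split(wm_b)
    train_b <- wm_b[split_b$train, , drop = FALSE]
    test_b <- wm_b[split_b$test, , drop = FALSE]
    cfg_m <- preset_config(config$model, seed = config$seed)
    mw <- fit_weight_model(train_b, cfg_m)
    # in-sample metrics mirror the training-batch reporting convention;
    # the temporal test tail measures extrapolation, where depth-bounded
    # trees saturate by construction
    metrics_in <- evaluate(stats::predict(mw, train_b), train_b$y_g_per_bird)
    metrics <- evaluate(stats::predict(mw, test_b), test_b$y_g_per_bird)
    iv_b <- mats$iv[mats$iv$cage_id %in% wm_b$cage_id, , drop = FALSE]
    mf <- fit_feed_model(iv_b, cfg_m)
    stage_log("train", "%s weight model in-sample RMSE %.1f g (R2 %.4f), temporal-test RMSE %.1f g; feed model on %d pairs",
              config$model, metrics_in$RMSE, metrics_in$R2, metrics$RMSE,
              nrow(iv_b))
    list(mw = mw, mf = mf, metrics = metrics, metrics_in = metrics_in,
         train = train_b)
  })
  save_model(models$mw, file.path(out_dir, "models", "weight_model.json"))
  save_model(models$mf, file.path(out_dir, "models", "feed_model.json"))
  metrics_tab <- data.frame(breed = config$breed, model = config$model,
                            scope = c("in_sample", "temporal_test"),
                            MSE = c(models$metrics_in$MSE, models$metrics$MSE),
                            MAE = c(models$metrics_in$MAE, models$metrics$MAE),
                            RMSE = c(models$metrics_in$RMSE, models$metrics$RMSE),
                            R2 = c(models$metrics_in$R2, models$metrics$R2))
  utils::write.csv(metrics_tab, file.path(out_dir, "report", "metrics.csv"),
                   row.names = FALSE)

  # --- schedule ---------------------------------------------------------
  sc <- config$schedule
  sched <- run_stage("schedule", {
    spec <- interval_spec(sc$start_weight, sc$target_weight,
                          sc$target_day - sc$start_day)
    cfg_s <- schedule_config(tolerance = sc$tolerance, max_iter = sc$max_iter,
                             daily_min = sc$daily_min, daily_max = sc$daily_max,
                             max_rel_change = sc$max_rel_change)
    env_fc <- env_climatology(models$train, spec$d_remain)
    res <- run_schedule(spec, models$mf, models$mw, env_fc, cfg_s,
                        start_age = sc$start_day,
                        n_birds = dat$records$n_birds[1])
    stage_log("schedule", "%d iterations, terminal error %+.1f g, FCR %.2f",
              res$iterations, res$terminal_error, res$fcr)
    res
  })
  utils::write.csv(sched$plan, file.path(out_dir, "schedule", "ration_plan.csv"),
                   row.names = FALSE)

  # --- economics --------------------------------------------------------
  ec <- config$economics
  econ <- run_stage("economics", {
    contrast <- fcr_contrast(ec$adlib_intake_g, ec$adlib_gain_g,
                             sched$total, sc$target_weight - sc$start_weight)
    gain_kg <- (sc$target_weight - sc$start_weight) / 1000
    pb <- partial_budget(ec$n_birds_commercial, gain_kg,
                         contrast$fcr0_2dp, contrast$fcr1_2dp,
                         feed_price = ec$feed_price)
    stage_log("economics", "FCR %.2f vs %.2f ad lib; saving %s NTD at N=%d",
              contrast$fcr1_2dp, contrast$fcr0_2dp,
              format(pb$display$saving), ec$n_birds_commercial)
    list(contrast = unclass(contrast), partial_budget = unclass(pb))
  })

  manifest$inputs <- list(records = config$records, env = config$env,
                          simulated = is.null(config$records))
  manifest$metrics <- list(weight_model = unclass(models$metrics),
                           weight_model_in_sample = unclass(models$metrics_in),
                           schedule = list(iterations = sched$iterations,
                                           terminal_error = sched$terminal_error,
                                           converged = sched$converged,
                                           fcr = sched$fcr),
                           economics = econ)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommands: `simulate-data`, `preprocess`, `train`, `explain`,
#' `schedule`, `economics`, `run-all`. Invoke via the wrapper script in
#' `inst/cli/fowlplan.R` or `Rscript -e 'fowlplan::fowlplan_cli()'` followed
#' by arguments.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
fowlplan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fowlplan <subcommand> [options]",
    "subcommands: simulate-data preprocess train explain schedule economics run-all",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[1]; rest <- args[-1]
  status <- tryCatch({
    switch(sub,
      "simulate-data" = cli_simulate(rest),
      "preprocess" = cli_preprocess(rest),
      "train" = cli_train(rest),
      "explain" = cli_explain(rest),
      "schedule" = cli_schedule(rest),
      "economics" = cli_economics(rest),
      "run-all" = cli_run_all(rest),
      { message("unknown subcommand: ", sub, "\n", usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_parse <- function(option_list, args) {
  optparse::parse_args(optparse::OptionParser(option_list = option_list),
                       args = args)
}

cli_simulate <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = ".")), args)
  cfg <- if (is.null(o$config)) default_run_config(seed = o$seed)
         else read_run_config(o$config)
  cfg$seed <- o$seed
  sc <- cfg$simulate
  d <- gen_dataset(synthetic_config(n_batches = sc$n_batches,
                                    n_days = sc$n_days, breeds = sc$breeds,
                                    seed = o$seed))
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  write_daily_records(d$records, file.path(o$out, "daily_records.csv"))
  write_env_samples(d$env, file.path(o$out, "env_samples.csv"))
  stage_log("simulate", "wrote %d records and %d env samples to %s",
            nrow(d$records), nrow(d$env), o$out)
  0L
}

cli_preprocess <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--records", type = "character"),
    optparse::make_option("--env", type = "character"),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--weighing-time", type = "character",
                          default = "08:00", dest = "weighing_time")), args)
  rec <- read_daily_records(o$records)
  env <- read_env_samples(o$env)
  wm <- build_weight_matrix(rec, env, weighing_hour = o$weighing_time)
  iv <- build_interval_examples(wm)
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(wm, file.path(o$out, "weight_matrix.csv"), row.names = FALSE)
  utils::write.csv(iv, file.path(o$out, "interval_examples.csv"),
                   row.names = FALSE)
  stage_log("preprocess", "wrote %d matrix rows and %d interval examples",
            nrow(wm), nrow(iv))
  0L
}

cli_train <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--matrix", type = "character"),
    optparse::make_option("--model", type = "character", default = "et"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = ".")), args)
  wm <- utils::read.csv(o$matrix, stringsAsFactors = FALSE)
  split <- temporal_split(wm)
  mw <- fit_weight_model(wm[split$train, , drop = FALSE],
                         preset_config(o$model, seed = o$seed))
  m <- evaluate(stats::predict(mw, wm[split$test, , drop = FALSE]),
                wm$y_g_per_bird[split$test])
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  save_model(mw, file.path(o$out, "weight_model.json"))
  stage_log("train", "test RMSE %.1f g, R2 %.4f; model written", m$RMSE, m$R2)
  0L
}

cli_explain <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--matrix", type = "character"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--permutations", type = "integer", default = 100L),
    optparse::make_option("--out", type = "character", default = ".")), args)
  wm <- utils::read.csv(o$matrix, stringsAsFactors = FALSE)
  att <- env_only_attribution(wm, n_permutations = o$permutations,
                              seed = o$seed)
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(att$breed_balanced,
                   file.path(o$out, "env_attribution.csv"), row.names = FALSE)
  stage_log("explain", "top environmental feature: %s",
            att$breed_balanced$feature[1])
  0L
}

cli_schedule <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--model-weight", type = "character",
                          dest = "model_weight"),
    optparse::make_option("--model-feed", type = "character",
                          dest = "model_feed"),
    optparse::make_option("--env", type = "character"),
    optparse::make_option("--start-weight", type = "double",
                          dest = "start_weight", default = 785),
    optparse::make_option("--target-weight", type = "double",
                          dest = "target_weight", default = 2500),
    optparse::make_option("--start-day", type = "integer", dest = "start_day",
                          default = 46L),
    optparse::make_option("--target-day", type = "integer",
                          dest = "target_day", default = 100L),
    optparse::make_option("--out", type = "character", default = ".")), args)
  mw <- load_model(o$model_weight)
  mf <- load_model(o$model_feed)
  envh <- utils::read.csv(o$env, stringsAsFactors = FALSE)
  spec <- interval_spec(o$start_weight, o$target_weight,
                        o$target_day - o$start_day)
  res <- run_schedule(spec, mf, mw, env_climatology(envh, spec$d_remain),
                      start_age = o$start_day)
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$plan, file.path(o$out, "ration_plan.csv"),
                   row.names = FALSE)
  print(res)
  0L
}

cli_economics <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--fcr0", type = "double"),
    optparse::make_option("--fcr1", type = "double"),
    optparse::make_option("--gain-kg", type = "double", dest = "gain_kg"),
    optparse::make_option("--n", type = "integer", default = 1000L),
    optparse::make_option("--price", type = "double", default = 14)), args)
  pb <- partial_budget(o$n, o$gain_kg, o$fcr0, o$fcr1, feed_price = o$price)
  print(pb)
  0L
}

cli_run_all <- function(args) {
  o <- cli_parse(list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "fowlplan-run")),
    args)
  cfg <- if (is.null(o$config)) default_run_config(seed = o$seed)
         else read_run_config(o$config)
  cfg$seed <- o$seed
  run_pipeline(cfg, out_dir = o$out)
  0L
}
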