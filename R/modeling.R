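# Regressor contract for the daily body-weight model M_w and the interval
# total-feed model M_F, plus evaluation metrics, an impurity-reduction
# verification utility, and Monte-Carlo permutation Shapley attribution.

#' Regressor configuration
#'
#' Uniform configuration for the four supported learner families. Only the
#' parameters relevant to the named family are used.
#'
#' @param family One of `"random-forest"`, `"extra-trees"`,
#'   `"gradient-boosting"`, `"feedforward-net"`.
#' @param n_trees Ensemble size (tree families).
#' @param max_depth Maximum tree depth.
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param learning_rate Shrinkage (boosting) or Adam step size (net).
#' @param mtry Candidate features per split; `NULL` = all.
#' @param hidden_widths Hidden-layer widths (net).
#' @param l2 L2 weight penalty (net).
#' @param epochs,batch_size,patience,tol,validation_frac Net training control.
#' @param seed Integer seed; training is deterministic given it.
#' @return Object of class `fp_regressor_config`.
#' @export
regressor_config <- function(family = c("extra-trees", "random-forest",
                                        "gradient-boosting", "feedforward-net"),
                             n_trees = 300L, max_depth = 6L,
                             min_samples_split = 2L, learning_rate = 0.05,
                             mtry = NULL, hidden_widths = c(64L, 32L),
                             l2 = 0.001, epochs = 2000L, batch_size = 32L,
                             patience = 20L, tol = 1e-4,
                             validation_frac = 0.1, seed = 1L) {
  family <- match.arg(family)
  n_trees <- check_count(n_trees, "n_trees", min = 1L)
  max_depth <- check_count(max_depth, "max_depth", min = 1L)
  min_samples_split <- check_count(min_samples_split, "min_samples_split",
                                   min = 2L)
  check_scalar_number(learning_rate, "learning_rate", lower = 0,
                      strict_lower = TRUE)
  structure(list(family = family, n_trees = n_trees, max_depth = max_depth,
                 min_samples_split = min_samples_split,
                 learning_rate = learning_rate, mtry = mtry,
                 hidden_widths = as.integer(hidden_widths), l2 = l2,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patience = as.integer(patience), tol = tol,
                 validation_frac = validation_frac, seed = as.integer(seed)),
            class = "fp_regressor_config")
}

#' Named hyperparameter presets
#'
#' The tuned configurations used throughout: random forest 300 trees / depth
#' 6 / min split 5; gradient boosting 600 trees / depth 6 / learning rate
#' 0.05; extra trees 300 trees / depth 6 / min split 2; feedforward net with
#' 64-32 ReLU hidden layers, Adam at 0.001, L2 0.001, early-stopping
#' patience 20.
#'
#' @param name One of `"et"`, `"rf"`, `"gbm"`, `"ann"`.
#' @param seed Seed recorded in the config.
#' @return An [regressor_config()] object.
#' @export
preset_config <- function(name = c("et", "rf", "gbm", "ann"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    et  = regressor_config("extra-trees", n_trees = 300L, max_depth = 6L,
                           min_samples_split = 2L, seed = seed),
    rf  = regressor_config("random-forest", n_trees = 300L, max_depth = 6L,
                           min_samples_split = 5L, seed = seed),
    gbm = regressor_config("gradient-boosting", n_trees = 600L, max_depth = 6L,
                           learning_rate = 0.05, seed = seed),
    ann = regressor_config("feedforward-net", learning_rate = 0.001,
                           hidden_widths = c(64L, 32L), l2 = 0.001,
                           patience = 20L, seed = seed))
}

#' Train a regressor under the uniform contract
#'
#' @param config [regressor_config()] (or preset name via [preset_config()]).
#' @param X Feature matrix or data frame (rows = observations). Feature
#'   columns must be numeric and complete; scale/impute upstream with
#'   [apply_transform()].
#' @param y Numeric response, `length(y) == nrow(X)`, at least 2 rows.
#' @return A fitted model handle of class `fp_regressor` supporting
#'   [predict()] on rows with the same named features.
#' @export
train_regressor <- function(config, X, y) {
  stopifnot(inherits(config, "fp_regressor_config"))
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("X rows and y length differ", call. = FALSE)
  if (nrow(X) < 2L)
    stop("need at least 2 training rows", call. = FALSE)
  if (anyNA(X) || anyNA(y))
    stop("training data contain missing values after preprocessing",
         call. = FALSE)
  switch(config$family,
    "random-forest" = ,
    "extra-trees" = fit_forest(X, y, config),
    "gradient-boosting" = fit_gbm(X, y, config),
    "feedforward-net" = fit_mlp(X, y, config))
}

#' Regression evaluation metrics
#'
#' Mean squared error, mean absolute error, root mean squared error, and the
#' coefficient of determination `R2 = 1 - SS_res / SS_tot`. With
#' zero-variance observations `R2` is undefined and reported as `NA` with a
#' warning.
#'
#' @param predictions,observations Equal-length numeric vectors, length >= 2.
#' @return Object of class `fp_metrics`: list `MSE`, `MAE`, `RMSE`, `R2`.
#' @export
evaluate <- function(predictions, observations) {
  if (length(predictions) != length(observations) || length(observations) < 2L)
    stop("predictions and observations must have equal length >= 2",
         call. = FALSE)
  err <- predictions - observations
  mse <- mean(err^2)
  ss_tot <- sum((observations - mean(observations))^2)
  r2 <- if (ss_tot == 0) {
    warning("observations have zero variance; R2 is undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  structure(list(MSE = mse, MAE = mean(abs(err)), RMSE = sqrt(mse), R2 = r2),
            class = "fp_metrics")
}

#' @export
print.fp_metrics <- function(x, ...) {
  cat(sprintf("MSE %.2f g^2 | MAE %.2f g | RMSE %.2f g | R2 %s\n",
              x$MSE, x$MAE, x$RMSE,
              if (is.na(x$R2)) "NA" else sprintf("%.4f", x$R2)))
  invisible(x)
}

#' Impurity reduction of a candidate split
#'
#' Verification utility for tree splits: with within-node variance
#' `I(D) = mean((y - mean(y))^2)`, the reduction of a split of parent
#' responses `parent` into child partitions `children` is
#' `I(D) - sum(|D_i|/|D| * I(D_i))`, which is non-negative.
#'
#' @param parent Numeric responses at the parent node.
#' @param children List of numeric vectors that partition `parent` (as a
#'   multiset).
#' @return The impurity reduction (variance units).
#' @export
#' @examples
#' impurity_reduction(c(0, 0, 10, 10), list(c(0, 0), c(10, 10)))  # 25
impurity_reduction <- function(parent, children) {
  pooled <- unlist(children, use.names = FALSE)
  if (length(pooled) != length(parent) ||
      !isTRUE(all.equal(sort(pooled), sort(parent))))
    stop("children do not partition the parent responses", call. = FALSE)
  node_var <- function(v) mean((v - mean(v))^2)
  n <- length(parent)
  impurity_children <- vapply(children, function(v)
    length(v) / n * node_var(v), numeric(1))
  node_var(parent) - sum(impurity_children)
}

#' Monte-Carlo permutation Shapley attribution
#'
#' Estimates per-feature Shapley values for each row of `X_explain` by
#' sampling feature permutations. The value function is the interventional
#' expectation: features outside the growing prefix are replaced by the
#' background rows and the model prediction is averaged over the whole
#' background set, so the only Monte-Carlo error is over permutations. Per
#' permutation the contributions telescope, so local accuracy (contributions
#' sum to prediction minus mean background prediction) holds exactly.
#'
#' @param model Fitted `fp_regressor` (or any object with a `predict`
#'   method), or a function `f(data.frame) -> numeric`.
#' @param X_background Data frame/matrix of background rows (non-empty).
#' @param X_explain Rows to attribute.
#' @param n_permutations Permutations sampled per explained row, >= 1.
#' @param seed Integer seed; estimates are deterministic given it.
#' @return List of class `fp_attribution`: `values` (matrix rows x features),
#'   `baseline` (mean background prediction), and `summary` (data frame
#'   `feature`, `mean_abs_shap`, `iqr`, ranked by descending mean absolute
#'   value; IQR is across explained rows of the absolute values).
#' @export
mc_shapley <- function(model, X_background, X_explain, n_permutations = 200L,
                       seed = 1L) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  f <- if (is.function(model)) model else
    function(d) stats::predict(model, d)
  bg <- as.data.frame(X_background)
  if (!nrow(bg)) stop("background set is empty", call. = FALSE)
  xe <- as.data.frame(X_explain)
  p <- ncol(bg)
  feats <- names(bg)
  baseline <- mean(f(bg))

  values <- matrix(0, nrow(xe), p, dimnames = list(NULL, feats))
  nb <- nrow(bg)
  stacked <- bg[rep(seq_len(nb), p), , drop = FALSE]  # stage l = rows block l
  with_seed(seed, {
    for (i in seq_len(nrow(xe))) {
      phi <- numeric(p)
      for (r in seq_len(n_permutations)) {
        perm <- sample.int(p)
        cur <- stacked
        for (l in seq_len(p)) {
          rows <- seq.int((l - 1L) * nb + 1L, p * nb)
          cur[[perm[l]]][rows] <- xe[[perm[l]]][i]
        }
        v <- colMeans(matrix(f(cur), nb, p))
        phi[perm] <- phi[perm] + diff(c(baseline, v))
      }
      values[i, ] <- phi / n_permutations
    }
  })
  absv <- abs(values)
  summ <- data.frame(feature = feats,
                     mean_abs_shap = colMeans(absv),
                     iqr = apply(absv, 2, stats::IQR))
  summ <- summ[order(-summ$mean_abs_shap), ]
  rownames(summ) <- NULL
  structure(list(values = values, baseline = baseline, summary = summ),
            class = "fp_attribution")
}

#' Environmental-only attribution
#'
#' Fits an extra-trees model per breed on the 5 environmental features only
#' (mean temperature, mean RH, CO/H2S/NH3 daily maxima) and attributes its
#' predictions with [mc_shapley()], giving a unified cross-breed comparison
#' of environmental associations with body weight.
#'
#' @param wm Weight model matrix from [build_weight_matrix()].
#' @param n_permutations,seed Passed to [mc_shapley()].
#' @param n_explain Rows attributed per breed (subsampled for speed).
#' @return Named list (per breed) of `fp_attribution` objects, plus a
#'   `breed_balanced` summary data frame averaging the per-breed summaries.
#' @export
env_only_attribution <- function(wm, n_permutations = 100L, seed = 1L,
                                 n_explain = 25L) {
  env_feats <- c("temp_mean_c", "rh_mean_pct", "co_max_ppm", "h2s_max_ppm",
                 "nh3_max_ppm")
  out <- list()
  for (breed in unique(wm$breed)) {
    d <- wm[wm$breed == breed, , drop = FALSE]
    d <- d[stats::complete.cases(d[env_feats]), , drop = FALSE]
    st <- fit_transform_state(d, numeric_features = env_feats)
    Z <- apply_transform(d, st)[env_feats]
    model <- train_regressor(preset_config("et", seed = derive_seed(seed, breed)),
                             Z, d$y_g_per_bird)
    keep <- if (nrow(Z) > n_explain)
      with_seed(derive_seed(seed, breed, "rows"),
                sort(sample.int(nrow(Z), n_explain)))
    else seq_len(nrow(Z))
    out[[breed]] <- mc_shapley(model, Z, Z[keep, , drop = FALSE],
                               n_permutations = n_permutations,
                               seed = derive_seed(seed, breed, "shap"))
  }
  summaries <- lapply(out, function(a) {
    s <- a$summary[order(a$summary$feature), ]
    s
  })
  bal <- summaries[[1]]
  if (length(summaries) > 1L) {
    bal$mean_abs_shap <- rowMeans(sapply(summaries, `[[`, "mean_abs_shap"))
    bal$iqr <- rowMeans(sapply(summaries, `[[`, "iqr"))
  }
  bal <- bal[order(-bal$mean_abs_shap), ]
  rownames(bal) <- NULL
  c(out, list(breed_balanced = bal))
}

# Pipelines -------------------------------------------------------------------

#' Fit an end-to-end prediction pipeline (transform + regressor)
#'
#' Bundles a train-only [fit_transform_state()] with a fitted regressor so
#' prediction accepts raw-scale feature rows. `fit_weight_model` targets the
#' per-bird daily weight from the 7 canonical features; `fit_feed_model`
#' targets interval total feed from (start weight, target weight, remaining
#' days).
#'
#' @param train Training rows: weight model matrix ([build_weight_matrix()])
#'   or interval examples ([build_interval_examples()]).
#' @param config [regressor_config()]; default extra-trees preset.
#' @return Object of class `fp_pipeline` with a `predict` method on raw rows.
#' @export
fit_weight_model <- function(train, config = preset_config("et")) {
  fit_pipeline(train, weight_feature_names(), "y_g_per_bird", config)
}

#' @rdname fit_weight_model
#' @export
fit_feed_model <- function(train, config = preset_config("et")) {
  fit_pipeline(train, feed_feature_names(), "total_feed_g", config)
}

fit_pipeline <- function(train, features, target, config) {
  missing_cols <- setdiff(c(features, target), names(train))
  if (length(missing_cols))
    stop("training table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- is.finite(train[[target]])
  train <- train[keep, , drop = FALSE]
  state <- fit_transform_state(train, numeric_features = features)
  Z <- apply_transform(train, state)[features]
  model <- train_regressor(config, Z, train[[target]])
  structure(list(state = state, model = model, features = features,
                 target = target, config = config),
            class = "fp_pipeline")
}

#' @export
predict.fp_pipeline <- function(object, newdata, ...) {
  Z <- apply_transform(as.data.frame(newdata), object$state)
  stats::predict(object$model, Z[object$features])
}

# Serialization ---------------------------------------------------------------

#' Save / load a fitted model as a versioned JSON artifact
#'
#' Tree ensembles are flattened to arrays and net weights to matrices; the
#' config and seed that produced the model are recorded so an artifact is
#' self-describing. Pipelines (transform + model) round-trip too.
#'
#' @param object Fitted `fp_regressor` or `fp_pipeline`.
#' @param path Output path (`.json`).
#' @return `load_model` returns the restored object; `save_model` returns
#'   `path` invisibly.
#' @export
save_model <- function(object, path) {
  payload <- serialize_obj(object)
  payload$format_version <- 1L
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

serialize_obj <- function(object) {
  if (inherits(object, "fp_pipeline")) {
    return(list(kind = "pipeline",
                state = unclass(object$state),
                features = object$features, target = object$target,
                config = unclass(object$config),
                model = serialize_obj(object$model)))
  }
  if (inherits(object, "fp_mlp")) {
    return(list(kind = "mlp", W = object$W, b = object$b,
                sizes = object$sizes, x_mu = object$x_mu, x_sd = object$x_sd,
                y_mu = object$y_mu, y_sd = object$y_sd,
                features = object$features, config = unclass(object$config)))
  }
  stopifnot(inherits(object, "fp_regressor"))
  list(kind = if (inherits(object, "fp_gbm")) "gbm" else "forest",
       init = object$init, trees = object$trees,
       features = object$features, config = unclass(object$config))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  deserialize_obj(payload)
}

deserialize_obj <- function(payload) {
  cfg <- function(x) structure(x, class = "fp_regressor_config")
  fix_trees <- function(trees) {
    if (is.data.frame(trees)) trees <- split(trees, seq_len(nrow(trees)))
    lapply(trees, function(tr)
      list(feature = as.integer(unlist(tr$feature)),
           threshold = as.numeric(unlist(tr$threshold)),
           left = as.integer(unlist(tr$left)),
           right = as.integer(unlist(tr$right)),
           value = as.numeric(unlist(tr$value))))
  }
  switch(payload$kind,
    pipeline = structure(list(
      state = structure(payload$state, class = "fp_transform_state"),
      model = deserialize_obj(payload$model),
      features = payload$features, target = payload$target,
      config = cfg(payload$config)), class = "fp_pipeline"),
    mlp = structure(list(
      W = lapply(payload$W, as.matrix), b = lapply(payload$b, as.numeric),
      sizes = payload$sizes, x_mu = payload$x_mu, x_sd = payload$x_sd,
      y_mu = payload$y_mu, y_sd = payload$y_sd, features = payload$features,
      config = cfg(payload$config)), class = c("fp_mlp", "fp_regressor")),
    gbm = structure(list(
      init = payload$init, trees = fix_trees(payload$trees),
      features = payload$features, config = cfg(payload$config)),
      class = c("fp_gbm", "fp_regressor")),
    forest = structure(list(
      trees = fix_trees(payload$trees), features = payload$features,
      config = cfg(payload$config)),
      class = c("fp_forest", "fp_regressor")),
    stop("unknown model artifact kind: ", payload$kind, call. = FALSE))
}
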