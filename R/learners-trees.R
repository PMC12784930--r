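# Regression-tree learners backing the regressor contract.
#
# CART-style variance-reduction trees with three ensemble modes:
#   * random-forest: bootstrap resampling, exhaustive best-split search
#   * extra-trees: full sample, one uniform random threshold per candidate
#     feature (fully randomized thresholds)
#   * gradient-boosting: stagewise trees fit to residuals with shrinkage
# Trees are stored as parallel arrays (feature, threshold, left, right, value)
# and predictions use a vectorized level-by-level descent, so no compiled code
# is needed at this data scale (hundreds to a few thousand rows).

# Grow one regression tree on rows `idx`. Returns parallel-array node table.
# `randomized = TRUE` draws one uniform threshold per candidate feature
# instead of searching all split points.
grow_tree <- function(X, y, idx, max_depth, min_split, mtry,
                      randomized = FALSE) {
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); value <- numeric(0)

  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    value[length(value) + 1L] <<- NA_real_
    length(feature)
  }

  best_split <- function(rows) {
    yr <- y[rows]; n <- length(yr)
    cand <- if (mtry >= ncol(X)) seq_len(ncol(X)) else
      sample.int(ncol(X), mtry)
    best <- NULL; best_sse <- Inf
    for (j in cand) {
      x <- X[rows, j]
      lo <- min(x); hi <- max(x)
      if (lo == hi) next
      if (randomized) {
        thr <- stats::runif(1, lo, hi)
        lmask <- x <= thr
        nl <- sum(lmask)
        if (nl == 0L || nl == n) next
        yl <- yr[lmask]; yrr <- yr[!lmask]
        sse <- sum(yl^2) - sum(yl)^2 / nl +
          sum(yrr^2) - sum(yrr)^2 / (n - nl)
        if (sse < best_sse) { best_sse <- sse; best <- list(j = j, thr = thr) }
      } else {
        ord <- order(x, method = "radix")
        xs <- x[ord]; ys <- yr[ord]
        cs <- cumsum(ys); cs2 <- cumsum(ys^2)
        i <- seq_len(n - 1L)
        valid <- xs[i] < xs[i + 1L]
        if (!any(valid)) next
        sse_l <- cs2[i] - cs[i]^2 / i
        sse_r <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
        tot <- sse_l + sse_r
        tot[!valid] <- Inf
        pos <- which.min(tot)
        if (tot[pos] < best_sse) {
          best_sse <- tot[pos]
          best <- list(j = j, thr = (xs[pos] + xs[pos + 1L]) / 2)
        }
      }
    }
    best
  }

  build <- function(rows, depth) {
    id <- new_node()
    yr <- y[rows]
    if (depth >= max_depth || length(rows) < min_split ||
        length(rows) < 2L || stats::var(yr) == 0) {
      value[id] <<- mean(yr)
      return(id)
    }
    sp <- best_split(rows)
    if (is.null(sp)) {
      value[id] <<- mean(yr)
      return(id)
    }
    lmask <- X[rows, sp$j] <= sp$thr
    l_id <- build(rows[lmask], depth + 1L)
    r_id <- build(rows[!lmask], depth + 1L)
    feature[id] <<- sp$j
    threshold[id] <<- sp$thr
    left[id] <<- l_id
    right[id] <<- r_id
    id
  }

  build(idx, 0L)
  list(feature = feature, threshold = threshold, left = left, right = right,
       value = value)
}

# Vectorized prediction for one parallel-array tree.
predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    f <- tree$feature[node]
    act <- which(!is.na(f))
    if (!length(act)) break
    xv <- X[cbind(act, f[act])]
    goleft <- xv <= tree$threshold[node[act]]
    node[act] <- ifelse(goleft, tree$left[node[act]], tree$right[node[act]])
  }
  tree$value[node]
}

fit_forest <- function(X, y, config) {
  n <- nrow(X)
  mtry <- if (is.null(config$mtry)) ncol(X) else min(config$mtry, ncol(X))
  bootstrap <- config$family == "random-forest"
  randomized <- config$family == "extra-trees"
  trees <- with_seed(config$seed, {
    lapply(seq_len(config$n_trees), function(m) {
      rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      grow_tree(X, y, rows, config$max_depth, config$min_samples_split,
                mtry, randomized = randomized)
    })
  })
  structure(list(trees = trees, config = config, features = colnames(X)),
            class = c("fp_forest", "fp_regressor"))
}

fit_gbm <- function(X, y, config) {
  n <- nrow(X)
  mtry <- if (is.null(config$mtry)) ncol(X) else min(config$mtry, ncol(X))
  init <- mean(y)
  pred <- rep(init, n)
  trees <- vector("list", config$n_trees)
  with_seed(config$seed, {
    for (t in seq_len(config$n_trees)) {
      tr <- grow_tree(X, y - pred, seq_len(n), config$max_depth,
                      config$min_samples_split, mtry)
      trees[[t]] <- tr
      pred <- pred + config$learning_rate * predict_tree(tr, X)
    }
  })
  structure(list(init = init, trees = trees, config = config,
                 features = colnames(X)),
            class = c("fp_gbm", "fp_regressor"))
}

#' @export
predict.fp_forest <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$features)
  acc <- numeric(nrow(X))
  for (tr in object$trees) acc <- acc + predict_tree(tr, X)
  acc / length(object$trees)
}

#' @export
predict.fp_gbm <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$features)
  acc <- rep(object$init, nrow(X))
  for (tr in object$trees)
    acc <- acc + object$config$learning_rate * predict_tree(tr, X)
  acc
}

# Coerce a data frame / matrix to the feature matrix the model was trained on.
as_feature_matrix <- function(newdata, features) {
  X <- as.matrix(as.data.frame(newdata)[, features, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop("prediction input contains missing values; impute before predicting",
         call. = FALSE)
  X
}
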