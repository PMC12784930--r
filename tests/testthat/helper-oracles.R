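# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by brute force / closed form,
# independent of the package's implementation paths.

# Exhaustive Shapley values by subset enumeration. Value function is the
# interventional expectation over the full background set (same convention
# as mc_shapley). Exponential in p; for p <= 4 only.
exact_shapley <- function(f, bg, x_row) {
  p <- ncol(bg)
  stopifnot(p <= 4L)
  vcache <- numeric(2^p)
  subset_value <- function(mask) {
    cur <- bg
    for (j in seq_len(p)) if (bitwAnd(mask, bitwShiftL(1L, j - 1L)))
      cur[[j]] <- x_row[[j]]
    mean(f(cur))
  }
  for (mask in 0:(2^p - 1)) vcache[mask + 1L] <- subset_value(mask)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^p - 1)) {
      if (bitwAnd(mask, bit_j)) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + w * (vcache[mask + bit_j + 1L] - vcache[mask + 1L])
    }
  }
  names(phi) <- names(bg)
  phi
}

# Feasibility scan for a ration plan against a schedule config.
plan_feasible <- function(f, cfg, tol = 1e-6) {
  n <- length(f)
  all(f >= cfg$daily_min - tol * sum(f)) &&
    all(f <= cfg$daily_max + tol * sum(f)) &&
    (n == 1L || all(abs(f[-1] / f[-n] - 1) <= cfg$max_rel_change + tol))
}

# Stub daily-weight model: weight = anchor + rate * cumulative feed.
# With gain clipping disabled the terminal weight is anchor + rate * total.
stub_weight_model <- function(anchor, rate) {
  force(anchor); force(rate)
  function(d) anchor + rate * cumsum(d$feed_per_bird_g)
}

# Constant environmental forecast rows.
const_env <- function(n, temp = 26, rh = 70, co = 0.1, h2s = 1, nh3 = 2) {
  data.frame(temp_mean_c = temp, rh_mean_pct = rh, co_max_ppm = co,
             h2s_max_ppm = h2s, nh3_max_ppm = nh3)[rep(1L, n), , drop = FALSE]
}

# Noiseless Gompertz feature/target fixture for learner recovery tests.
gompertz_fixture <- function(n, seed = 42,
                             params = growth_params(2600, 4.2, 0.036)) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    age <- sample(0:76, n, replace = TRUE)
    X <- data.frame(age_days = age,
                    temp_mean_c = runif(n, 22, 30),
                    rh_mean_pct = runif(n, 60, 80),
                    feed_per_bird_g = runif(n, 50, 150),
                    co_max_ppm = runif(n, 0.02, 0.8),
                    h2s_max_ppm = runif(n, 0.2, 4.5),
                    nh3_max_ppm = runif(n, 0.3, 4.0))
    list(X = X, y = gompertz_weight(age, params))
  })
}

# Tiny daily-record/env tables with explicit batch structure, for split and
# CV tests (dates consecutive within batch).
batch_records <- function(sizes, start = as.Date("2024-11-05")) {
  do.call(rbind, lapply(seq_along(sizes), function(b) {
    data.frame(date = format(start + seq_len(sizes[b]) - 1L),
               batch_id = sprintf("B%02d", b),
               value = seq_len(sizes[b]))
  }))
}
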