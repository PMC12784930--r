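#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit. All randomness inside the package
#' flows through this helper so that every operation is deterministic given
#' its `seed` argument and never disturbs the user's RNG stream.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Deterministic splitting of one user-facing seed into independent
#' sub-streams (one per batch, per tree, per repeat, ...). Kept below 2^31
#' so the result is always a valid R integer seed.
#'
#' @param seed Parent integer seed.
#' @param ... Integer or character stream labels.
#' @return Integer scalar.
#' @keywords internal
derive_seed <- function(seed, ...) {
  labels <- c(...)
  h <- as.double(seed) %% 2147483647
  for (lab in labels) {
    bytes <- utf8ToInt(as.character(lab))
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Shared argument checks ------------------------------------------------------

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %s (got %s)", name, lower, x), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %s (got %s)", name, lower, x), call. = FALSE)
  if (x > upper)
    stop(sprintf("`%s` must be <= %s (got %s)", name, upper, x), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, lower = min)
  if (x != as.integer(x))
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  invisible(as.integer(x))
}

#' Parse an ISO-8601 date, failing loudly
#' @keywords internal
parse_iso_date <- function(x, name = "date") {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d))
    stop(sprintf("`%s` contains values not parseable as ISO-8601 dates: %s",
                 name, paste(utils::head(x[is.na(d)], 3L), collapse = ", ")),
         call. = FALSE)
  d
}
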