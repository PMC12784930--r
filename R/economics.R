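# Partial-budget economics: feed savings implied by an FCR improvement and
# their monetary value, plus the FCR contrast between two feeding regimens.

#' Partial-budget feed savings from an FCR improvement
#'
#' With `delta_fcr = fcr0 - fcr1` the feed saved per batch is
#' `delta_feed = delta_fcr * gain_kg * n_birds` (kg) and its monetary value
#' `saving = delta_feed * feed_price` (currency). Results are computed at
#' full precision; `display` applies the reporting convention (feed to 2
#' decimals; money to 1 decimal below 1000, integer part at or above 1000).
#'
#' @param n_birds Birds per batch, >= 1.
#' @param gain_kg Live-weight gain per bird over the interval, kg, > 0.
#' @param fcr0,fcr1 Baseline and improved feed conversion ratios.
#' @param feed_price Feed price per kg (default 14, NTD).
#' @param currency Currency label (default `"NTD"`).
#' @return Object of class `fp_econ`: `delta_fcr`, `delta_feed_kg`,
#'   `saving`, and a `display` list with the rounded presentation values.
#' @export
#' @examples
#' partial_budget(n_birds = 4, gain_kg = 1.705, fcr0 = 3.42, fcr1 = 3.27)
partial_budget <- function(n_birds, gain_kg, fcr0, fcr1, feed_price = 14,
                           currency = "NTD") {
  n_birds <- check_count(n_birds, "n_birds", min = 1L)
  check_scalar_number(gain_kg, "gain_kg", lower = 0, strict_lower = TRUE)
  check_scalar_number(feed_price, "feed_price", lower = 0)
  delta_fcr <- fcr0 - fcr1
  delta_feed <- delta_fcr * gain_kg * n_birds
  saving <- delta_feed * feed_price
  structure(list(
    n_birds = n_birds, gain_kg = gain_kg, fcr0 = fcr0, fcr1 = fcr1,
    feed_price = feed_price, currency = currency,
    delta_fcr = delta_fcr, delta_feed_kg = delta_feed, saving = saving,
    display = list(
      delta_feed_kg = round(delta_feed, 2),
      saving = if (abs(saving) >= 1000) trunc(saving) else round(saving, 1))),
    class = "fp_econ")
}

#' @export
print.fp_econ <- function(x, ...) {
  cat(sprintf(
    "partial budget (N = %d birds, gain %.3f kg/bird, feed %.2f %s/kg)\n  dFCR = %.4f -> feed saved %.2f kg, worth %s %s\n",
    x$n_birds, x$gain_kg, x$feed_price, x$currency, x$delta_fcr,
    x$display$delta_feed_kg, format(x$display$saving), x$currency))
  invisible(x)
}

#' FCR contrast between two feeding regimens
#'
#' Computes each regimen's FCR (total intake / gain) and the relative
#' reduction. The headline `reduction_pct` follows the field's reporting
#' convention of contrasting the 2-decimal FCRs
#' (`100 * (round(FCR0) - round(FCR1)) / round(FCR0)`); the full-precision
#' reduction is stored alongside as `reduction_pct_full`.
#'
#' @param intake0,gain0 Baseline (e.g. ad libitum) per-bird total intake and
#'   weight gain over its interval, g.
#' @param intake1,gain1 Comparison (scheduled) intake and gain, g.
#' @return List of class `fp_fcr_contrast`: `fcr0`, `fcr1` (full precision),
#'   `fcr0_2dp`, `fcr1_2dp`, `reduction_pct` (2-decimal display, rounded-FCR
#'   convention) and `reduction_pct_full`.
#' @export
#' @examples
#' fcr_contrast(7506.75, 2194.75, 5578.08, 1705)  # 3.42 vs 3.27, -4.39%
fcr_contrast <- function(intake0, gain0, intake1, gain1) {
  check_scalar_number(gain0, "gain0", lower = 0, strict_lower = TRUE)
  check_scalar_number(gain1, "gain1", lower = 0, strict_lower = TRUE)
  fcr0 <- intake0 / gain0
  fcr1 <- intake1 / gain1
  f0r <- round(fcr0, 2); f1r <- round(fcr1, 2)
  structure(list(
    fcr0 = fcr0, fcr1 = fcr1, fcr0_2dp = f0r, fcr1_2dp = f1r,
    reduction_pct = round(100 * (f0r - f1r) / f0r, 2),
    reduction_pct_full = 100 * (fcr0 - fcr1) / fcr0),
    class = "fp_fcr_contrast")
}

#' @export
print.fp_fcr_contrast <- function(x, ...) {
  cat(sprintf("FCR %.2f -> %.2f (relative reduction %.2f%%)\n",
              x$fcr0_2dp, x$fcr1_2dp, x$reduction_pct))
  invisible(x)
}
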