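# Fruit-value pricing: ripeness and minimum-weight gates, dry-matter
# interpolation between a low and a high price curve, flat above the
# fresh-weight cap; plus calibration of the cap prices from published
# end-of-trial summaries.

#' Value of a pot of dwarf tomato at harvest
#'
#' Implements the trial's piecewise price rules. A pot is unsellable
#' (price 0) when fewer than `ripeness_min` of the fruits are red or the
#' ripe fresh weight is below `ffw_min` g. Otherwise the price at the
#' fresh-weight cap interpolates linearly on the dry-matter percentage
#' between the low-curve price (at `dmp <= dm_low`) and the high-curve
#' price (at `dmp >= dm_high`); fresh weight beyond `ffw_cap` earns no
#' additional value, and below the cap the price scales with
#' `ffw / ffw_cap`. Ripeness fractions slightly above 1 (different plants
#' measured for red and total weight) are clamped for gating.
#'
#' @param ffw ripe (red) fruit fresh weight, g/pot, non-negative.
#' @param dmp fruit dry-matter percentage (e.g. 6.8 for 6.8%).
#' @param rfp ripeness fraction, red over total fresh weight.
#' @param model a [price_model()].
#' @return EUR per pot; vectorized over the first three arguments.
#' @export
pot_price <- function(ffw, dmp, rfp, model = price_model()) {
  if (any(ffw < 0) || any(dmp < 0) || any(rfp < 0)) {
    stop("ffw, dmp and rfp must be non-negative")
  }
  w <- pmin(pmax((dmp - model$dm_low) / (model$dm_high - model$dm_low), 0), 1)
  cap_price <- model$price_low_at_cap + w * (model$price_high_at_cap - model$price_low_at_cap)
  p <- cap_price * pmin(ffw, model$ffw_cap) / model$ffw_cap
  unsellable <- pmin(rfp, 1) < model$ripeness_min | ffw < model$ffw_min
  p[unsellable] <- 0
  p
}

#' Gains per pot at harvest
#'
#' The pot's price minus the plant cost (seed, pot, substrate,
#' propagation), optionally minus a penalty per manual intervention when
#' the cost book enables it (robustness is normally judged separately from
#' profitability, so the penalty is off by default).
#'
#' @param price EUR/pot from [pot_price()], non-negative.
#' @param book a [cost_book()].
#' @param interventions number of manual interventions during the trial.
#' @return EUR/pot (can be negative).
#' @export
gains_per_pot <- function(price, book = cost_book(), interventions = 0L) {
  if (any(price < 0)) stop("price must be non-negative")
  g <- price - book$plant_cost
  if (isTRUE(book$intervention_penalty_enabled)) {
    g <- g - interventions * book$intervention_penalty
  }
  g
}

#' Calibrate the price-curve cap values from observed gains
#'
#' The numeric endpoints of the low and high price curves are not published;
#' they can be recovered from a results table in which every strategy
#' exceeded the fresh-weight cap, so each observed gain satisfies
#' `gains + plant_cost = low + w(dmp) * (high - low)` with
#' `w = clamp((dmp - dm_low)/(dm_high - dm_low), 0, 1)`. The two cap prices
#' are the least-squares solution of that linear system.
#'
#' @param results `data.frame` with columns `gains` (EUR/pot), `dmp`
#'   (percent) and `ffw` (g/pot); all `ffw` must be at or above the cap.
#' @param model a [price_model()] supplying the gates and dry-matter knots.
#' @param plant_cost EUR/pot added back to gains to recover prices.
#' @return list with `price_low_at_cap`, `price_high_at_cap`,
#'   `max_residual` (largest absolute gains misfit, EUR) and `model`, a
#'   [price_model()] with the fitted caps installed.
#' @export
calibrate_price_caps <- function(results, model = price_model(), plant_cost = 0.75) {
  results <- as.data.frame(results)
  stopifnot(all(c("gains", "dmp", "ffw") %in% names(results)))
  if (any(results$ffw < model$ffw_cap)) {
    stop("calibration requires every row at or above the fresh-weight cap")
  }
  w <- pmin(pmax((results$dmp - model$dm_low) / (model$dm_high - model$dm_low), 0), 1)
  x <- cbind(low = 1 - w, high = w)
  if (qr(x)$rank < 2L) {
    stop("cap prices are underdetermined: need rows on both sides of dm_low")
  }
  y <- results$gains + plant_cost
  fit <- qr.solve(x, y)
  resid <- y - as.numeric(x %*% fit)
  cal <- model
  cal$price_low_at_cap <- unname(fit["low"])
  cal$price_high_at_cap <- unname(fit["high"])
  list(price_low_at_cap = cal$price_low_at_cap,
       price_high_at_cap = cal$price_high_at_cap,
       max_residual = max(abs(resid)),
       model = cal)
}
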