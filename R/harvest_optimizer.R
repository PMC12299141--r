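# Retrospective optimal-harvest-date search: linearly interpolate the
# sparse destructive crop measurements to daily resolution, then scan every
# candidate day for the net profit a harvest on that day would have earned,
# holding dry matter and the realized cultivation strategy fixed.

#' Interpolate sparse crop observations to daily resolution
#'
#' Piecewise-linear interpolation of the quantities that determine the
#' gains — red fruit fresh weight and ripeness fraction — at every integer
#' day between the first and last observation. No extrapolation: asking for
#' days outside the observed window is an error.
#'
#' @param obs a [crop_observations()] with at least two records.
#' @param days integer days to evaluate; defaults to every day in the
#'   observed window.
#' @return `data.frame(day, red_ffw, red_fruit_fraction)`.
#' @export
interpolate_observations <- function(obs, days = NULL) {
  if (nrow(obs) < 2L) stop("need at least two observations to interpolate")
  lo <- obs$day[1]; hi <- obs$day[nrow(obs)]
  if (is.null(days)) days <- seq.int(lo, hi)
  if (any(days < lo | days > hi)) {
    stop(sprintf("cannot extrapolate outside the observed window [%d, %d]", lo, hi))
  }
  data.frame(
    day = as.integer(days),
    red_ffw = stats::approx(obs$day, obs$red_ffw, xout = days)$y,
    red_fruit_fraction = stats::approx(obs$day, obs$red_fruit_fraction, xout = days)$y
  )
}

#' Retrospective profit-maximizing harvest day
#'
#' Exhaustively scans every candidate harvest day `D'` in the observed
#' window (bounded above by the actual harvest day): gains on day `D'` come
#' from pricing the interpolated red fresh weight and ripeness at the
#' final observed dry-matter percentage, and the net profit is the
#' objective truncated at `D'` — costs after an earlier harvest are simply
#' not incurred, and the realized spacing-change count keeps its charge.
#' Ties go to the earliest day (shorter cycles allow more cycles per
#' year).
#'
#' @param obs a [crop_observations()] covering the window of interest.
#' @param daily_costs per-day total costs `F + Vd` in EUR/m2/day: a numeric
#'   vector indexed by day, or a ledger from [daily_cost_ledger()].
#' @param schedule the realized [density_schedule()].
#' @param book a [cost_book()].
#' @param model a [price_model()].
#' @param dmp dry-matter percentage held fixed over the scan; defaults to
#'   the last observation's value.
#' @param actual_day the realized harvest day; defaults to the last
#'   observation day.
#' @return list with `optimal_day`, `profit_optimal`, `actual_day`,
#'   `profit_actual`, `days_earlier`, `delta` (EUR/m2/day gained) and
#'   `scan`, the per-candidate `data.frame(day, gains, net_profit)`.
#'   A warning is raised when no candidate day clears the ripeness or
#'   weight gates (all prices zero: the maximum of uniformly negative
#'   profits is still reported).
#' @export
optimal_harvest_day <- function(obs, daily_costs, schedule,
                                book = cost_book(), model = price_model(),
                                dmp = NULL, actual_day = NULL) {
  if (is.data.frame(daily_costs)) daily_costs <- daily_costs$F + daily_costs$Vd
  ad <- pot_area_series(schedule)
  if (length(daily_costs) < length(ad)) {
    stop("daily_costs must cover every day of the schedule")
  }
  if (is.null(dmp)) dmp <- 100 * obs$dry_matter_fraction[nrow(obs)]
  if (is.null(actual_day)) actual_day <- obs$day[nrow(obs)]
  lo <- obs$day[1]
  hi <- min(obs$day[nrow(obs)], actual_day, schedule$duration_days)
  if (hi < lo) stop("empty candidate window")
  cand <- seq.int(lo, hi)
  daily <- interpolate_observations(obs, cand)
  price <- pot_price(daily$red_ffw, dmp, pmax(daily$red_fruit_fraction, 0), model)
  gains <- gains_per_pot(price, book)
  cum_cost <- cumsum(daily_costs[seq_len(schedule$duration_days)] * ad)
  cum_area <- cumsum(ad)
  np <- (gains - cum_cost[cand]) / cum_area[cand]
  if (all(price == 0)) {
    warning("no candidate day clears the ripeness/weight gates; all profits negative")
  }
  best <- which.max(np)  # first maximum = earliest day on ties
  profit_actual <- if (actual_day >= lo && actual_day <= hi) np[match(actual_day, cand)] else NA_real_
  list(optimal_day = cand[best],
       profit_optimal = np[best],
       actual_day = actual_day,
       profit_actual = profit_actual,
       days_earlier = actual_day - cand[best],
       delta = np[best] - profit_actual,
       scan = data.frame(day = cand, gains = gains, net_profit = np))
}

#' Format a harvest-optimization result as a sensitivity note
#'
#' Mirrors the "current -> maximal" annotation style: days the harvest
#' could have moved earlier, and the absolute and percentage profit gain.
#' The percentage is reported as `n/a` when the realized profit is not
#' positive.
#'
#' @param result output of [optimal_harvest_day()].
#' @return list with `days_earlier`, `delta`, `percent` (NA when
#'   undefined) and `label`, e.g. `"8 days earlier: 0.18 -> 0.27, +0.09 (+50%)"`.
#' @export
harvest_sensitivity_report <- function(result) {
  delta <- result$profit_optimal - result$profit_actual
  pct <- if (!is.na(result$profit_actual) && result$profit_actual > 0) {
    100 * delta / result$profit_actual
  } else NA_real_
  label <- sprintf("%d day(s) earlier: %.2f -> %.2f, %+.2f (%s)",
                   result$days_earlier,
                   round_half_up(result$profit_actual, 2),
                   round_half_up(result$profit_optimal, 2),
                   round_half_up(delta, 2),
                   if (is.na(pct)) "n/a" else sprintf("%+.0f%%", pct))
  list(days_earlier = result$days_earlier, delta = delta, percent = pct,
       label = label)
}
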