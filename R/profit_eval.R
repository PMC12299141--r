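# The net-profit objective over a plant-density schedule, plus derived
# agronomic metrics (average density, annualized yield, light use
# efficiency) and strategy ranking.

#' Daily area occupied per pot
#'
#' The reciprocal of the plant density in force on each day: a spacing
#' event on day `k` changes the density from day `k` onward.
#' @param schedule a [density_schedule()].
#' @return numeric vector of length `D`, m2 per pot per day.
#' @export
pot_area_series <- function(schedule) {
  d <- schedule$duration_days
  dens <- numeric(d)
  for (i in seq_len(nrow(schedule$events))) {
    dens[schedule$events$day[i]:d] <- schedule$events$density[i]
  }
  1 / dens
}

#' Average plant density of a schedule
#'
#' `D / sum(ad)`: the reciprocal of the mean daily area per pot (a
#' harmonic-type mean of the densities, weighted by days).
#' @param schedule a [density_schedule()].
#' @return pots per m2.
#' @export
average_density <- function(schedule) {
  schedule$duration_days / sum(pot_area_series(schedule))
}

#' Net profit of a cultivation (full-ledger path)
#'
#' The trial's objective: gains per pot minus accumulated costs per pot,
#' divided by the total pot-area-days,
#' `(G - sum_d (F + Vd) * ad) / sum_d ad`, in EUR per m2 of greenhouse per
#' day. Costs accrue on every day including the harvest day.
#'
#' @param gains EUR/pot at harvest, from [gains_per_pot()].
#' @param ledger daily cost ledger from [daily_cost_ledger()], one row per
#'   cultivation day.
#' @param schedule a [density_schedule()] covering the same days.
#' @return EUR/m2/day.
#' @export
net_profit <- function(gains, ledger, schedule) {
  ad <- pot_area_series(schedule)
  if (nrow(ledger) != length(ad)) {
    stop(sprintf("ledger covers %d day(s) but schedule %d", nrow(ledger), length(ad)))
  }
  (gains - sum((ledger$F + ledger$Vd) * ad)) / sum(ad)
}

#' Net profit from end-of-cultivation summary quantities
#'
#' The same objective computed from the four numbers a results table
#' prints: gains per pot, total costs per pot, cultivation duration and
#' average plant density. Algebraically
#' `(gains - cost_per_pot) * avg_density / duration`.
#'
#' @param gains,cost_per_pot EUR/pot (`cost_per_pot` as a positive
#'   magnitude).
#' @param duration cultivation length, days.
#' @param avg_density pots/m2.
#' @return EUR/m2/day.
#' @export
net_profit_summary <- function(gains, cost_per_pot, duration, avg_density) {
  (gains - cost_per_pot) * avg_density / duration
}

#' Annualized yield of a single-harvest cultivation
#'
#' Extrapolates one cycle's ripe-fruit production to back-to-back cycles
#' over a year: `red_ffw * avg_density / duration * 365 / 1000` kg per m2
#' per year.
#' @param red_ffw ripe fruit fresh weight at harvest, g/pot.
#' @param avg_density pots/m2.
#' @param duration cycle length, days.
#' @return kg/m2/year.
#' @export
annualized_yield <- function(red_ffw, avg_density, duration) {
  red_ffw * avg_density / duration * 365 / 1000
}

#' Light use efficiency
#'
#' Grams of fruit fresh weight produced per m2 of greenhouse per mol of
#' total PAR (sunlight plus lamps) received on that m2.
#' @param fresh_weight_per_m2 g/m2 over the cultivation.
#' @param total_par mol/m2 over the cultivation.
#' @return g/mol.
#' @export
light_use_efficiency <- function(fresh_weight_per_m2, total_par) {
  if (total_par <= 0) stop("total_par must be positive")
  fresh_weight_per_m2 / total_par
}

new_evaluation <- function(team, duration, schedule, ledger, ad, price, gains,
                           cost_per_pot, net_profit, avg_density,
                           annualized_yield, lue, plant_cost = NA_real_) {
  structure(list(team = team, duration = duration, schedule = schedule,
                 ledger = ledger, ad = ad, price = price, gains = gains,
                 cost_per_pot = cost_per_pot, net_profit = net_profit,
                 avg_density = avg_density, annualized_yield = annualized_yield,
                 lue = lue, plant_cost = plant_cost),
            class = "cultivation_evaluation")
}

#' Evaluate a cultivation from its raw 5-minute trace
#'
#' The full pipeline: build the daily cost ledger from the trace, price the
#' final crop observation, and assemble net profit and the derived metrics.
#'
#' @param trace a [control_trace()] covering the whole cultivation.
#' @param schedule a [density_schedule()] with the same duration.
#' @param final_obs the harvest-day measurement: either a
#'   [crop_observations()] (its last record is used) or a list with
#'   `red_ffw` (g/pot), `dry_matter_fraction` (e.g. 0.068) and
#'   `red_fruit_fraction`.
#' @param book a [cost_book()].
#' @param model a [price_model()].
#' @param equipment optional [equipment_choice()]; by default the installed
#'   intensity is the trace's maximum activation and the spacing-change
#'   count comes from the schedule.
#' @param total_par optional total PAR over the cultivation, mol/m2, used
#'   only for the light-use-efficiency metric.
#' @param interventions manual interventions, passed to [gains_per_pot()].
#' @param team optional label.
#' @return a `cultivation_evaluation` with the daily ledger attached.
#' @export
evaluate_cultivation <- function(trace, schedule, final_obs,
                                 book = cost_book(), model = price_model(),
                                 equipment = NULL, total_par = NULL,
                                 interventions = 0L, team = NA_character_) {
  d <- trace_duration(trace)
  if (d != schedule$duration_days) {
    stop(sprintf("trace covers %d day(s) but schedule %d", d, schedule$duration_days))
  }
  if (is.null(equipment)) {
    equipment <- equipment_choice(installed_intensity_from_trace(trace, book),
                                  n_spacing_changes(schedule),
                                  book$lamp_max_intensity)
  }
  if (inherits(final_obs, "crop_observations")) final_obs <- final_obs[nrow(final_obs), ]
  ledger <- daily_cost_ledger(trace, equipment, book)
  ad <- pot_area_series(schedule)
  price <- pot_price(final_obs$red_ffw, 100 * final_obs$dry_matter_fraction,
                     final_obs$red_fruit_fraction, model)
  gains <- gains_per_pot(price, book, interventions)
  cost_per_pot <- sum((ledger$F + ledger$Vd) * ad)
  avg_dens <- average_density(schedule)
  lue <- if (is.null(total_par)) NA_real_ else {
    light_use_efficiency(final_obs$red_ffw * avg_dens, total_par)
  }
  new_evaluation(team, d, schedule, ledger, ad, price, gains, cost_per_pot,
                 net_profit = (gains - cost_per_pot) / sum(ad),
                 avg_density = avg_dens,
                 annualized_yield = annualized_yield(final_obs$red_ffw, avg_dens, d),
                 lue = lue, plant_cost = book$plant_cost)
}

#' Evaluate a cultivation from summary quantities
#'
#' The summary path: no daily ledger, just the end-of-cultivation numbers a
#' results table prints. Useful for re-deriving rankings from published
#' tables and for cross-checking the full-trace path.
#'
#' @param gains,cost_per_pot EUR/pot (cost as a positive magnitude).
#' @param duration days.
#' @param avg_density pots/m2.
#' @param red_ffw optional ripe fresh weight g/pot (enables the annualized
#'   yield metric).
#' @param total_par optional total PAR mol/m2 (enables LUE).
#' @param price optional EUR/pot.
#' @param team optional label.
#' @return a `cultivation_evaluation` without a ledger.
#' @export
evaluate_summary <- function(gains, cost_per_pot, duration, avg_density,
                             red_ffw = NA_real_, total_par = NULL,
                             price = NA_real_, team = NA_character_) {
  yield <- if (is.na(red_ffw)) NA_real_ else annualized_yield(red_ffw, avg_density, duration)
  lue <- if (is.null(total_par) || is.na(red_ffw)) NA_real_ else {
    light_use_efficiency(red_ffw * avg_density, total_par)
  }
  new_evaluation(team, duration, schedule = NULL, ledger = NULL, ad = NULL,
                 price = price, gains = gains, cost_per_pot = cost_per_pot,
                 net_profit = net_profit_summary(gains, cost_per_pot, duration, avg_density),
                 avg_density = avg_density, annualized_yield = yield, lue = lue,
                 plant_cost = if (is.na(price)) NA_real_ else price - gains)
}

#' @export
print.cultivation_evaluation <- function(x, ...) {
  cat(sprintf("Cultivation evaluation%s\n",
              if (is.na(x$team)) "" else paste0(": ", x$team)))
  cat(sprintf("  duration        %d days\n", as.integer(x$duration)))
  cat(sprintf("  avg density     %.1f pots/m2\n", x$avg_density))
  cat(sprintf("  gains           %.2f EUR/pot\n", round_half_up(x$gains, 2)))
  cat(sprintf("  costs           %.2f EUR/pot\n", round_half_up(x$cost_per_pot, 2)))
  cat(sprintf("  net profit      %.2f EUR/m2/day\n", round_half_up(x$net_profit, 2)))
  if (!is.na(x$annualized_yield)) {
    cat(sprintf("  annualized yield %.1f kg/m2/year\n", x$annualized_yield))
  }
  if (!is.na(x$lue)) cat(sprintf("  light use eff.  %.1f g/mol\n", x$lue))
  invisible(x)
}

#' Rank cultivation strategies by net profit
#'
#' @param evaluations a list of `cultivation_evaluation` objects, or a
#'   `data.frame` with columns `gains`, `cost_per_pot`, `duration`,
#'   `avg_density` (and optionally `team`, `red_ffw`) to be run through
#'   [evaluate_summary()] row-wise.
#' @return `data.frame` sorted by net profit descending, ties broken by the
#'   lower cost per pot; columns `rank`, `team`, `net_profit`,
#'   `cost_per_pot`, `gains`, `avg_density`, `duration`,
#'   `annualized_yield`.
#' @export
rank_teams <- function(evaluations) {
  if (is.data.frame(evaluations)) {
    df <- evaluations
    evaluations <- lapply(seq_len(nrow(df)), function(i) {
      evaluate_summary(gains = df$gains[i], cost_per_pot = df$cost_per_pot[i],
                       duration = df$duration[i], avg_density = df$avg_density[i],
                       red_ffw = df$red_ffw[i] %||% NA_real_,
                       team = if ("team" %in% names(df)) df$team[i] else paste0("entry-", i))
    })
  }
  if (length(evaluations) < 1L) stop("need at least one evaluation")
  tab <- do.call(rbind, lapply(evaluations, function(e) {
    data.frame(team = e$team, net_profit = e$net_profit,
               cost_per_pot = e$cost_per_pot, gains = e$gains,
               avg_density = e$avg_density, duration = e$duration,
               annualized_yield = e$annualized_yield)
  }))
  tab <- tab[order(-tab$net_profit, tab$cost_per_pot), ]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' End-of-trial summary of the six 2024 dwarf-tomato strategies
#'
#' The published end-of-cultivation results of the fourth autonomous
#' greenhouse challenge (autumn 2024, dwarf cherry tomato): per strategy
#' the ripe fruit fresh weight, fruit dry-matter percentage, ripeness
#' fraction, gains and costs per pot, cultivation duration, average plant
#' density, and the printed net profit. Costs are stored as positive
#' magnitudes; `net_profit_printed` is the published (rounded) value, kept
#' for cross-checks rather than computation.
#'
#' @return `data.frame` with one row per strategy.
#' @export
team_results_2024 <- function() {
  data.frame(
    team = c("IDEAS", "MuGrow", "Trigger", "Reference", "Agrifusion", "Tomatonuts"),
    red_ffw = c(219, 252, 268, 275, 258, 283),
    dmp = c(6.8, 7.3, 5.9, 6.6, 7.2, 6.0),
    rfp = c(0.86, 0.76, 1.01, 0.81, 0.92, 0.98),
    gains = c(1.05, 1.11, 1.05, 1.05, 1.09, 1.05),
    cost_per_pot = c(0.44, 0.74, 0.73, 0.67, 0.72, 0.91),
    duration = c(70, 70, 80, 74, 78, 80),
    avg_density = c(39.7, 33.1, 33.4, 25.3, 25.0, 23.0),
    net_profit_printed = c(0.34, 0.18, 0.13, 0.13, 0.12, 0.04)
  )
}
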