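# Daily fixed and variable cost accounting from a 5-minute control trace:
# lamp electricity under a peak/off-peak tariff, pipe-rail heating from the
# pipe-air temperature difference, CO2 dosing from the cumulative counter.

#' Equipment choice charged through the fixed costs
#'
#' @param installed_lamp_intensity umol/(m2 s); in the trial this is the
#'   maximum lamp activation actually used, see
#'   [installed_intensity_from_trace()].
#' @param n_spacing_changes integer 0..3.
#' @param lamp_max_intensity upper bound for validation.
#' @return an `equipment_choice` list.
#' @export
equipment_choice <- function(installed_lamp_intensity, n_spacing_changes,
                             lamp_max_intensity = 200) {
  if (installed_lamp_intensity < 0 || installed_lamp_intensity > lamp_max_intensity) {
    stop("installed lamp intensity must lie in [0, ", lamp_max_intensity, "]")
  }
  if (!(n_spacing_changes %in% 0:3)) stop("n_spacing_changes must be 0..3")
  structure(list(installed_lamp_intensity = installed_lamp_intensity,
                 n_spacing_changes = as.integer(n_spacing_changes)),
            class = "equipment_choice")
}

#' Lamp electricity use of one 5-minute record
#'
#' The lamps dim linearly: at activation `a` percent they draw
#' `a/100 * lamp_max_intensity / lamp_efficacy` W/m2 (photon flux over
#' photon efficacy), which over one of the 12 five-minute records per hour
#' is that power `/1000/12` kWh/m2. At 100% with a 200 umol/(m2 s) fixture
#' of 3.2 umol/J efficacy one record uses 0.00520833 kWh/m2.
#'
#' @param activation percent in `[0, 100]`, vectorized.
#' @param book a [cost_book()].
#' @return kWh/m2 per record.
#' @export
lamp_energy_per_record <- function(activation, book = cost_book()) {
  if (any(activation < 0 | activation > 100)) stop("activation must be within [0, 100]")
  (activation / 100) * book$lamp_max_intensity / book$lamp_efficacy / 1000 / 12
}

#' Electricity tariff applying to each record
#'
#' On-peak on workdays (Monday-Friday) within the configured local-clock
#' window (default 07:00 inclusive to 23:00 exclusive), off-peak at all
#' other times including the whole weekend. Each record is priced by its
#' start timestamp, evaluated on the civil clock of `book$tz` (so daylight
#' saving transitions are priced by local time).
#'
#' @param timestamps `POSIXct`.
#' @param book a [cost_book()].
#' @return EUR/kWh per timestamp.
#' @export
record_tariff <- function(timestamps, book = cost_book()) {
  lt <- as.POSIXlt(timestamps, tz = book$tz)
  workday <- lt$wday >= 1 & lt$wday <= 5
  on_peak <- workday & lt$hour >= book$on_peak_start & lt$hour < book$on_peak_end
  ifelse(on_peak, book$on_peak_price, book$off_peak_price)
}

#' Daily lamp electricity use and cost
#'
#' @param trace a [control_trace()].
#' @param book a [cost_book()].
#' @return `data.frame(day, EL, Ld)`: energy kWh/m2 and cost EUR/m2 per day.
#' @export
electricity_cost <- function(trace, book = cost_book()) {
  day <- trace_day_index(trace)
  el <- lamp_energy_per_record(trace$lamp_activation, book)
  price <- record_tariff(trace$timestamp, book)
  data.frame(day = sort(unique(day)),
             EL = as.numeric(rowsum(el, day)),
             Ld = as.numeric(rowsum(el * price, day)))
}

#' Instantaneous pipe-rail heating power
#'
#' A standard pipe-rail delivers roughly 2 W/m2 per degree of positive
#' pipe-minus-air temperature difference; with the circulation pump off no
#' heat is delivered regardless of the pipe temperature.
#'
#' @param pipe_t,air_t degrees C, vectorized.
#' @param pump logical, circulation pump running.
#' @return W/m2.
#' @export
heating_power <- function(pipe_t, air_t, pump) {
  p <- ifelse(is.na(pipe_t) | !pump, 0, 2 * pmax(0, pipe_t - air_t))
  as.numeric(p)
}

#' Daily heating energy and cost
#'
#' Each record contributes `Ppipe / 1000 / 12` kWh/m2 (12 records per hour);
#' the daily energy is priced at the flat heat tariff.
#' @param trace a [control_trace()].
#' @param book a [cost_book()].
#' @return `data.frame(day, EH, Hd)`: energy kWh/m2 and cost EUR/m2 per day.
#' @export
heating_cost <- function(trace, book = cost_book()) {
  day <- trace_day_index(trace)
  p <- heating_power(trace$pipe_temperature, trace$air_temperature, trace$pump_running)
  eh <- p / 1000 / 12
  data.frame(day = sort(unique(day)),
             EH = as.numeric(rowsum(eh, day)),
             Hd = as.numeric(rowsum(eh, day)) * book$heat_price)
}

#' Daily CO2 mass dosed and its cost
#'
#' The trace records a cumulative dosing-duration counter in minutes; each
#' record's positive increment, times the dosing mass flow (default
#' 0.125 g/m2 per minute), is the mass dosed. Counter decreases (device
#' resets) contribute nothing.
#' @param trace a [control_trace()].
#' @param book a [cost_book()].
#' @return `data.frame(day, co2_kg, Cd)`: kg/m2 and EUR/m2 per day.
#' @export
co2_cost <- function(trace, book = cost_book()) {
  day <- trace_day_index(trace)
  inc <- pmax(0, diff(c(trace$co2_dosing_cumulative[1], trace$co2_dosing_cumulative)))
  grams <- inc * book$co2_rate
  kg <- as.numeric(rowsum(grams, day)) / 1000
  data.frame(day = sort(unique(day)), co2_kg = kg, Cd = kg * book$co2_price)
}

#' Daily fixed costs of an equipment choice
#'
#' Greenhouse maintenance and depreciation, lamp depreciation proportional
#' to the installed intensity, and a charge per spacing step, all annual
#' rates divided by 365.
#' @param eq an [equipment_choice()].
#' @param book a [cost_book()].
#' @return EUR/m2/day (scalar).
#' @export
fixed_costs <- function(eq, book = cost_book()) {
  book$base_fixed / 365 +
    book$lamp_depreciation * eq$installed_lamp_intensity / 365 +
    book$spacing_step_cost * eq$n_spacing_changes / 365
}

#' Installed lamp intensity implied by a trace
#'
#' The trial charges lamp depreciation on the maximum activation percentage
#' used at any point, converted to umol/(m2 s) of the installed fixture.
#' @param trace a [control_trace()].
#' @param book a [cost_book()].
#' @return umol/(m2 s).
#' @export
installed_intensity_from_trace <- function(trace, book = cost_book()) {
  max(trace$lamp_activation) / 100 * book$lamp_max_intensity
}

#' Full daily cost ledger of a cultivation
#'
#' Combines [electricity_cost()], [heating_cost()], [co2_cost()] and
#' [fixed_costs()] into one row per cultivation day, with the variable
#' costs `Vd = Ld + Hd + Cd`.
#'
#' @param trace a [control_trace()].
#' @param equipment an [equipment_choice()]; when `NULL` the installed
#'   intensity is inferred from the trace and `n_changes` must be given.
#' @param book a [cost_book()].
#' @param n_changes spacing changes, used only when `equipment` is `NULL`.
#' @return `data.frame(day, EL, Ld, EH, Hd, co2_kg, Cd, F, Vd)`.
#' @export
daily_cost_ledger <- function(trace, equipment = NULL, book = cost_book(),
                              n_changes = 0L) {
  if (is.null(equipment)) {
    equipment <- equipment_choice(installed_intensity_from_trace(trace, book),
                                  n_changes, book$lamp_max_intensity)
  }
  led <- merge(merge(electricity_cost(trace, book), heating_cost(trace, book),
                     by = "day"),
               co2_cost(trace, book), by = "day")
  led$F <- fixed_costs(equipment, book)
  led$Vd <- led$Ld + led$Hd + led$Cd
  led[order(led$day), ]
}

#' Write a daily cost ledger to CSV
#' @param ledger output of [daily_cost_ledger()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}
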