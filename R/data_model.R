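# Domain types: control traces, density schedules, crop observations,
# cost book, price model. All constructors validate; readers parse CSV/YAML/JSON.

RECORDS_PER_DAY <- 288L
RECORD_SECONDS <- 300

ALLOWED_DENSITIES <- c(56, 42, 30, 20)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated 5-minute control trace
#'
#' A control trace holds the uniformly sampled (5-minute) actuator and
#' climate state of one greenhouse compartment over a whole cultivation:
#' lamp dimming percentage, heating-pipe and air temperature, circulation
#' pump state, and the cumulative CO2 dosing-duration counter (minutes).
#'
#' Cultivation days are 24-hour windows counted from the first record, which
#' must fall on a local midnight; a complete trace has exactly 288 records
#' per day. The cumulative CO2 counter may drop when the recording device
#' resets; resets are tolerated here (with a flag) and ignored by the
#' positive-difference rule in [co2_cost()].
#'
#' @param timestamps `POSIXct`, strictly increasing at 300 s spacing.
#' @param lamp_activation numeric percent in `[0, 100]`.
#' @param air_temperature numeric, degrees C.
#' @param pipe_temperature numeric, degrees C, or `NULL` when the compartment
#'   reports none; `NA` where the circulation pump was off.
#' @param pump_running logical; if `NULL` it is inferred as "pipe temperature
#'   present", the convention used when the pump channel is not exported.
#' @param co2_dosing_cumulative numeric minutes, non-decreasing except at
#'   device resets, or `NULL` for a compartment without CO2 dosing.
#' @return A `control_trace`: a `data.frame` with one row per record and an
#'   attribute `co2_resets` counting detected counter resets.
#' @seealso [read_control_trace()], [daily_cost_ledger()]
#' @export
control_trace <- function(timestamps, lamp_activation, air_temperature,
                          pipe_temperature = NULL, pump_running = NULL,
                          co2_dosing_cumulative = NULL) {
  n <- length(timestamps)
  if (n == 0L) stop("control trace must contain at least one record")
  if (!inherits(timestamps, "POSIXct")) stop("timestamps must be POSIXct")
  dt <- diff(as.numeric(timestamps))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (any(abs(dt - RECORD_SECONDS) > 1e-6)) {
    stop("timestamps must be spaced exactly 300 s apart; use read_control_trace() for gap filling")
  }
  if (n %% RECORDS_PER_DAY != 0L) {
    stop(sprintf("trace must cover whole days (288 records/day); got %d records", n))
  }
  stopifnot(length(lamp_activation) == n, length(air_temperature) == n)
  if (any(!is.finite(lamp_activation)) ||
      any(lamp_activation < 0 | lamp_activation > 100)) {
    stop("lamp_activation must be finite and within [0, 100]")
  }
  if (is.null(pipe_temperature)) pipe_temperature <- rep(NA_real_, n)
  if (is.null(pump_running)) pump_running <- !is.na(pipe_temperature)
  if (is.null(co2_dosing_cumulative)) co2_dosing_cumulative <- rep(0, n)
  stopifnot(length(pipe_temperature) == n, length(pump_running) == n,
            length(co2_dosing_cumulative) == n)
  if (any(!is.finite(co2_dosing_cumulative))) {
    stop("co2_dosing_cumulative must be finite")
  }
  resets <- sum(diff(co2_dosing_cumulative) < 0)
  tr <- data.frame(
    timestamp = timestamps,
    lamp_activation = as.numeric(lamp_activation),
    air_temperature = as.numeric(air_temperature),
    pipe_temperature = as.numeric(pipe_temperature),
    pump_running = as.logical(pump_running),
    co2_dosing_cumulative = as.numeric(co2_dosing_cumulative)
  )
  attr(tr, "co2_resets") <- resets
  class(tr) <- c("control_trace", "data.frame")
  tr
}

#' Number of cultivation days covered by a trace
#' @param trace a `control_trace`.
#' @return integer day count.
#' @export
trace_duration <- function(trace) nrow(trace) %/% RECORDS_PER_DAY

#' Cultivation day index of every record
#'
#' Day 1 starts at the first record (the transplant-day midnight); each day
#' is the following 24-hour window, i.e. 288 consecutive records.
#' @param trace a `control_trace`.
#' @return integer vector, one entry per record.
#' @export
trace_day_index <- function(trace) {
  el <- as.numeric(trace$timestamp) - as.numeric(trace$timestamp[1])
  as.integer(el %/% 86400) + 1L
}

#' Default column mapping for control-trace CSV files
#'
#' @param timestamp,lamp,air,pipe,pump,co2 column names in the CSV; set
#'   `pipe`, `pump` or `co2` to `NA` for files without that channel.
#' @return named list usable as the `dialect` of [read_control_trace()].
#' @export
trace_dialect <- function(timestamp = "timestamp",
                          lamp = "lamp_activation",
                          air = "air_temperature",
                          pipe = "pipe_temperature",
                          pump = "pump_running",
                          co2 = "co2_dosing_cumulative") {
  list(timestamp = timestamp, lamp = lamp, air = air,
       pipe = pipe, pump = pump, co2 = co2)
}

parse_iso8601 <- function(x) {
  # ISO-8601 with explicit numeric UTC offset, e.g. 2024-09-03T00:05:00+0200
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%d %H:%M:%S%z", tz = "UTC")
  if (any(is.na(out))) stop("unparseable ISO-8601 timestamp(s), e.g. ", x[which(is.na(out))[1]])
  out
}

locf <- function(x) {
  idx <- cumsum(!is.na(x))
  if (idx[1] == 0L) stop("cannot carry forward before the first observation")
  x[which(!is.na(x))][idx]
}

#' Read a control trace from CSV, filling short gaps
#'
#' Expects a comma-separated file with an ISO-8601 timestamp column (explicit
#' UTC offset) plus the named channels. Records are aligned on the regular
#' 300-second grid between the first and last timestamp. Runs of up to
#' `max_gap` missing records are filled by last observation carried forward
#' (the cumulative CO2 counter is interpolated linearly instead, so it stays
#' non-decreasing); a longer gap is an error, as is any out-of-order
#' timestamp or a missing required channel.
#'
#' @param path CSV file path.
#' @param dialect column mapping from [trace_dialect()].
#' @param max_gap maximum number of consecutive missing records filled
#'   (default 6, i.e. 30 minutes).
#' @return a validated [control_trace()]; a warning reports how many records
#'   were gap-filled.
#' @export
read_control_trace <- function(path, dialect = trace_dialect(), max_gap = 6L) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(dialect$timestamp, dialect$lamp, dialect$air)
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required channel(s): ", paste(miss, collapse = ", "))
  ts <- parse_iso8601(raw[[dialect$timestamp]])
  if (any(diff(as.numeric(ts)) <= 0)) stop("timestamps out of order")
  off <- as.numeric(ts) - as.numeric(ts[1])
  if (any(abs(off - round(off / RECORD_SECONDS) * RECORD_SECONDS) > 1e-6)) {
    stop("timestamps do not lie on a 300 s grid")
  }
  slot <- as.integer(round(off / RECORD_SECONDS)) + 1L
  n <- slot[length(slot)]
  grid_ts <- ts[1] + RECORD_SECONDS * (seq_len(n) - 1L)

  present <- logical(n); present[slot] <- TRUE
  if (!all(present)) {
    gaps <- rle(present)
    runs <- gaps$lengths[!gaps$values]
    if (any(runs > max_gap)) {
      stop(sprintf("gap of %d consecutive records exceeds limit of %d",
                   max(runs), max_gap))
    }
    warning(sprintf("filled %d missing record(s) (last observation carried forward)",
                    sum(!present)))
  }

  pick <- function(col) {
    if (is.null(col) || is.na(col) || !(col %in% names(raw))) return(NULL)
    x <- rep(NA_real_, n); x[slot] <- as.numeric(raw[[col]]); x
  }
  lamp <- locf(pick(dialect$lamp))
  air  <- locf(pick(dialect$air))
  pipe <- pick(dialect$pipe)
  has_pipe_rows <- !is.null(pipe) && any(!is.na(pipe[slot]))
  if (!is.null(pipe)) {
    # pipe may legitimately be NA while the pump is off: only fill the
    # synthesized gap slots, leaving genuine NAs alone
    for (i in which(!present)) pipe[i] <- pipe[max(which(present[seq_len(i)]))]
  }
  pump <- NULL
  if (!is.null(dialect$pump) && !is.na(dialect$pump) && dialect$pump %in% names(raw)) {
    p <- rep(NA, n)
    p[slot] <- as.logical(raw[[dialect$pump]])
    pump <- as.logical(locf(as.numeric(p)))
  }
  co2 <- pick(dialect$co2)
  if (!is.null(co2) && any(is.na(co2))) {
    # linear interpolation preserves monotonicity of the cumulative counter
    co2 <- stats::approx(which(!is.na(co2)), co2[!is.na(co2)], xout = seq_len(n),
                         rule = 2)$y
  }
  control_trace(grid_ts, lamp, air,
                pipe_temperature = pipe, pump_running = pump,
                co2_dosing_cumulative = co2)
}

#' Write a control trace to CSV
#'
#' Inverse of [read_control_trace()]: timestamps are written as ISO-8601
#' with explicit UTC offset, all channel values at full precision, so a
#' read-then-write round trip is lossless.
#' @param trace a `control_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_control_trace <- function(trace, path) {
  out <- as.data.frame(trace)
  out$timestamp <- format(trace$timestamp, "%Y-%m-%dT%H:%M:%S%z")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a plant-density schedule
#'
#' Dwarf tomato is transplanted at 56 plants/m2 and may be re-spaced down
#' through 42, 30 and 20 plants/m2 as the canopy closes, at most three
#' times. The schedule is piecewise constant in days since transplanting:
#' an event on day `k` applies from day `k` onward.
#'
#' @param events `data.frame` with columns `day` (integer, >= 1, strictly
#'   increasing) and `density` (plants/m2, from 56/42/30/20, strictly
#'   decreasing). The first event must be `(1, 56)`.
#' @param duration_days cultivation length `D` in days (harvest day
#'   included).
#' @return a `density_schedule` object.
#' @export
density_schedule <- function(events, duration_days) {
  events <- as.data.frame(events)[, c("day", "density")]
  duration_days <- as.integer(duration_days)
  if (duration_days < 1L) stop("duration_days must be >= 1")
  if (nrow(events) < 1L) stop("schedule needs at least the initial density event")
  if (events$day[1] != 1L || events$density[1] != 56) {
    stop("schedule must start at day 1 with 56 plants/m2")
  }
  if (!all(events$density %in% ALLOWED_DENSITIES)) {
    stop("densities must be drawn from {56, 42, 30, 20} plants/m2")
  }
  if (any(diff(events$day) <= 0)) stop("event days must be strictly increasing")
  if (any(diff(events$density) >= 0)) stop("density must strictly decrease at each spacing event")
  if (nrow(events) > 4L) stop("at most 3 spacing changes are allowed")
  if (any(events$day > duration_days)) stop("event day beyond cultivation duration")
  structure(list(events = events, duration_days = duration_days),
            class = "density_schedule")
}

#' Number of spacing changes in a schedule
#' @param schedule a `density_schedule`.
#' @return integer in 0..3.
#' @export
n_spacing_changes <- function(schedule) nrow(schedule$events) - 1L

#' Read a density schedule from CSV or JSON
#'
#' CSV files carry `day,density` event rows and need `duration_days`
#' supplied; JSON files are self-contained:
#' `{"duration_days": D, "events": [{"day":1,"density":56}, ...]}`.
#' @param path file path (`.json` or `.csv`).
#' @param duration_days required for CSV input.
#' @return a validated [density_schedule()].
#' @export
read_density_schedule <- function(path, duration_days = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    density_schedule(as.data.frame(x$events), x$duration_days)
  } else {
    ev <- utils::read.csv(path)
    if (is.null(duration_days)) stop("duration_days is required for CSV schedules")
    density_schedule(ev, duration_days)
  }
}

#' @export
print.density_schedule <- function(x, ...) {
  cat(sprintf("Density schedule: %d day(s), %d spacing change(s)\n",
              x$duration_days, n_spacing_changes(x)))
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Construct a sparse crop-observation series
#'
#' Destructive measurements taken at a few dates during the cultivation:
#' total and red (ripe) fruit fresh weight per pot, fruit dry-matter
#' fraction, and the ripeness fraction (red over total fresh weight).
#' Because successive measurements destroy different plants, the red weight
#' can slightly exceed the total of another sample; such records are
#' flagged (attribute `rfp_overshoot`), not rejected, and the ripeness
#' fraction is clamped to 1 wherever it gates the price.
#'
#' @param day integer days since transplanting, strictly increasing.
#' @param total_ffw,red_ffw fresh fruit weight, g/pot, non-negative.
#' @param dry_matter_fraction dimensionless in (0, 1), e.g. 0.068 for 6.8%.
#' @param red_fruit_fraction optional; defaults to `red_ffw / total_ffw`.
#' @return a `crop_observations` data.frame.
#' @export
crop_observations <- function(day, total_ffw, red_ffw, dry_matter_fraction,
                              red_fruit_fraction = NULL) {
  n <- length(day)
  stopifnot(length(total_ffw) == n, length(red_ffw) == n)
  if (n >= 2L && any(diff(day) <= 0)) stop("observation days must be strictly increasing")
  if (any(total_ffw < 0) || any(red_ffw < 0)) stop("fruit weights must be non-negative")
  if (is.null(red_fruit_fraction)) {
    red_fruit_fraction <- ifelse(total_ffw > 0, red_ffw / total_ffw, 0)
  }
  if (length(dry_matter_fraction) == 1L) dry_matter_fraction <- rep(dry_matter_fraction, n)
  overshoot <- which(red_fruit_fraction > 1.05)
  if (length(overshoot)) {
    warning(sprintf("%d observation(s) have red fruit weight > 105%% of total; check sampling",
                    length(overshoot)))
  }
  obs <- data.frame(day = as.integer(day), total_ffw = total_ffw, red_ffw = red_ffw,
                    red_fruit_fraction = red_fruit_fraction,
                    dry_matter_fraction = dry_matter_fraction)
  attr(obs, "rfp_overshoot") <- overshoot
  class(obs) <- c("crop_observations", "data.frame")
  obs
}

#' Read crop observations from CSV
#' @param path CSV with columns `day,total_ffw,red_ffw,dry_matter_fraction`
#'   (and optionally `red_fruit_fraction`).
#' @return a validated [crop_observations()].
#' @export
read_crop_observations <- function(path) {
  x <- utils::read.csv(path)
  crop_observations(x$day, x$total_ffw, x$red_ffw, x$dry_matter_fraction,
                    red_fruit_fraction = x[["red_fruit_fraction"]])
}

#' Economic constants of the cultivation trial
#'
#' All tariffs, depreciation rates and unit prices entering the cost side
#' of the net-profit objective. Defaults are the trial's published values.
#'
#' @param base_fixed greenhouse maintenance + depreciation, EUR/m2/year.
#' @param lamp_depreciation lamp depreciation, EUR per umol/(m2 s) per year.
#' @param spacing_step_cost cost per spacing step, EUR/m2/year.
#' @param on_peak_price,off_peak_price electricity tariffs, EUR/kWh.
#' @param on_peak_start,on_peak_end on-peak window on workdays, local hours
#'   (start inclusive, end exclusive).
#' @param tz time zone whose civil clock defines the tariff window.
#' @param heat_price heating energy price, EUR/kWh.
#' @param co2_rate dosing mass flow, g CO2 per m2 per minute of dosing.
#' @param co2_price EUR per kg CO2.
#' @param plant_cost seed + pot + substrate + propagation, EUR/pot.
#' @param lamp_max_intensity installed maximum, umol/(m2 s).
#' @param lamp_efficacy photon efficacy, umol/J.
#' @param intervention_penalty EUR/pot per manual intervention.
#' @param intervention_penalty_enabled whether [gains_per_pot()] charges it;
#'   disabled by default so profitability and robustness are judged apart.
#' @return a `cost_book` list.
#' @export
cost_book <- function(base_fixed = 18.1250,
                      lamp_depreciation = 0.07,
                      spacing_step_cost = 1.50,
                      on_peak_price = 0.30,
                      off_peak_price = 0.20,
                      on_peak_start = 7L,
                      on_peak_end = 23L,
                      tz = "Europe/Amsterdam",
                      heat_price = 0.09,
                      co2_rate = 0.125,
                      co2_price = 0.30,
                      plant_cost = 0.75,
                      lamp_max_intensity = 200,
                      lamp_efficacy = 3.2,
                      intervention_penalty = 0.10,
                      intervention_penalty_enabled = FALSE) {
  book <- list(base_fixed = base_fixed, lamp_depreciation = lamp_depreciation,
               spacing_step_cost = spacing_step_cost,
               on_peak_price = on_peak_price, off_peak_price = off_peak_price,
               on_peak_start = on_peak_start, on_peak_end = on_peak_end, tz = tz,
               heat_price = heat_price, co2_rate = co2_rate, co2_price = co2_price,
               plant_cost = plant_cost, lamp_max_intensity = lamp_max_intensity,
               lamp_efficacy = lamp_efficacy,
               intervention_penalty = intervention_penalty,
               intervention_penalty_enabled = intervention_penalty_enabled)
  num <- vapply(book[setdiff(names(book), c("tz", "intervention_penalty_enabled"))],
                identity, numeric(1))
  if (any(num < 0)) stop("cost-book prices and rates must be non-negative")
  class(book) <- "cost_book"
  book
}

#' Piecewise fruit-value price model
#'
#' The value of a pot at harvest depends on the ripe-fruit fresh weight and
#' the fruit dry-matter percentage. Pots with a ripeness fraction below
#' `ripeness_min` or ripe fresh weight below `ffw_min` are unsellable
#' (price 0). Above the gates, the price at the weight cap interpolates
#' linearly on dry matter between a low curve (at or below `dm_low` percent)
#' and a high curve (at or above `dm_high` percent); weight beyond `ffw_cap`
#' earns no extra value. Below the cap the price scales proportionally with
#' `ffw / ffw_cap` (the trial's strategies all exceeded the cap, so this
#' region is a documented modelling assumption).
#'
#' The cap prices default to values calibrated from the trial's published
#' end-of-cultivation summary via [calibrate_price_caps()].
#'
#' @param ripeness_min minimum red fresh-weight fraction (default 1/3).
#' @param ffw_min minimum sellable ripe fresh weight, g/pot.
#' @param ffw_cap fresh weight above which price is flat, g/pot.
#' @param dm_low,dm_high dry-matter percentages bounding the interpolation.
#' @param price_low_at_cap,price_high_at_cap EUR at the weight cap on the
#'   low/high dry-matter curves.
#' @return a `price_model` list.
#' @export
price_model <- function(ripeness_min = 1 / 3,
                        ffw_min = 50,
                        ffw_cap = 150,
                        dm_low = 7,
                        dm_high = 8,
                        price_low_at_cap = 1.80,
                        price_high_at_cap = 2.00) {
  if (!(ffw_min > 0 && ffw_min < ffw_cap)) stop("need 0 < ffw_min < ffw_cap")
  if (!(dm_low < dm_high)) stop("need dm_low < dm_high")
  if (price_low_at_cap < 0 || price_high_at_cap < 0) stop("prices must be non-negative")
  structure(list(ripeness_min = ripeness_min, ffw_min = ffw_min, ffw_cap = ffw_cap,
                 dm_low = dm_low, dm_high = dm_high,
                 price_low_at_cap = price_low_at_cap,
                 price_high_at_cap = price_high_at_cap),
            class = "price_model")
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path)
}

#' Read a cost book or price model from YAML/JSON
#'
#' Fields present in the file override the defaults of [cost_book()] /
#' [price_model()]; unknown fields are an error.
#' @param path YAML or JSON file.
#' @return a `cost_book` / `price_model`.
#' @export
read_cost_book <- function(path) {
  x <- read_config_file(path)
  unknown <- setdiff(names(x), names(formals(cost_book)))
  if (length(unknown)) stop("unknown cost-book field(s): ", paste(unknown, collapse = ", "))
  do.call(cost_book, x)
}

#' @rdname read_cost_book
#' @export
read_price_model <- function(path) {
  x <- read_config_file(path)
  unknown <- setdiff(names(x), names(formals(price_model)))
  if (length(unknown)) stop("unknown price-model field(s): ", paste(unknown, collapse = ", "))
  do.call(price_model, x)
}

# half-up rounding for human-readable monetary output (base round() is
# round-half-even); internal arithmetic never rounds
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write an evaluation to a CSV ledger and JSON summary
#'
#' Produces `<stem>_ledger.csv` (one row per day, full precision) and
#' `<stem>_summary.json`. The JSON carries every total at full machine
#' precision plus a `display` block with EUR amounts rounded half-up to two
#' decimals for human readers.
#'
#' @param eval a `cultivation_evaluation` from [evaluate_cultivation()] or
#'   [evaluate_summary()].
#' @param stem output path stem (directory must exist).
#' @return named character vector of the files written, invisibly.
#' @export
write_evaluation_report <- function(eval, stem) {
  if (!inherits(eval, "cultivation_evaluation")) stop("eval must be a cultivation_evaluation")
  files <- c(summary = paste0(stem, "_summary.json"))
  if (!is.null(eval$ledger)) {
    if (nrow(eval$ledger) == 0L) stop("evaluation has an empty ledger")
    utils::write.csv(cbind(eval$ledger, ad = eval$ad),
                     paste0(stem, "_ledger.csv"), row.names = FALSE)
    files <- c(files, ledger = paste0(stem, "_ledger.csv"))
  }
  totals <- eval[c("team", "duration", "gains", "price", "cost_per_pot",
                   "net_profit", "avg_density", "annualized_yield", "lue")]
  disp <- lapply(totals[c("gains", "price", "cost_per_pot", "net_profit")],
                 function(v) sprintf("%.2f", round_half_up(v, 2)))
  jsonlite::write_json(
    list(totals = totals, display = disp,
         schedule = list(events = eval$schedule$events,
                         duration_days = eval$schedule$duration_days)),
    files[["summary"]], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(files)
}

#' Read back a JSON evaluation summary
#'
#' Reconstructs a summary-path `cultivation_evaluation` from the machine
#' fields written by [write_evaluation_report()]; the round trip is exact.
#' @param path `<stem>_summary.json` file.
#' @return a `cultivation_evaluation` (summary path: no daily ledger).
#' @export
read_evaluation_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  t <- x$totals
  ev <- evaluate_summary(gains = t$gains, cost_per_pot = t$cost_per_pot,
                         duration = t$duration, avg_density = t$avg_density,
                         team = t$team %||% NA_character_,
                         price = t$price %||% NA_real_,
                         red_ffw = NA_real_)
  ev$annualized_yield <- t$annualized_yield %||% NA_real_
  ev$lue <- t$lue %||% NA_real_
  ev
}
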