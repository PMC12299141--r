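# Seeded generators for trial-like inputs: 5-minute actuator traces,
# density schedules, and sparse destructive crop observations following
# logistic growth/ripening trajectories. Defaults emulate the 2024
# dwarf-tomato trial's ranges (cultivations of 70-80 days, ripe fresh
# weight saturating at 250-300 g/pot, average densities between roughly
# 23 and 40 pots/m2).

# independent sub-streams per generated component, so a trace and its crop
# series can be regenerated separately under one root seed
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 1e6) * 2039 + stream * 7919) %% 2147483647L
}

#' Scenario configuration for the synthetic generators
#'
#' Bundles every knob of the synthetic cultivation: photoperiod and lamp
#' dimming, day/night air temperatures and the night-time pipe heating
#' response, CO2 dosing, the density schedule, and the logistic crop
#' trajectories. Defaults describe a plausible autumn dwarf-tomato cycle:
#' a 70-day cultivation under a 16-hour photoperiod at 70% mean dimming,
#' 21/18 degC day/night temperatures with an 8 degC night pipe offset,
#' two hours of CO2 dosing per day, three spacing steps, total fruit
#' weight saturating near 260 g/pot around day 45 and ripening centred on
#' day 58.
#'
#' @param seed root RNG seed; every generator derives its own sub-stream.
#' @param duration cultivation days.
#' @param photoperiod lamp hours per day (lamps on from `lamp_on_hour`).
#' @param lamp_on_hour local hour the photoperiod starts.
#' @param lamp_mean,lamp_sd mean and per-record sd of the dimming
#'   percentage while lamps are on.
#' @param day_temp,night_temp,temp_sd air temperature regime, degC.
#' @param pipe_offset pipe-minus-air temperature during heating hours,
#'   degC (heating runs while lamps are off).
#' @param co2_dosing dosing minutes per day, spread over the photoperiod.
#' @param density_events `data.frame(day, density)` schedule template.
#' @param crop list `(K, r, t0)`: logistic total fresh weight, g/pot.
#' @param ripening list `(r, t0)`: logistic ripeness fraction.
#' @param dmp fruit dry-matter percentage (constant).
#' @param noise_sd sd of the destructive-measurement noise, g/pot.
#' @param obs_days observation days; default `c(34, 49, 63, duration)`,
#'   mirroring a trial with three in-cycle destructive measurements plus
#'   the harvest measurement.
#' @param start transplant date (the trace starts at local midnight).
#' @param tz fixed-offset time zone of the generated timestamps.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            duration = 70L,
                            photoperiod = 16,
                            lamp_on_hour = 2,
                            lamp_mean = 70,
                            lamp_sd = 5,
                            day_temp = 21,
                            night_temp = 18,
                            temp_sd = 0.3,
                            pipe_offset = 8,
                            co2_dosing = 120,
                            density_events = data.frame(
                              day = c(1L, 21L, 42L, 56L),
                              density = c(56, 42, 30, 20)),
                            crop = list(K = 260, r = 0.12, t0 = 45),
                            ripening = list(r = 0.25, t0 = 58),
                            dmp = 6.8,
                            noise_sd = 5,
                            obs_days = NULL,
                            start = "2024-09-03",
                            tz = "Etc/GMT-2") {
  stopifnot(duration >= 1, photoperiod >= 0, photoperiod <= 24,
            lamp_mean >= 0, lamp_mean <= 100,
            crop$K > 0, crop$r > 0, ripening$r > 0,
            co2_dosing >= 0, noise_sd >= 0)
  if (is.null(obs_days)) obs_days <- unique(pmin(c(34L, 49L, 63L, duration), duration))
  structure(list(seed = seed, duration = as.integer(duration),
                 photoperiod = photoperiod, lamp_on_hour = lamp_on_hour,
                 lamp_mean = lamp_mean, lamp_sd = lamp_sd,
                 day_temp = day_temp, night_temp = night_temp, temp_sd = temp_sd,
                 pipe_offset = pipe_offset, co2_dosing = co2_dosing,
                 density_events = density_events, crop = crop,
                 ripening = ripening, dmp = dmp, noise_sd = noise_sd,
                 obs_days = as.integer(obs_days), start = start, tz = tz),
            class = "scenario_config")
}

#' Generate a synthetic 5-minute control trace
#'
#' Lamps run at the configured mean dimming (with per-record Gaussian
#' noise, clamped to `[0, 100]`) during the photoperiod and are off
#' otherwise; air temperature follows a day/night square wave with noise;
#' the heating pipe runs while the lamps are off, at `pipe_offset` degrees
#' above air temperature with the circulation pump on; the cumulative CO2
#' counter advances uniformly over the photoperiod by `co2_dosing` minutes
#' per day. Deterministic given `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return a validated [control_trace()] with `288 * duration` records.
#' @export
generate_trace <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 1L))
  n <- RECORDS_PER_DAY * cfg$duration
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = cfg$tz)
  ts <- t0 + RECORD_SECONDS * (seq_len(n) - 1L)
  hour <- ((seq_len(n) - 1L) %% RECORDS_PER_DAY) * RECORD_SECONDS / 3600
  lamps_on <- hour >= cfg$lamp_on_hour & hour < cfg$lamp_on_hour + cfg$photoperiod
  lamp <- numeric(n)
  lamp[lamps_on] <- pmin(100, pmax(0, stats::rnorm(sum(lamps_on), cfg$lamp_mean, cfg$lamp_sd)))
  air <- ifelse(lamps_on, cfg$day_temp, cfg$night_temp) +
    stats::rnorm(n, 0, cfg$temp_sd)
  heating <- !lamps_on
  pipe <- ifelse(heating, air + cfg$pipe_offset + stats::rnorm(n, 0, 0.5), NA_real_)
  pump <- heating
  inc <- numeric(n)
  if (cfg$photoperiod > 0 && cfg$co2_dosing > 0) {
    inc[lamps_on] <- cfg$co2_dosing / (cfg$photoperiod * 12)
  }
  control_trace(ts, lamp, air, pipe_temperature = pipe, pump_running = pump,
                co2_dosing_cumulative = cumsum(inc))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

logistic <- function(t, K, r, t0) K / (1 + exp(-r * (t - t0)))

#' Generate a sparse synthetic crop-observation series
#'
#' Total fresh fruit weight follows a logistic trajectory and the ripeness
#' fraction a delayed logistic; the red weight is their product. Each
#' destructive observation adds independent Gaussian noise (sd
#' `cfg$noise_sd` g/pot) to the total and red weights, emulating the
#' plant-to-plant variation of measuring different plants at each date;
#' the recorded ripeness fraction is recomputed from the noisy weights, so
#' it can slightly exceed 1 near full ripeness, as in real trials.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return a [crop_observations()] at `cfg$obs_days`.
#' @export
generate_crop_series <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 2L))
  t <- cfg$obs_days
  total <- logistic(t, cfg$crop$K, cfg$crop$r, cfg$crop$t0)
  rfp <- logistic(t, 1, cfg$ripening$r, cfg$ripening$t0)
  red <- total * rfp
  total_obs <- pmax(0, total + stats::rnorm(length(t), 0, cfg$noise_sd))
  red_obs <- pmax(0, pmin(red + stats::rnorm(length(t), 0, cfg$noise_sd),
                          total_obs * 1.05))
  crop_observations(t, total_obs, red_obs, cfg$dmp / 100)
}

#' Density schedule of a scenario
#' @param cfg a [scenario_config()].
#' @return a validated [density_schedule()].
#' @export
generate_density_schedule <- function(cfg) {
  density_schedule(cfg$density_events, cfg$duration)
}

#' Fit a logistic growth curve to observed weights
#'
#' Levenberg-Marquardt least squares of `K / (1 + exp(-r (t - t0)))`,
#' with data-driven starting values. Used for parameter-recovery checks of
#' the synthetic crop generator and for smoothing real destructive series.
#'
#' @param day observation days.
#' @param weight g/pot.
#' @return named vector `c(K, r, t0)`.
#' @export
fit_logistic_growth <- function(day, weight) {
  start <- list(K = max(weight) * 1.05, r = 0.1, t0 = stats::median(day))
  fit <- minpack.lm::nlsLM(weight ~ K / (1 + exp(-r * (day - t0))),
                           data = data.frame(day = day, weight = weight),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  stats::coef(fit)
}

# density templates spanning 1-3 spacing steps with trial-like average
# densities (roughly 24-39 pots/m2)
benchmark_density_templates <- function() {
  list(
    list(events = data.frame(day = c(1L, 35L, 50L, 60L), density = c(56, 42, 30, 20)),
         duration = 70L),
    list(events = data.frame(day = c(1L, 21L, 42L, 56L), density = c(56, 42, 30, 20)),
         duration = 70L),
    list(events = data.frame(day = c(1L, 20L, 45L), density = c(56, 42, 30)),
         duration = 72L),
    list(events = data.frame(day = c(1L, 30L, 55L), density = c(56, 30, 20)),
         duration = 76L),
    list(events = data.frame(day = c(1L, 20L), density = c(56, 20)),
         duration = 74L),
    list(events = data.frame(day = c(1L, 8L, 20L, 32L), density = c(56, 42, 30, 20)),
         duration = 80L)
  )
}

#' Generate a benchmark suite of synthetic cultivation bundles
#'
#' Produces `n` complete scenario bundles spanning different density
#' strategies (1-3 spacing steps, average densities in the trial's
#' observed span) and lighting intensities. Each bundle carries the
#' generated trace, schedule and crop observations plus the ground-truth
#' daily cost ledger computed at generation time, retained so downstream
#' results can be checked against an independently stored reference.
#'
#' @param n_compartments number of bundles.
#' @param seed root seed; bundle `i` uses sub-stream `seed`-derived seeds.
#' @param book a [cost_book()].
#' @param model a [price_model()].
#' @return list of `n_compartments` bundles, each a list with `team`,
#'   `cfg`, `trace`, `schedule`, `obs`, `equipment`, `ledger`, `book`,
#'   `model`.
#' @export
generate_benchmark_suite <- function(n_compartments = 6L, seed = 1L,
                                     book = cost_book(), model = price_model()) {
  if (n_compartments < 1L) stop("need at least one compartment")
  tmpl <- benchmark_density_templates()
  lamp_means <- c(80, 95, 60, 70, 50, 88)
  bundles <- vector("list", n_compartments)
  for (i in seq_len(n_compartments)) {
    k <- ((i - 1L) %% length(tmpl)) + 1L
    cfg <- scenario_config(
      seed = derive_seed(seed, 100L + i),
      duration = tmpl[[k]]$duration,
      lamp_mean = lamp_means[((i - 1L) %% length(lamp_means)) + 1L],
      density_events = tmpl[[k]]$events,
      crop = list(K = 240 + 10 * (i %% 5), r = 0.12, t0 = 45),
      ripening = list(r = 0.25, t0 = 50 + tmpl[[k]]$duration - 62)
    )
    trace <- generate_trace(cfg)
    schedule <- generate_density_schedule(cfg)
    eq <- equipment_choice(installed_intensity_from_trace(trace, book),
                           n_spacing_changes(schedule), book$lamp_max_intensity)
    bundles[[i]] <- list(team = sprintf("synth-%02d", i), cfg = cfg,
                         trace = trace, schedule = schedule,
                         obs = generate_crop_series(cfg), equipment = eq,
                         ledger = daily_cost_ledger(trace, eq, book),
                         book = book, model = model)
  }
  bundles
}
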