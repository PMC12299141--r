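# Fixture builders: all traces are constructed in code on the regular
# 5-minute grid. 2024-09-02 was a Monday; 2024-09-03 a Tuesday.

MONDAY <- "2024-09-02"
TUESDAY <- "2024-09-03"

trace_timestamps <- function(days, start = TUESDAY, tz = "Etc/GMT-2") {
  as.POSIXct(paste(start, "00:00:00"), tz = tz) + 300 * (0:(288 * days - 1))
}

make_trace <- function(days = 1, lamp = 0, air = 20, pipe = NULL, pump = NULL,
                       co2_cum = NULL, start = TUESDAY) {
  n <- 288 * days
  control_trace(trace_timestamps(days, start),
                rep_len(lamp, n), rep_len(air, n),
                pipe_temperature = if (is.null(pipe)) NULL else rep_len(pipe, n),
                pump_running = if (is.null(pump)) NULL else rep_len(pump, n),
                co2_dosing_cumulative = co2_cum)
}

trace_csv <- function(trace, path = tempfile(fileext = ".csv")) {
  write_control_trace(trace, path)
  path
}

constant_schedule <- function(days) {
  density_schedule(data.frame(day = 1L, density = 56), days)
}

# a crop series following known logistic trajectories, noiseless
logistic_obs <- function(days, K = 260, r = 0.12, t0 = 45,
                         rr = 0.25, rt0 = 55, dmp = 0.068) {
  total <- K / (1 + exp(-r * (days - t0)))
  rfp <- 1 / (1 + exp(-rr * (days - rt0)))
  crop_observations(days, total, total * rfp, dmp)
}
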