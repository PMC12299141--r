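# Table- and figure-style report views over evaluations: cost breakdowns
# per pot and per greenhouse m2, and the energy breakdown. Reports are
# pure views: they never modify the evaluations they summarize.

#' Cost breakdown per pot and per greenhouse m2
#'
#' Splits each evaluation's costs into plant, fixed, electricity, heating
#' and CO2 components. Per pot, each daily per-m2 component is weighted by
#' the area the pot occupied that day (`sum(component_d * ad)`), and the
#' plant cost is added; the non-plant components sum exactly to the
#' evaluation's `cost_per_pot`. Per m2, components are the plain sums over
#' days (EUR per m2 of greenhouse over the cultivation), which is
#' unaffected by the density schedule and so comparable across
#' compartments; the plant component there is the plant cost times the
#' average density.
#'
#' @param evaluations list of `cultivation_evaluation` objects with
#'   ledgers (full-trace path).
#' @return list of two `data.frame`s, `per_pot` and `per_m2`, one row per
#'   evaluation with columns `team, plant, fixed, electricity, heating,
#'   co2, total`.
#' @export
cost_breakdown_report <- function(evaluations) {
  if (inherits(evaluations, "cultivation_evaluation")) evaluations <- list(evaluations)
  rows <- lapply(evaluations, function(e) {
    if (is.null(e$ledger)) stop("cost breakdown needs full-trace evaluations with ledgers")
    led <- e$ledger; ad <- e$ad
    list(
      per_pot = data.frame(team = e$team,
                           plant = e$plant_cost %||% NA_real_,
                           fixed = sum(led$F * ad),
                           electricity = sum(led$Ld * ad),
                           heating = sum(led$Hd * ad),
                           co2 = sum(led$Cd * ad)),
      per_m2 = data.frame(team = e$team,
                          plant = (e$plant_cost %||% NA_real_) * e$avg_density,
                          fixed = sum(led$F),
                          electricity = sum(led$Ld),
                          heating = sum(led$Hd),
                          co2 = sum(led$Cd))
    )
  })
  per_pot <- do.call(rbind, lapply(rows, `[[`, "per_pot"))
  per_m2 <- do.call(rbind, lapply(rows, `[[`, "per_m2"))
  per_pot$total <- rowSums(per_pot[, c("plant", "fixed", "electricity", "heating", "co2")])
  per_m2$total <- rowSums(per_m2[, c("plant", "fixed", "electricity", "heating", "co2")])
  list(per_pot = per_pot, per_m2 = per_m2)
}

#' Energy breakdown per greenhouse m2
#'
#' Total lamp electricity and heating energy over the cultivation, both in
#' kWh/m2 (heating is accounted in kWh throughout; 1 kWh = 3.6 MJ), plus
#' the CO2 mass dosed.
#'
#' @param evaluations list of `cultivation_evaluation` objects with ledgers.
#' @return `data.frame(team, electricity_kwh, heating_kwh, co2_kg)`.
#' @export
energy_breakdown_report <- function(evaluations) {
  if (inherits(evaluations, "cultivation_evaluation")) evaluations <- list(evaluations)
  do.call(rbind, lapply(evaluations, function(e) {
    if (is.null(e$ledger)) stop("energy breakdown needs full-trace evaluations with ledgers")
    data.frame(team = e$team,
               electricity_kwh = sum(e$ledger$EL),
               heating_kwh = sum(e$ledger$EH),
               co2_kg = sum(e$ledger$co2_kg))
  }))
}
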