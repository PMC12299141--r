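book <- cost_book()
model <- price_model()

test_that("pot-area series and average density follow the spacing events", {
  s <- constant_schedule(70)
  expect_equal(pot_area_series(s), rep(1 / 56, 70))
  expect_equal(average_density(s), 56)

  s2 <- density_schedule(data.frame(day = c(1, 36), density = c(56, 30)), 70)
  ad <- pot_area_series(s2)
  expect_equal(sum(ad), 35 / 56 + 35 / 30)
  expect_equal(average_density(s2), 70 / (35 / 56 + 35 / 30), tolerance = 1e-12)
  expect_equal(average_density(s2), 39.07, tolerance = 1e-3)

  # any schedule's average lies between its extreme densities
  s3 <- density_schedule(data.frame(day = c(1, 10, 60), density = c(56, 42, 20)), 80)
  expect_gte(average_density(s3), 20)
  expect_lte(average_density(s3), 56)
})

test_that("summary-path net profit reproduces the published results table", {
  tab <- team_results_2024()
  np <- net_profit_summary(tab$gains, tab$cost_per_pot, tab$duration, tab$avg_density)
  expect_true(all(abs(np - tab$net_profit_printed) <= 0.01))
  expect_equal(np[tab$team == "IDEAS"], 0.346, tolerance = 1e-3)
  expect_equal(np[tab$team == "Tomatonuts"], 0.04025, tolerance = 1e-6)
})

test_that("net profit identity and monotonicity hold on random schedules", {
  set.seed(21)
  for (rep in 1:10) {
    nev <- sample(1:4, 1)
    days <- if (nev == 1) 1L else sort(c(1L, sample(2:59, nev - 1)))
    dens <- c(56, 42, 30, 20)[seq_len(nev)]
    D <- sample(60:80, 1)
    s <- density_schedule(data.frame(day = days, density = dens), D)
    led <- data.frame(day = 1:D, F = runif(D, 0.04, 0.1), Vd = runif(D, 0, 0.4))
    G <- runif(1, -0.5, 1.5)
    np <- net_profit(G, led, s)
    cost_pot <- sum((led$F + led$Vd) * pot_area_series(s))
    expect_equal(np, (G - cost_pot) * average_density(s) / D, tolerance = 1e-12)
    # strictly decreasing in any cost, strictly increasing in gains
    led_up <- led; led_up$Vd[3] <- led_up$Vd[3] + 0.1
    expect_lt(net_profit(G, led_up, s), np)
    expect_gt(net_profit(G + 0.1, led, s), np)
  }
})

test_that("a 3-day toy cultivation matches a hand-computed ledger exactly", {
  # constant 50% lamps, air 20 / pipe 45 with pump on, 0.5 min CO2 per record,
  # Tue-Thu so every day has 16 on-peak hours
  n <- 3 * 288
  tr <- make_trace(days = 3, lamp = 50, air = 20, pipe = 45, pump = TRUE,
                   co2_cum = cumsum(rep(0.5, n)), start = TUESDAY)
  s <- constant_schedule(3)
  obs <- crop_observations(3, 220, 200, 0.068)
  ev <- evaluate_cultivation(tr, s, obs, book, model, team = "toy")

  e_rec <- 0.5 * 200 / 3.2 / 1000 / 12          # kWh per record at 50%
  EL <- 288 * e_rec                              # 0.75 kWh/m2/day
  Ld <- e_rec * (192 * 0.30 + 96 * 0.20)         # 16 h on-peak, 8 h off-peak
  EH <- 288 * (2 * 25) / 1000 / 12               # 1.2 kWh/m2/day
  Hd <- EH * 0.09
  co2_day <- c(287, 288, 288) * 0.5 * 0.125 / 1000   # first increment unpriced
  F <- (18.125 + 0.07 * 100) / 365               # intensity = 50% of 200 umol
  expect_equal(ev$ledger$EL, rep(EL, 3), tolerance = 1e-12)
  expect_equal(ev$ledger$Ld, rep(Ld, 3), tolerance = 1e-12)
  expect_equal(ev$ledger$EH, rep(EH, 3), tolerance = 1e-12)
  expect_equal(ev$ledger$Hd, rep(Hd, 3), tolerance = 1e-12)
  expect_equal(ev$ledger$co2_kg, co2_day, tolerance = 1e-12)
  expect_equal(ev$ledger$F, rep(F, 3), tolerance = 1e-12)

  expect_equal(ev$price, 1.80)                   # 200 g ripe, dmp 6.8 -> low cap
  expect_equal(ev$gains, 1.05)
  cost_pot <- sum((F + Ld + Hd + co2_day * 0.30) / 56)
  expect_equal(ev$cost_per_pot, cost_pot, tolerance = 1e-12)
  expect_equal(ev$net_profit, (1.05 - cost_pot) / (3 / 56), tolerance = 1e-12)
})

test_that("zero-input traces accrue only fixed costs", {
  tr <- make_trace(days = 2, lamp = 0, air = 20)
  s <- constant_schedule(2)
  ev <- evaluate_cultivation(tr, s, crop_observations(2, 200, 180, 0.07),
                             book, model)
  expect_equal(ev$ledger$Vd, c(0, 0))
  expect_equal(ev$cost_per_pot, 2 * (18.125 / 365) / 56, tolerance = 1e-12)
})

test_that("a brute-force per-record recomputation matches the evaluation", {
  set.seed(99)
  D <- 5L; n <- D * 288L
  lamp <- pmin(100, pmax(0, rnorm(n, 40, 30)))
  air <- rnorm(n, 20, 1)
  pipe <- air + rnorm(n, 6, 4)
  cum <- cumsum(runif(n, 0, 0.3))
  tr <- make_trace(days = D, lamp = lamp, air = air, pipe = pipe, pump = TRUE,
                   co2_cum = cum)
  s <- density_schedule(data.frame(day = c(1, 3), density = c(56, 42)), D)
  obs <- crop_observations(D, 230, 200, 0.072)
  ev <- evaluate_cultivation(tr, s, obs, book, model)

  # independent oracle: one pass over the records, then the objective
  tot <- 0
  Fd <- (18.125 + 0.07 * max(lamp) / 100 * 200 + 1.50 * 1) / 365
  ad <- c(rep(1 / 56, 2), rep(1 / 42, 3))
  for (i in seq_len(n)) {
    d <- (i - 1) %/% 288 + 1
    lt <- as.POSIXlt(tr$timestamp[i], tz = "Europe/Amsterdam")
    peak <- lt$wday %in% 1:5 && lt$hour >= 7 && lt$hour < 23
    e <- lamp[i] / 100 * 200 / 3.2 / 1000 / 12
    v <- e * (if (peak) 0.3 else 0.2) +
      2 * max(0, pipe[i] - air[i]) / 1000 / 12 * 0.09 +
      (if (i == 1) 0 else max(0, cum[i] - cum[i - 1])) * 0.125 / 1000 * 0.30
    tot <- tot + v * ad[d]
  }
  tot <- tot + Fd * sum(ad)
  G <- pot_price(200, 7.2, 200 / 230, model) - 0.75
  expect_equal(ev$net_profit, (G - tot) / sum(ad), tolerance = 1e-12)
})

test_that("annualized yield and light use efficiency match their definitions", {
  expect_equal(annualized_yield(219, 39.7, 70), 45.3, tolerance = 0.05)
  expect_equal(round(annualized_yield(268, 33.4, 80)), 41)
  expect_equal(annualized_yield(200, 40, 70), 2 * annualized_yield(200, 20, 70))

  expect_equal(light_use_efficiency(8694, 791), 10.99, tolerance = 0.01)
  expect_equal(light_use_efficiency(0, 100), 0)
  expect_equal(light_use_efficiency(500, 50), light_use_efficiency(1000, 100))
  expect_error(light_use_efficiency(100, 0), "positive")
})

test_that("teams rank by net profit with cost per pot breaking ties", {
  ranked <- rank_teams(team_results_2024())
  expect_equal(ranked$team,
               c("IDEAS", "MuGrow", "Trigger", "Reference", "Agrifusion", "Tomatonuts"))
  # Trigger (0.73 cost) edges Reference (0.67)? both print 0.13 but the
  # unrounded objective separates them: 0.1336 vs 0.1299
  expect_gt(ranked$net_profit[3], ranked$net_profit[4])

  one <- rank_teams(team_results_2024()[1, ])
  expect_equal(nrow(one), 1L)

  tie <- data.frame(team = c("a", "b"), gains = c(1.0, 1.25),
                    cost_per_pot = c(0.5, 0.75), duration = c(70, 70),
                    avg_density = c(28, 28))
  expect_equal(rank_teams(tie)$team, c("a", "b"))  # equal profit, lower cost first
})
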