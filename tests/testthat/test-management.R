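test_that("a year without growth yields no harvest and no events", {
  met <- constant_meteo(1, temp = -10, precip = 1, rad = 40)
  st <- grass_state(1, shoot = 400, root = 400)
  out <- simulate_cut_year(st, met, 1:365, 380, 0)
  expect_equal(out$y_cut, 0)
  expect_equal(out$events, 0)
})

test_that("cut bookkeeping identity holds on favorable forcing", {
  met <- seasonal_meteo(1)
  st <- grass_state(1, shoot = 600, root = 600, water = 150)
  mp <- management_params()
  out <- simulate_cut_year(st, met, 1:365, 380, 50, mp)
  expect_gte(out$events, 2)
  # Y_cut equals the sum of standing biomass at each cut minus the residual
  expect_equal(out$y_cut, out$cut_biomass - out$events * mp$cut_residual,
               tolerance = 1e-9)
  expect_ledger_balanced(out$ledger)
})

test_that("an infinite trigger leaves a single end-of-season salvage cut", {
  met <- seasonal_meteo(1)
  st <- grass_state(1, shoot = 600, root = 600, water = 150)
  mp <- management_params(cut_trigger = Inf)
  out <- simulate_cut_year(st, met, 1:365, 380, 50, mp)
  expect_equal(out$events, 1)
  expect_gt(out$y_cut, 0)
})

test_that("raising the mowing trigger never increases the event count", {
  met <- seasonal_meteo(1)
  st <- grass_state(1, shoot = 600, root = 600, water = 150)
  ev <- vapply(c(1200, 2000, 3000, 6000), function(trig) {
    simulate_cut_year(st, met, 1:365, 380, 50,
                      management_params(cut_trigger = trig))$events
  }, numeric(1))
  expect_true(all(diff(ev) <= 0))
})

test_that("grazing respects stocking, thresholds and the recovery rule", {
  met <- seasonal_meteo(1)
  st <- grass_state(1, shoot = 600, root = 600, water = 150)
  mp <- management_params()

  # S = 0: nothing ingested, animals out the whole grazing season
  cut <- simulate_cut_year(st, met, 1:365, 380, 50, mp)
  gw <- graze_window(vegetation_mask(cut$growth), cut$shoot,
                     mp$graze_threshold)
  z <- simulate_grazed_year(st, met, 1:365, 380, 50, 0, mp,
                            veg_mask = gw$window)
  expect_equal(z$y_graze, 0)
  expect_equal(z$graze_days, sum(gw$window))
  expect_equal(z$graze_days + gw$t_farm, 365)

  # biomass that never exceeds the threshold is never grazed
  low <- simulate_grazed_year(grass_state(1, shoot = 100, root = 100),
                              constant_meteo(1, temp = -10, rad = 40),
                              1:365, 380, 0, 2, mp)
  expect_equal(low$y_graze, 0)
  expect_equal(low$graze_days, 0)

  # intake cap is exact: Y_graze <= grazing days x IC x S
  for (s in c(0.5, 2, 10)) {
    g <- simulate_grazed_year(st, met, 1:365, 380, 50, s, mp,
                              veg_mask = gw$window)
    expect_lte(g$y_graze, g$graze_days * mp$ic * s + 1e-9)
    expect_ledger_balanced(g$ledger)
  }

  # overstocking: ingestion plateaus at what the sward can produce,
  # far below the herd's intake capacity
  big <- simulate_grazed_year(st, met, 1:365, 380, 50, 50, mp,
                              veg_mask = gw$window)
  big2 <- simulate_grazed_year(st, met, 1:365, 380, 50, 10, mp,
                               veg_mask = gw$window)
  expect_equal(big$y_graze, big2$y_graze, tolerance = 1e-6)
  expect_lt(big$y_graze, 0.1 * big$graze_days * mp$ic * 50)
})

test_that("indoor period complements the smoothed positive-growth run", {
  growth <- matrix(0, 365, 3)
  growth[100:250, 1] <- 1          # 151-day season -> T_farm = 214
  growth[, 2] <- 1                 # year-round growth
  expect_equal(indoor_period(growth), c(214, 0, 365))

  # smoothing bridges <= 2-day gaps and removes <= 2-day spikes
  g2 <- matrix(0, 365, 1)
  g2[100:250, 1] <- 1
  g2[150:151, 1] <- 0              # short gap inside the season
  g2[300, 1] <- 1                  # isolated spike
  expect_equal(indoor_period(g2), 214)
})

test_that("graze window opens at turn-out and closes with the season", {
  growth <- matrix(0, 365, 1)
  growth[100:250, 1] <- 1
  shoot <- matrix(0, 365, 1)
  shoot[120:365, 1] <- 500         # biomass passes 300 only on day 120
  gw <- graze_window(vegetation_mask(growth), shoot, 300)
  expect_equal(unname(colSums(gw$window)), 131)   # days 120..250
  expect_equal(unname(gw$t_farm), 365 - 131)
  expect_true(all(which(gw$window[, 1]) >= 120))
})

test_that("mass is conserved through combined annual simulations", {
  # stochastic forcing, both management modes, all three zones
  st <- fx$sp$state
  cut <- simulate_cut_year(st, fx$met2, 366:730, 380, 30)
  expect_ledger_balanced(cut$ledger)
  gr <- simulate_grazed_year(st, fx$met2, 366:730, 380, 30, 1.5)
  expect_ledger_balanced(gr$ledger)
  expect_error(simulate_grazed_year(st, fx$met2, 366:730, 380, 30, -1),
               "non-negative")
})
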