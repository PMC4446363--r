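test_that("spin-up converges to near-zero NEE and reports its loops", {
  expect_true(fx$sp$converged)
  expect_true(all(abs(fx$sp$nee) < 1))

  # an equilibrated state passes in a single loop
  again <- spinup(fx$sp$state, fx$met2, 1, 296, 20)
  expect_equal(again$loops, 1)

  # an unreachable criterion errors rather than silently returning
  expect_error(spinup(grass_state(3), fx$met2, 1, 296, 20, tol = 0,
                      max_loops = 3), "did not converge")
})

test_that("trend estimation matches closed-form least squares", {
  const <- trend(c(2, 2, 2, 2))
  expect_equal(const$slope, 0)
  expect_equal(const$p_value, 1)

  lin <- trend(c(100, 101, 102, 103))
  expect_equal(lin$slope, 1, tolerance = 1e-12)
  expect_equal(lin$percent_per_year, 100 / 101.5, tolerance = 1e-12)
  expect_lt(lin$p_value, 0.001)

  # slope 0.02 on a mean-2 series is 1% per year
  y <- 2 + 0.02 * (1:10 - mean(1:10))
  expect_equal(trend(y)$percent_per_year, 1, tolerance = 1e-10)

  expect_error(trend(c(1, 2)), "3 years")
})

test_that("attribution arithmetic decomposes trend differences", {
  at <- attribute(1.62e-2, 0.06e-2, 1.67e-2, 1.38e-2)
  expect_equal(unname(at$contributions["co2"]), 1.56e-2)
  expect_equal(unname(at$contributions["climate"]), -0.05e-2)
  expect_equal(unname(at$contributions["nitrogen"]), 0.24e-2,
               tolerance = 1e-12)
  expect_equal(at$total, sum(at$contributions))
  expect_equal(unname(at$percentages["co2"]), 100 * 1.56 / 1.62,
               tolerance = 1e-9)

  same <- attribute(1, 1, 1, 1)
  expect_true(all(same$percentages == 0))

  zero <- attribute(0, 1, 1, 1)
  expect_true(zero$undefined)
  expect_true(all(is.na(zero$percentages)))
})

test_that("the uncertainty ensemble enumerates the 2^4 factorial design", {
  ens <- build_ensemble(photosynthesis_params())
  expect_equal(length(ens$members), 16)
  expect_equal(nrow(unique(ens$design)), 16)

  # printed parameter bounds: +/-20% relative, n_addmax +/-0.2 absolute
  expect_equal(sort(unique(ens$design$a)), c(0.6, 0.9))
  expect_equal(sort(unique(ens$design$n_addmax)), c(0.4, 0.8))
  expect_equal(sort(unique(ens$design$sla_max)), c(0.0384, 0.0576))
  vc <- sort(unique(vapply(ens$members, `[[`, numeric(1), "vcmax_base")))
  jm <- sort(unique(vapply(ens$members, `[[`, numeric(1), "jmax_base")))
  expect_equal(vc, c(44, 66))
  expect_equal(jm, c(88, 132))
  # capacities move jointly: jmax/vcmax ratio preserved in every member
  for (m in ens$members) expect_equal(unname(m$jmax_base / m$vcmax_base), 2)

  # the all-minimum member exists exactly once
  mins <- vapply(ens$members, function(m) {
    isTRUE(all.equal(c(m$a, m$n_addmax, m$vcmax_base, m$sla_max),
                     c(0.6, 0.4, 44, 0.0384), tolerance = 1e-12))
  }, logical(1))
  expect_equal(sum(mins), 1)

  # member spread: order-invariant, zero for a constant response
  f <- function(m) m$vcmax_base + 100 * m$a
  sd1 <- ensemble_apply(ens, f)$sd
  ens_rev <- ens
  ens_rev$members <- rev(ens$members)
  expect_equal(ensemble_apply(ens_rev, f)$sd, sd1)
  expect_equal(ensemble_apply(ens, function(m) 1)$sd, 0)
})

test_that("protocol runs produce shaped, stationary-null trajectories", {
  grid <- generate_grid(1, 1, seed = 9)
  grid$zone <- "temperate"
  met <- tile_meteo(generate_meteo(grid, 1, seed = 13), 15)
  cfg <- protocol_config(spinup_window = 1:2, hist_window = 3:5,
                         analysis_window = 6:15)
  res <- run_protocol(grid, list(meteo = met, co2 = 340, n_amount = 40), cfg,
                      experiments = "e4")
  tr <- res$e4$trajectory
  expect_equal(nrow(tr), 10)          # one record per analysis year per cell
  expect_true(all(c("y_cut", "y_graze", "npp", "d_opt", "f_opt",
                    "s_opt") %in% names(tr)))
  expect_true(all(tr$graze_days + tr$t_farm <= 365))
  # all drivers constant: productivity trend is null (deterministic forcing)
  ps <- productivity_series(tr, grid)
  expect_lt(abs(trend(ps$productivity)$percent_per_year), 0.2)

  expect_error(run_protocol(grid, list(meteo = met, co2 = 340,
                                       n_amount = 40),
                            protocol_config(analysis_window = 6:50)),
               "missing years")
})

test_that("the pipeline is seeded end-to-end", {
  grid <- generate_grid(2, 2, seed = 3)
  f1 <- synthetic_forcing(grid, 3, seed = 21)
  f2 <- synthetic_forcing(grid, 3, seed = 21)
  f3 <- synthetic_forcing(grid, 3, seed = 22)
  expect_identical(f1$meteo, f2$meteo)
  expect_identical(f1$n_amount, f2$n_amount)
  expect_identical(f1$co2, f2$co2)
  expect_false(identical(f1$meteo$temp, f3$meteo$temp))
  # CO2 starts at the 1900-level default
  expect_equal(f1$co2[1], 296)
})
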