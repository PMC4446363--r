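# Shared fixtures, built once per test run. The 3-cell strip spans the
# three climate zones (mediterranean, temperate, cold).
fx <- new.env()
fx$grid3 <- generate_grid(3, 1, seed = 2)
fx$met2 <- generate_meteo(fx$grid3, 2, seed = 3)
fx$sp <- spinup(grass_state(3), fx$met2, 1, 296, 20)

# single-cell view of a daily_meteo
submet <- function(met, j) {
  structure(list(temp = met$temp[, j, drop = FALSE],
                 precip = met$precip[, j, drop = FALSE],
                 rad = met$rad[, j, drop = FALSE],
                 rh = met$rh[, j, drop = FALSE],
                 years = met$years, doy = met$doy, year = met$year),
            class = "daily_meteo")
}

# deterministic constant weather (growth possible every day)
constant_meteo <- function(ncell = 1, years = 1, temp = 18, precip = 3,
                           rad = 250, rh = 0.7) {
  nd <- 365L * years
  m <- function(v) matrix(v, nd, ncell)
  structure(list(temp = m(temp), precip = m(precip), rad = m(rad),
                 rh = m(rh), years = years,
                 doy = rep(seq_len(365L), years),
                 year = rep(seq_len(years), each = 365L)),
            class = "daily_meteo")
}

# deterministic weather with an explicit winter (no growth outside
# days [gs_start, gs_end])
seasonal_meteo <- function(ncell = 1, years = 1, gs_start = 100,
                           gs_end = 265, temp = 18, precip = 3) {
  met <- constant_meteo(ncell, years, temp = temp, precip = precip)
  winter <- !(met$doy >= gs_start & met$doy <= gs_end)
  met$temp[winter, ] <- -10
  met$rad[winter, ] <- 40
  met
}

# closed-form farm optimum for S-independent yields
closed_form_opt <- function(y_graze, y_cut, t_farm, ic = 13) {
  s <- y_graze / (ic * (365 - t_farm))
  f <- y_cut / (ic * t_farm * s + y_cut)
  list(s = s, f = f, d = s * f)
}

expect_ledger_balanced <- function(ledger, tol = 1e-6) {
  removed <- if (!is.null(ledger$removed)) ledger$removed else
    ledger$ingested + ledger$trampled
  lhs <- ledger$initial + ledger$grown - ledger$drained -
    ledger$senesced - removed
  expect_equal(lhs, ledger$final, tolerance = tol)
}
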