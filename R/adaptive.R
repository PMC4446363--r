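#' Year-end forage surplus or deficit
#'
#' Per hectare of farm: `X'_i = Y_cut,i * (1 - F_opt)` is the conserved
#' forage produced on the cut fraction and `X_i = IC * T_farm * S_opt *
#' F_opt` the indoor feed demand of the grazing herd; their difference is the
#' surplus (positive) or deficit (negative) that drives next year's density
#' adjustment.
#'
#' @param y_cut annual cut yield per mown hectare (kg DM ha-1 yr-1)
#' @param t_farm indoor period (days)
#' @param farm a `farm_optimum` (current S_opt, F_opt)
#' @param mp [management_params()]
#' @return list `dm` (= X' - X), `x_prod`, `x_need` (kg DM per farm ha)
#' @export
forage_balance <- function(y_cut, t_farm, farm, mp = management_params()) {
  x_prod <- y_cut * (1 - farm$f_opt)
  x_need <- mp$ic * t_farm * farm$s_opt * farm$f_opt
  list(dm = x_prod - x_need, x_prod = x_prod, x_need = x_need)
}

#' Realized year-end density change
#'
#' The maximal density change a year's forage balance could support is
#' `dM / IC / 365`; the farmer realizes only a fraction `alpha` of it
#' (default 0.2, a moderate-risk response equivalent to tracking a roughly
#' five-year mean productivity).
#'
#' @param dm forage surplus/deficit (kg DM per farm ha)
#' @param mp [management_params()] (supplies IC)
#' @param alpha realized fraction in [0,1]; defaults to `mp$alpha`
#' @return density change (LSU ha-1), same sign as `dm`
#' @export
density_step <- function(dm, mp = management_params(), alpha = mp$alpha) {
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha must lie in [0,1]")
  dm / mp$ic / 365 * alpha
}

#' Apply a density change to a farm
#'
#' The new density `D = max(0, D + dD)` is realized by adjusting the grazed
#' fraction at fixed stocking rate (`F = D / S`); if that would push F beyond
#' 1 (all land grazed), F is clipped to 1 and the stocking rate is raised so
#' that D remains continuous.
#'
#' @param farm a `farm_optimum`
#' @param dd density change (LSU ha-1), per cell
#' @return updated `farm_optimum`
#' @export
update_farm <- function(farm, dd) {
  d_new <- pmax(0, farm$d_opt + dd)
  s <- farm$s_opt
  f <- ifelse(s > 0, d_new / s, 0)
  over <- f > 1
  f[over] <- 1
  s[over] <- d_new[over]
  zero <- d_new <= 0
  f[zero] <- 0
  farm$d_opt <- d_new
  farm$f_opt <- f
  farm$s_opt <- s
  farm
}

#' Run the adaptive-management loop over a sequence of years
#'
#' Each year the cut fraction and the grazed fraction of every cell are
#' simulated on their own parcels (cut land animal-free, grazed land at the
#' current stocking rate); at year end the forage balance updates the
#' livestock density for the next year.
#'
#' @param state initial `grass_state`
#' @param farm initial `farm_optimum` (from [solve_optimum()])
#' @param meteo a `daily_meteo`
#' @param years integer vector of year indices into `meteo`
#' @param co2 ppm per year (recycled to `length(years)`)
#' @param n_amount matrix years x cells (or vector, recycled)
#' @param mp,pp,pg parameter sets
#' @param labels optional year labels for the output table
#' @param state_graze optional separate initial state for the grazed
#'   parcels (defaults to `state`, e.g. when both sides start equilibrated)
#' @return list: `trajectory` data.frame (year, cell, y_cut, y_graze, npp,
#'   t_farm, x_prod, x_need, dm, dd, d_opt, f_opt, s_opt), `state`, `farm`
#'   (end of run)
#' @export
run_adaptive <- function(state, farm, meteo, years, co2, n_amount,
                         mp = management_params(),
                         pp = photosynthesis_params(),
                         pg = growth_params(), labels = years,
                         state_graze = NULL) {
  n <- length(state$shoot)
  co2 <- rep_len(co2, length(years))
  n_amount <- if (is.matrix(n_amount)) n_amount else
    matrix(rep(n_amount, length.out = n), length(years), n, byrow = TRUE)
  # cut and grazed parcels carry their own biomass state
  st_cut <- state
  st_graze <- if (is.null(state_graze)) state else state_graze
  rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    days <- (years[i] - 1L) * 365L + seq_len(365L)
    cut <- simulate_cut_year(st_cut, meteo, days, co2[i], n_amount[i, ],
                             mp, pp, pg)
    gw <- graze_window(vegetation_mask(cut$growth), cut$shoot,
                       mp$graze_threshold)
    gr <- simulate_grazed_year(st_graze, meteo, days, co2[i], n_amount[i, ],
                               farm$s_opt, mp, pp, pg, veg_mask = gw$window)
    st_cut <- cut$state
    st_graze <- gr$state
    t_farm <- gw$t_farm
    bal <- forage_balance(cut$y_cut, t_farm, farm, mp)
    dd <- density_step(bal$dm, mp)
    rows[[i]] <- data.frame(
      year = labels[i], cell = seq_len(n), y_cut = cut$y_cut,
      y_graze = gr$y_graze,
      npp = farm$f_opt * gr$npp + (1 - farm$f_opt) * cut$npp,
      t_farm = t_farm, x_prod = bal$x_prod, x_need = bal$x_need,
      dm = bal$dm, dd = dd, d_opt = farm$d_opt, f_opt = farm$f_opt,
      s_opt = farm$s_opt, mow_events = cut$events,
      graze_days = gr$graze_days)
    farm <- update_farm(farm, dd)
  }
  list(trajectory = do.call(rbind, rows), state_cut = st_cut,
       state_graze = st_graze, farm = farm)
}
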