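#' Photosynthesis parameter set
#'
#' Base (unfertilized) photosynthetic capacities and the constants of the
#' saturating nitrogen-response curve. `vcmax_base` and `jmax_base` are the
#' optimum-temperature maximum Rubisco carboxylation and electron-transport
#' rates before any nitrogen enhancement; `a` controls the shape of the
#' saturating response and `n_addmax` its asymptote (the maximal fractional
#' increase of photosynthetic capacity under very high nitrogen supply).
#'
#' @param vcmax_base,jmax_base umol m-2 s-1 (defaults 55 / 110)
#' @param sla_max maximum specific leaf area, m2 gC-1 (default 0.048)
#' @param a unitless shape constant in (0,1) (default 0.75)
#' @param n_addmax asymptotic fractional response in (0,1] (default 0.6)
#' @return a `photosynthesis_params` list
#' @export
photosynthesis_params <- function(vcmax_base = 55, jmax_base = 110,
                                  sla_max = 0.048, a = 0.75, n_addmax = 0.6) {
  p <- list(vcmax_base = vcmax_base, jmax_base = jmax_base,
            sla_max = sla_max, a = a, n_addmax = n_addmax)
  if (a <= 0 || a >= 1) stop("a must lie in (0,1)")
  if (n_addmax <= 0 || n_addmax > 1) stop("n_addmax must lie in (0,1]")
  if (any(unlist(p) <= 0)) stop("all photosynthesis parameters must be positive")
  class(p) <- "photosynthesis_params"
  p
}

#' Fractional photosynthetic-capacity response to nitrogen addition
#'
#' Saturating exponential response
#' `N_add = n_addmax * (1 - a^(N_amount/30))`, monotone non-decreasing in the
#' annual nitrogen addition and bounded by `n_addmax`. With the standard
#' constants, capacity rises by about 60\% under very high nitrogen supply.
#'
#' @param n_amount annual nitrogen addition, kg N ha-1 yr-1 (>= 0); the sum
#'   of organic and mineral fertilization and atmospheric deposition
#' @param params a [photosynthesis_params()] set
#' @return unitless multiplier increment in `[0, n_addmax)`
#' @export
nitrogen_response <- function(n_amount, params = photosynthesis_params()) {
  if (any(n_amount < 0)) stop("n_amount must be non-negative")
  params$n_addmax * (1 - params$a^(n_amount / 30))
}

#' Nitrogen-enhanced photosynthetic capacities
#'
#' Applies the additive capacity increase: `vcmax = (1 + n_add) * vcmax_base`
#' and likewise for `jmax`.
#'
#' @param params a [photosynthesis_params()] set
#' @param n_add fractional increase from [nitrogen_response()], in
#'   `[0, n_addmax]`
#' @return list with elements `vcmax`, `jmax` (umol m-2 s-1)
#' @export
effective_photosynthesis_params <- function(params, n_add) {
  if (any(n_add < 0) || any(n_add > params$n_addmax + 1e-12)) {
    stop("n_add must lie in [0, n_addmax]")
  }
  list(vcmax = (1 + n_add) * params$vcmax_base,
       jmax = (1 + n_add) * params$jmax_base)
}

#' Growth substrate constants
#'
#' Tunable constants of the minimal daily growth substrate: big-leaf light
#' response, piecewise thermal optimum, bucket soil water, saturating CO2
#' response (normalized to 1 at 380 ppm), fixed shoot:root allocation and
#' first-order senescence/turnover, plus a single litter pool whose
#' decomposition closes the ecosystem carbon balance (NEE proxy).
#'
#' @param c_vcmax,c_jmax conversion from capacity (umol m-2 s-1) to a daily
#'   canopy assimilation ceiling (g C m-2 d-1 per unit capacity)
#' @param k_ext canopy light-extinction coefficient on LAI
#' @param rad_half radiation half-saturation (W m-2)
#' @param t_opt,t_width thermal optimum (degC) and width of the quadratic
#'   response (zero below about -5 degC for the defaults)
#' @param co2_half Michaelis constant of the CO2 response (ppm)
#' @param resp_frac growth-respiration fraction of GPP
#' @param rm_coef maintenance respiration per gC biomass per day at t_opt
#' @param alloc_shoot fraction of positive NPP allocated to shoots (rest to
#'   roots)
#' @param sen_base,sen_stress baseline and stress-dependent daily shoot
#'   senescence rates; `root_turn` daily root turnover
#' @param k_litter litter decomposition rate per day at t_opt
#' @param soil_cap bucket capacity (mm); `fw_half` fraction of capacity at
#'   which water stress reaches 1; `drain_frac` daily fractional water loss
#'   to drainage and bare-soil evaporation
#' @param shoot_floor protected crown/stubble biomass (kg DM ha-1) that
#'   neither senescence nor carbon drain can remove, so swards regrow after
#'   winter dieback
#' @param carbon_frac g C per g dry matter
#' @return a `growth_params` list
#' @export
growth_params <- function(c_vcmax = 0.15, c_jmax = 0.075, k_ext = 0.5,
                          rad_half = 120, t_opt = 18, t_width = 23,
                          co2_half = 300, resp_frac = 0.35, rm_coef = 0.002,
                          alloc_shoot = 0.6, sen_base = 0.006,
                          sen_stress = 0.03, root_turn = 0.004,
                          k_litter = 0.0035, soil_cap = 150, fw_half = 0.4,
                          drain_frac = 0.012, shoot_floor = 30,
                          carbon_frac = 0.45) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) > 0), alloc_shoot < 1, resp_frac < 1)
  class(p) <- "growth_params"
  p
}

#' Initialize per-cell grass state
#'
#' @param n number of cells
#' @param shoot,root initial biomass pools (kg DM ha-1)
#' @param litter initial litter carbon (g C m-2)
#' @param water initial soil water (mm); default half capacity
#' @param gp [growth_params()]
#' @return a `grass_state` list of length-`n` numeric vectors
#' @export
grass_state <- function(n, shoot = 500, root = 500, litter = 200,
                        water = NULL, gp = growth_params()) {
  if (is.null(water)) water <- gp$soil_cap / 2
  st <- list(shoot = rep(shoot, n), root = rep(root, n),
             litter = rep(litter, n), water = rep(water, n),
             npp_year = rep(0, n))
  class(st) <- "grass_state"
  st
}

# kg DM/ha shoot -> m2/m2 leaf area (via carbon fraction and SLA)
lai_from_shoot <- function(shoot, sla_max, carbon_frac = 0.45) {
  shoot * 0.1 * carbon_frac * sla_max
}

#' Convert between areal carbon and dry-matter stocks
#'
#' Uses a carbon fraction of 0.45 g C per g DM and 1 g C m-2 = 10 kg C ha-1,
#' so 450 g C m-2 corresponds to 10 t DM ha-1.
#'
#' @param value non-negative stock
#' @param direction `"c_to_dm"`: g C m-2 -> t DM ha-1; `"dm_to_c"`: the
#'   inverse
#' @param carbon_frac g C per g DM
#' @return converted value
#' @export
dm_carbon_convert <- function(value, direction = c("c_to_dm", "dm_to_c"),
                              carbon_frac = 0.45) {
  direction <- match.arg(direction)
  if (any(value < 0)) stop("value must be non-negative")
  switch(direction,
    c_to_dm = value * 10 / carbon_frac / 1000,
    dm_to_c = value * 1000 * carbon_frac / 10
  )
}

#' Advance the grass substrate by one day
#'
#' Daily gross primary production is the minimum of a light/electron-transport
#' limited rate and a Rubisco-limited rate, attenuated by canopy closure,
#' a piecewise thermal optimum, bucket-soil water stress, the nitrogen
#' capacity enhancement and a saturating CO2 response normalized to 1 at
#' 380 ppm. NPP = GPP minus growth and maintenance respiration; positive NPP
#' is allocated shoot:root, negative NPP drains root then shoot. First-order
#' senescence feeds a litter pool whose decomposition is the heterotrophic
#' respiration of the NEE proxy.
#'
#' All state vectors are per cell, so one call advances every cell at once.
#'
#' @param state a `grass_state`
#' @param temp,precip,rad,rh per-cell meteorology vectors for the day
#' @param co2 atmospheric CO2 (ppm, scalar)
#' @param eff effective capacities from [effective_photosynthesis_params()]
#' @param pp [photosynthesis_params()] (for SLA)
#' @param gp [growth_params()]
#' @return list `state` (updated) and `fluxes` (`gpp`, `resp`, `npp` in
#'   g C m-2 d-1; `senescence` kg DM ha-1 d-1; `et` mm d-1; `rh_soil`
#'   heterotrophic respiration g C m-2 d-1; `growth` shoot growth
#'   kg DM ha-1 d-1)
#' @export
step_day <- function(state, temp, precip, rad, rh, co2, eff,
                     pp = photosynthesis_params(), gp = growth_params()) {
  if (any(!is.finite(c(temp, precip, rad, rh, co2)))) {
    stop("non-finite meteorology or CO2")
  }
  lai <- lai_from_shoot(state$shoot, pp$sla_max, gp$carbon_frac)
  canopy <- 1 - exp(-gp$k_ext * lai)

  f_t <- pmax(0, 1 - ((temp - gp$t_opt) / gp$t_width)^2)
  f_w <- pmin(1, state$water / (gp$fw_half * gp$soil_cap))
  f_co2 <- (co2 / (co2 + gp$co2_half)) / (380 / (380 + gp$co2_half))
  f_light <- rad / (rad + gp$rad_half)

  a_light <- gp$c_jmax * eff$jmax * f_light
  a_rub <- gp$c_vcmax * eff$vcmax
  gpp <- pmin(a_light, a_rub) * canopy * f_t * f_w * f_co2

  biomass_c <- (state$shoot + state$root) * 0.1 * gp$carbon_frac  # g C m-2
  f_resp <- 2^((pmin(temp, 40) - gp$t_opt) / 10)
  rm <- gp$rm_coef * biomass_c * f_resp
  resp <- gp$resp_frac * gpp + rm
  npp <- gpp - resp

  # pools in kg DM/ha; 1 g C m-2 = 10/carbon_frac kg DM/ha
  c2dm <- 10 / gp$carbon_frac
  growth_dm <- pmax(npp, 0) * c2dm
  deficit_dm <- pmax(-npp, 0) * c2dm

  shoot <- state$shoot + gp$alloc_shoot * growth_dm
  root <- state$root + (1 - gp$alloc_shoot) * growth_dm
  # negative NPP: draw down root first, then shoot (exact amounts kept for
  # the mass ledger); the crown/stubble floor is untouchable
  from_root <- pmin(root, deficit_dm)
  root <- root - from_root
  from_shoot <- pmin(pmax(shoot - gp$shoot_floor, 0), deficit_dm - from_root)
  shoot <- shoot - from_shoot

  sen_rate <- gp$sen_base + gp$sen_stress * (1 - f_t)
  sen_shoot <- pmax(shoot - gp$shoot_floor, 0) * sen_rate
  sen_root <- root * gp$root_turn
  shoot <- shoot - sen_shoot
  root <- root - sen_root

  litter_in <- (sen_shoot + sen_root) / c2dm          # g C m-2
  rh_soil <- gp$k_litter * f_resp * state$litter
  litter <- state$litter + litter_in - rh_soil

  pet <- (0.013 * rad + 0.06 * pmax(temp, 0)) * (1.3 - rh)
  et <- pmin(state$water, pet * pmax(canopy, 0.3))
  drain <- gp$drain_frac * (state$water - et)
  water <- pmin(gp$soil_cap, state$water + precip - et - drain)

  state$shoot <- shoot
  state$root <- root
  state$litter <- pmax(litter, 0)
  state$water <- pmax(water, 0)
  state$npp_year <- state$npp_year + npp

  list(state = state,
       fluxes = list(gpp = gpp, resp = resp, npp = npp,
                     senescence = sen_shoot + sen_root, et = et,
                     rh_soil = rh_soil,
                     # shoot-pool ledger terms (kg DM/ha/d)
                     alloc_shoot_dm = gp$alloc_shoot * growth_dm,
                     shoot_drain_dm = from_shoot,
                     sen_shoot_dm = sen_shoot,
                     growth = gp$alloc_shoot * growth_dm - sen_shoot))
}

#' Simulate unmanaged growth for one year
#'
#' Steps the substrate through 365 days without any management and returns
#' daily traces needed by the management layer.
#'
#' @param state a `grass_state`
#' @param meteo a `daily_meteo`; `days` selects the rows of the year
#' @param days integer vector of 365 row indices into `meteo`
#' @param co2 ppm (scalar for the year)
#' @param n_amount per-cell annual nitrogen addition (kg N ha-1 yr-1)
#' @param pp,gp parameter sets
#' @return list: `state` (end of year), `npp` (annual g C m-2 yr-1 per cell),
#'   `growth` (365 x ncell matrix of daily net shoot growth, kg DM ha-1 d-1),
#'   `shoot` (365 x ncell end-of-day shoot biomass), `nee` (annual NEE proxy,
#'   g C m-2 yr-1, positive = carbon source)
#' @export
simulate_growth_year <- function(state, meteo, days, co2, n_amount,
                                 pp = photosynthesis_params(),
                                 gp = growth_params()) {
  n <- length(state$shoot)
  state$npp_year <- rep(0, n)
  n_add <- nitrogen_response(n_amount, pp)
  eff <- effective_photosynthesis_params(pp, n_add)
  growth <- shoot <- matrix(0, length(days), n)
  nee <- rep(0, n)
  for (k in seq_along(days)) {
    d <- days[k]
    res <- step_day(state, meteo$temp[d, ], meteo$precip[d, ],
                    meteo$rad[d, ], meteo$rh[d, ], co2, eff, pp, gp)
    state <- res$state
    growth[k, ] <- res$fluxes$growth
    shoot[k, ] <- state$shoot
    nee <- nee + res$fluxes$rh_soil - res$fluxes$npp
  }
  list(state = state, npp = state$npp_year, growth = growth,
       shoot = shoot, nee = nee)
}
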