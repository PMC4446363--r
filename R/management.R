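#' Management rule parameters
#'
#' @param ic daily dry-matter intake capacity per livestock unit
#'   (kg DM LSU-1 d-1, default 13; 1 LSU is the grazing equivalent of one
#'   adult dairy cow producing 3000 kg milk per year without concentrate
#'   feed)
#' @param graze_threshold shoot biomass below which grazing stops and above
#'   which recovery is counted (kg DM ha-1, default 300)
#' @param recovery_days consecutive days above the threshold required before
#'   grazing resumes (default 15)
#' @param cut_trigger shoot biomass that triggers a mowing event
#'   (kg DM ha-1)
#' @param cut_residual stubble left after mowing (kg DM ha-1, < trigger)
#' @param min_salvage minimum removable biomass above the residual for the
#'   end-of-season salvage cut (kg DM ha-1)
#' @param use_efficiency fraction of biomass removed by grazing that is
#'   actually ingested; the remainder is lost to trampling and fouling
#' @param alpha fraction of the maximal year-end density correction realized
#'   by the farmer (default 0.2, the response to a roughly 5-year mean)
#' @return a `management_params` list
#' @export
management_params <- function(ic = 13, graze_threshold = 300,
                              recovery_days = 15, cut_trigger = 2000,
                              cut_residual = 500, min_salvage = 100,
                              use_efficiency = 0.7, alpha = 0.2) {
  stopifnot(ic > 0, graze_threshold >= 0, recovery_days >= 0,
            cut_residual >= 0, cut_residual < cut_trigger,
            use_efficiency > 0, use_efficiency <= 1,
            alpha >= 0, alpha <= 1)
  p <- list(ic = ic, graze_threshold = graze_threshold,
            recovery_days = recovery_days, cut_trigger = cut_trigger,
            cut_residual = cut_residual, min_salvage = min_salvage,
            use_efficiency = use_efficiency, alpha = alpha)
  class(p) <- "management_params"
  p
}

#' Simulate one year of mowing on cut grassland
#'
#' Whenever shoot biomass exceeds the mowing trigger, biomass above the
#' residual stubble is harvested; a salvage cut removes any standing biomass
#' above residual + `min_salvage` once growth has ceased for five
#' consecutive days (end of the growing season), with a final backstop on
#' the last day of the year. All quantities are per hectare of cut
#' grassland.
#'
#' @param state initial `grass_state` (animal-free parcels)
#' @param meteo,days,co2,n_amount forcing for the year, as in
#'   [simulate_growth_year()]
#' @param mp [management_params()]
#' @param pp,pg photosynthesis and growth parameter sets
#' @return list: `y_cut` annual harvest (kg DM ha-1 yr-1 per cell), `events`
#'   mowing events per cell, `cut_biomass` sum of standing biomass at the
#'   moments of cutting, `growth` daily net shoot growth trace, `shoot`
#'   daily end-of-day standing biomass, `npp` annual NPP, `state` end state,
#'   `ledger` shoot mass balance components
#' @export
simulate_cut_year <- function(state, meteo, days, co2, n_amount,
                              mp = management_params(),
                              pp = photosynthesis_params(),
                              pg = growth_params()) {
  n <- length(state$shoot)
  state$npp_year <- rep(0, n)
  eff <- effective_photosynthesis_params(pp, nitrogen_response(n_amount, pp))
  y_cut <- events <- cut_biomass <- numeric(n)
  grown <- drained <- senesced <- numeric(n)
  nogrow <- integer(n)
  growth <- shoot_trace <- matrix(0, length(days), n)
  shoot0 <- state$shoot
  for (k in seq_along(days)) {
    d <- days[k]
    res <- step_day(state, meteo$temp[d, ], meteo$precip[d, ],
                    meteo$rad[d, ], meteo$rh[d, ], co2, eff, pp, pg)
    state <- res$state
    grown <- grown + res$fluxes$alloc_shoot_dm
    drained <- drained + res$fluxes$shoot_drain_dm
    senesced <- senesced + res$fluxes$sen_shoot_dm
    growth[k, ] <- res$fluxes$growth

    nogrow <- ifelse(growth[k, ] > 0, 0L, nogrow + 1L)
    cut <- state$shoot > mp$cut_trigger |
      (nogrow == 5L & state$shoot > mp$cut_residual + mp$min_salvage) |
      (k == length(days) & state$shoot > mp$cut_residual + mp$min_salvage)
    if (any(cut)) {
      removed <- ifelse(cut, state$shoot - mp$cut_residual, 0)
      cut_biomass <- cut_biomass + ifelse(cut, state$shoot, 0)
      y_cut <- y_cut + removed
      events <- events + as.numeric(cut)
      state$shoot <- state$shoot - removed
    }
    shoot_trace[k, ] <- state$shoot
  }
  list(y_cut = y_cut, events = events, cut_biomass = cut_biomass,
       growth = growth, shoot = shoot_trace, npp = state$npp_year,
       state = state,
       ledger = list(initial = shoot0, grown = grown, drained = drained,
                     senesced = senesced, removed = y_cut,
                     final = state$shoot))
}

#' Simulate one year of grazing at a given stocking rate
#'
#' Daily ingestion is `min(IC * S, use_efficiency * available)` where
#' `available` is shoot biomass above the grazing threshold; the gross
#' removal is ingestion divided by the use efficiency (the remainder is
#' trampling/fouling loss). Grazing stops when shoot biomass falls below the
#' threshold and resumes only after it has stayed above the threshold for at
#' least `recovery_days` consecutive days; animals graze only on days with
#' positive net shoot growth (the vegetation period). All quantities are per
#' hectare of grazed grassland. The recovery wait applies to re-starts
#' after a grazing-induced stop; the first turn-out of the season only
#' requires biomass above the threshold.
#'
#' @inheritParams simulate_cut_year
#' @param s stocking rate, LSU per grazed hectare (scalar or per-cell vector,
#'   >= 0)
#' @param veg_mask optional logical 365 x ncell matrix confining grazing to
#'   a precomputed vegetation period (see [vegetation_mask()]); without it,
#'   grazing is permitted on any day with positive net shoot growth
#' @return list: `y_graze` annual ingested DM (kg DM ha-1 yr-1), `graze_days`
#'   days grazed per cell, `growth`, `npp`, `state`, `ledger` (with
#'   `ingested` and `trampled` components)
#' @export
simulate_grazed_year <- function(state, meteo, days, co2, n_amount, s,
                                 mp = management_params(),
                                 pp = photosynthesis_params(),
                                 pg = growth_params(), veg_mask = NULL) {
  if (any(s < 0)) stop("stocking rate must be non-negative")
  n <- length(state$shoot)
  s <- rep_len(s, n)
  state$npp_year <- rep(0, n)
  eff <- effective_photosynthesis_params(pp, nitrogen_response(n_amount, pp))
  y_graze <- graze_days <- ingested_tot <- trampled_tot <- numeric(n)
  grown <- drained <- senesced <- numeric(n)
  growth <- matrix(0, length(days), n)
  shoot0 <- state$shoot
  active <- state$shoot > mp$graze_threshold
  stopped <- rep(FALSE, n)   # has grazing ever been suspended this year?
  recov <- integer(n)        # consecutive days above the threshold
  for (k in seq_along(days)) {
    d <- days[k]
    res <- step_day(state, meteo$temp[d, ], meteo$precip[d, ],
                    meteo$rad[d, ], meteo$rh[d, ], co2, eff, pp, pg)
    state <- res$state
    grown <- grown + res$fluxes$alloc_shoot_dm
    drained <- drained + res$fluxes$shoot_drain_dm
    senesced <- senesced + res$fluxes$sen_shoot_dm
    growth[k, ] <- res$fluxes$growth

    in_season <- if (is.null(veg_mask)) growth[k, ] > 0 else veg_mask[k, ]
    above <- state$shoot > mp$graze_threshold
    recov <- ifelse(above, recov + 1L, 0L)
    # turn-out needs only biomass above the threshold; after an in-season
    # (grazing-driven) suspension, resumption requires `recovery_days`
    # consecutive days above it — winter dieback does not count
    start <- !active & above & (!stopped | recov >= mp$recovery_days)
    active <- active | start
    # stop immediately when biomass drops below the threshold
    suspended <- active & !above
    stopped <- stopped | (suspended & in_season)
    active <- active & above

    can_graze <- active & in_season
    avail <- pmax(0, state$shoot - mp$graze_threshold)
    ingested <- ifelse(can_graze,
                       pmin(mp$ic * s, mp$use_efficiency * avail), 0)
    removed <- ingested / mp$use_efficiency
    state$shoot <- state$shoot - removed
    y_graze <- y_graze + ingested
    ingested_tot <- ingested_tot + ingested
    trampled_tot <- trampled_tot + removed - ingested
    graze_days <- graze_days + as.numeric(can_graze)
  }
  list(y_graze = y_graze, graze_days = graze_days, growth = growth,
       npp = state$npp_year, state = state,
       ledger = list(initial = shoot0, grown = grown, drained = drained,
                     senesced = senesced, ingested = ingested_tot,
                     trampled = trampled_tot, final = state$shoot))
}

# rolling 5-day median per column, edges kept
smooth_growth <- function(growth) {
  apply(growth, 2, function(x) {
    if (length(x) < 5) return(x)
    stats::runmed(x, 5, endrule = "keep")
  })
}

#' Vegetation-period mask from a daily growth trace
#'
#' Marks, for every cell, the days belonging to the longest run of positive
#' net shoot growth after 5-day median smoothing — the vegetation period
#' that grazing is confined to and whose complement is the indoor feeding
#' period.
#'
#' @param growth 365 x ncell matrix of daily net shoot growth
#' @return logical matrix of the same shape
#' @export
vegetation_mask <- function(growth) {
  growth <- as.matrix(growth)
  sm <- smooth_growth(growth)
  apply(sm > 0, 2, function(pos) {
    r <- rle(pos)
    out <- rep(FALSE, length(pos))
    if (any(r$values)) {
      best <- which(r$values & r$lengths == max(r$lengths[r$values]))[1]
      from <- sum(r$lengths[seq_len(best - 1)]) + 1L
      out[from:(from + r$lengths[best] - 1L)] <- TRUE
    }
    out
  })
}

#' Indoor feeding period from a daily growth trace
#'
#' The vegetation period is the longest run of days with positive net shoot
#' growth after 5-day median smoothing; `T_farm` is the remainder of the
#' 365-day year, i.e. the number of non-growing-season days during which
#' animals must be fed on conserved (cut) forage.
#'
#' @param growth 365 x ncell matrix of daily net shoot growth
#'   (kg DM ha-1 d-1)
#' @return integer vector of T_farm per cell (days)
#' @export
indoor_period <- function(growth) {
  growth <- as.matrix(growth)
  nrow(growth) - colSums(vegetation_mask(growth))
}

#' Grazing-season window from the sward calendar
#'
#' The farm's grazing season opens at the first vegetation-period day on
#' which standing biomass exceeds the grazing threshold (turn-out) and
#' closes with the vegetation period; its complement is the indoor feeding
#' period used in the feed-balance equations, so every day an animal is not
#' on pasture is a day it is fed conserved forage.
#'
#' @param mask logical vegetation-period matrix from [vegetation_mask()]
#' @param shoot daily standing-biomass trace of the (animal-free) sward
#' @param threshold grazing threshold (kg DM ha-1)
#' @return list: `window` logical matrix of grazing-season days, `t_farm`
#'   per-cell indoor days (365 - window length)
#' @export
graze_window <- function(mask, shoot, threshold = 300) {
  window <- mask
  for (j in seq_len(ncol(mask))) {
    idx <- which(mask[, j] & shoot[, j] > threshold)
    if (!length(idx)) {
      window[, j] <- FALSE
    } else {
      window[seq_len(idx[1] - 1L), j] <- FALSE
    }
  }
  list(window = window, t_farm = nrow(mask) - colSums(window))
}
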