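#' Generate a synthetic simulation grid
#'
#' Builds a rectangular lat/lon grid of grassland cells with cell areas from
#' spherical geometry, a random grassland fraction per cell, rectangular
#' administrative regions, and a climate-zone label assigned by latitude band
#' (>= 55 deg N cold, 45--55 temperate, < 45 mediterranean).
#'
#' @param n_lat,n_lon number of grid rows / columns (>= 1)
#' @param seed integer seed; the same seed always yields an identical grid
#' @param lat_range,lon_range numeric length-2 extents in degrees
#' @param region_block approximate side length, in cells, of the rectangular
#'   regions the grid is partitioned into
#' @return a `forcing_grid`: data.frame with one row per cell and columns
#'   `cell`, `lat`, `lon`, `area_ha`, `grass_frac`, `region`, `zone`
#' @export
generate_grid <- function(n_lat, n_lon, seed = 1L,
                          lat_range = c(36, 68), lon_range = c(-10, 30),
                          region_block = 2L) {
  if (n_lat < 1 || n_lon < 1) {
    stop("grid dimensions must be >= 1")
  }
  set.seed(seed)
  dlat <- diff(lat_range) / n_lat
  dlon <- diff(lon_range) / n_lon
  lats <- lat_range[1] + (seq_len(n_lat) - 0.5) * dlat
  lons <- lon_range[1] + (seq_len(n_lon) - 0.5) * dlon
  grid <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("lat", "lon")]
  grid$cell <- seq_len(nrow(grid))

  # spherical cell area, m^2 -> ha
  r_earth <- 6371000
  grid$area_ha <- r_earth^2 * (dlat * pi / 180) * (dlon * pi / 180) *
    cos(grid$lat * pi / 180) / 1e4

  grid$grass_frac <- stats::runif(nrow(grid), 0.2, 0.8)

  # rectangular region tiles
  irow <- match(grid$lat, lats)
  icol <- match(grid$lon, lons)
  rrow <- (irow - 1L) %/% region_block
  rcol <- (icol - 1L) %/% region_block
  grid$region <- as.integer(factor(paste(rrow, rcol)))

  grid$zone <- ifelse(grid$lat >= 55, "cold",
                      ifelse(grid$lat >= 45, "temperate", "mediterranean"))
  grid <- grid[, c("cell", "lat", "lon", "area_ha", "grass_frac",
                   "region", "zone")]
  class(grid) <- c("forcing_grid", "data.frame")
  validate_grid(grid)
  grid
}

validate_grid <- function(grid) {
  stopifnot(
    all(grid$grass_frac >= 0 & grid$grass_frac <= 1),
    !anyNA(grid$region),
    all(grid$area_ha > 0)
  )
  invisible(grid)
}

#' Default per-zone weather generator parameters
#'
#' Mean annual temperature (degC), seasonal amplitude (degC), AR(1) noise
#' parameters, wet-day probability and mean wet-day precipitation (mm) for the
#' three latitude-band climate zones. Values are chosen so that annual totals
#' are realistic for the zone (e.g. ~730 mm in the temperate band, ~370 mm in
#' the mediterranean band).
#'
#' @return named list of per-zone parameter lists
#' @export
climate_profile <- function() {
  list(
    cold = list(t_mean = 3.5, t_amp = 12, t_phi = 0.75, t_sd = 2.2,
                wet_prob = 0.45, wet_mean = 3.5),
    temperate = list(t_mean = 9, t_amp = 8, t_phi = 0.75, t_sd = 2.0,
                     wet_prob = 0.40, wet_mean = 5.0),
    mediterranean = list(t_mean = 14.5, t_amp = 7, t_phi = 0.75, t_sd = 1.8,
                         wet_prob = 0.20, wet_mean = 5.0)
  )
}

#' Generate daily synthetic meteorology on a grid
#'
#' Temperature follows a sinusoidal seasonal cycle plus AR(1) noise and a
#' small annual anomaly; precipitation is a Bernoulli-gamma wet/dry process;
#' shortwave radiation follows day-of-year solar geometry scaled by a
#' cloudiness factor tied to wet days; relative humidity is higher on wet
#' days. The calendar has 365-day years (no leap days).
#'
#' @param grid a `forcing_grid` from [generate_grid()]
#' @param years number of years to simulate (>= 1)
#' @param seed integer seed
#' @param profile per-zone parameter list, see [climate_profile()]
#' @return a `daily_meteo` list with matrices `temp` (degC), `precip`
#'   (mm/day), `rad` (W/m2), `rh` (fraction), each `365*years` rows by
#'   `nrow(grid)` columns, plus `years` and `doy`/`year` index vectors
#' @export
generate_meteo <- function(grid, years, seed = 1L, profile = climate_profile()) {
  if (years < 1) stop("years must be >= 1")
  zones <- unique(grid$zone)
  if (!all(zones %in% names(profile))) {
    stop("profile is missing parameters for zone(s): ",
         paste(setdiff(zones, names(profile)), collapse = ", "))
  }
  need <- c("t_mean", "t_amp", "t_phi", "t_sd", "wet_prob", "wet_mean")
  for (z in zones) {
    if (!all(need %in% names(profile[[z]]))) {
      stop("malformed profile for zone ", z)
    }
  }
  set.seed(seed)
  ncell <- nrow(grid)
  ndays <- 365L * years
  doy <- rep(seq_len(365L), years)
  yr <- rep(seq_len(years), each = 365L)
  season <- -cos(2 * pi * (doy - 15) / 365)

  temp <- precip <- rad <- rh <- matrix(0, ndays, ncell)
  for (j in seq_len(ncell)) {
    p <- profile[[grid$zone[j]]]
    noise <- if (p$t_sd > 0) {
      as.numeric(stats::arima.sim(list(ar = p$t_phi), ndays,
                                  sd = p$t_sd * sqrt(1 - p$t_phi^2)))
    } else rep(0, ndays)
    anom <- rep(stats::rnorm(years, 0, 0.25 * p$t_sd), each = 365L)
    temp[, j] <- p$t_mean + p$t_amp * season + noise + anom

    wet <- stats::rbinom(ndays, 1L, p$wet_prob)
    amount <- stats::rgamma(ndays, shape = 0.9, scale = p$wet_mean / 0.9)
    precip[, j] <- wet * amount

    lat_f <- cos(grid$lat[j] * pi / 180) / cos(50 * pi / 180)
    clear <- pmax(15, 165 * lat_f + 130 * season * lat_f)
    cloud <- ifelse(wet == 1, 0.55, 0.9)
    rad[, j] <- clear * cloud

    rh[, j] <- pmin(1, pmax(0.05,
      0.6 + 0.2 * wet - 0.05 * season + stats::rnorm(ndays, 0, 0.05)))
  }
  structure(list(temp = temp, precip = precip, rad = rad, rh = rh,
                 years = years, doy = doy, year = yr),
            class = "daily_meteo")
}

#' Annual atmospheric CO2 trajectory
#'
#' @param start_year,end_year inclusive year range (`end_year >= start_year`)
#' @param base_ppm CO2 in the first year (ppm, > 0); the historical
#'   start-of-century level is 296 ppm
#' @param growth per-year increment: ppm/yr for `type = "linear"`, fractional
#'   rate for `type = "exponential"`
#' @param type growth law
#' @return named numeric vector of ppm, names are years
#' @export
co2_series <- function(start_year, end_year, base_ppm = 296, growth = 0,
                       type = c("linear", "exponential")) {
  type <- match.arg(type)
  if (end_year < start_year) stop("end_year must be >= start_year")
  if (base_ppm <= 0) stop("base_ppm must be positive")
  t <- seq.int(0, end_year - start_year)
  ppm <- switch(type,
    linear = base_ppm + growth * t,
    exponential = base_ppm * (1 + growth)^t
  )
  names(ppm) <- seq.int(start_year, end_year)
  ppm
}

#' Reconstruct annual nitrogen-addition inputs per cell
#'
#' Applies the historical reconstruction rules: organic fertilizer is constant
#' over time; mineral fertilizer is zero before 1951, ramps linearly from zero
#' (1951 carries 1/10 of the reference level) to the full reference level in
#' 1960--1961, and afterwards follows an optional per-year scaling series;
#' atmospheric N deposition is linearly interpolated between decadal anchor
#' multipliers placed at decade midpoints (constant outside the anchor range).
#'
#' @param grid a `forcing_grid`
#' @param reference_rates data.frame with one row per cell and columns
#'   `organic`, `mineral`, `deposition` (kg N/ha/yr, all >= 0); `mineral` and
#'   `deposition` are the reference-year (1961) levels
#' @param start_year,end_year inclusive year range
#' @param mineral_scaling optional named numeric vector (names are years) of
#'   multipliers applied to the reference mineral rate after 1961; default 1
#' @param deposition_anchors optional named numeric vector of decadal
#'   multipliers, names are anchor years (decade midpoints); default constant 1
#' @return data.frame (`annual_drivers`) with columns `year`, `cell`,
#'   `organic`, `mineral`, `deposition`, `n_amount` (their sum)
#' @export
nitrogen_timeline <- function(grid, reference_rates, start_year, end_year,
                              mineral_scaling = NULL,
                              deposition_anchors = NULL) {
  if (any(unlist(reference_rates[c("organic", "mineral", "deposition")]) < 0)) {
    stop("reference rates must be non-negative")
  }
  if (nrow(reference_rates) != nrow(grid)) {
    stop("reference_rates must have one row per grid cell")
  }
  years <- seq.int(start_year, end_year)

  mineral_mult <- vapply(years, function(y) {
    if (y < 1951) return(0)
    if (y <= 1960) return((y - 1950) / 10)
    if (is.null(mineral_scaling)) return(1)
    idx <- as.character(y)
    if (idx %in% names(mineral_scaling)) mineral_scaling[[idx]] else {
      # interpolate/extrapolate flat over gaps in the scaling series
      stats::approx(as.numeric(names(mineral_scaling)), mineral_scaling,
                    xout = y, rule = 2)$y
    }
  }, numeric(1))

  dep_mult <- if (is.null(deposition_anchors)) {
    rep(1, length(years))
  } else {
    stats::approx(as.numeric(names(deposition_anchors)), deposition_anchors,
                  xout = years, rule = 2)$y
  }

  out <- expand.grid(cell = grid$cell, year = years, KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("year", "cell")]
  out <- out[order(out$year, out$cell), ]
  i <- match(out$cell, grid$cell)
  iy <- match(out$year, years)
  out$organic <- reference_rates$organic[i]
  out$mineral <- reference_rates$mineral[i] * mineral_mult[iy]
  out$deposition <- reference_rates$deposition[i] * dep_mult[iy]
  out$n_amount <- out$organic + out$mineral + out$deposition
  rownames(out) <- NULL
  class(out) <- c("annual_drivers", "data.frame")
  out
}

#' Bundle a complete synthetic forcing set
#'
#' Convenience generator combining daily meteorology, a CO2 trajectory
#' starting at the 1900 level, and the reconstructed nitrogen-addition
#' timeline into the forcing list consumed by [run_protocol()].
#'
#' @param grid a `forcing_grid`
#' @param years number of forcing years
#' @param seed integer seed
#' @param start_year calendar year of the first forcing year
#' @param co2_base,co2_growth,co2_type CO2 trajectory, see [co2_series()];
#'   the default exponential 0.28\%/yr takes 296 ppm in 1901 to about
#'   400 ppm after 110 years
#' @param profile weather generator profile, see [climate_profile()]
#' @param reference_rates optional per-cell nitrogen reference rates (see
#'   [nitrogen_timeline()]); by default organic, mineral and deposition
#'   references are drawn once per cell from modest agricultural ranges
#' @return list with `meteo`, `co2` (ppm per year), `n_amount`
#'   (years x cells matrix), `drivers` (the nitrogen table), `start_year`
#' @export
synthetic_forcing <- function(grid, years, seed = 1L, start_year = 1901,
                              co2_base = 296, co2_growth = 0.0028,
                              co2_type = "exponential",
                              profile = climate_profile(),
                              reference_rates = NULL) {
  meteo <- generate_meteo(grid, years, seed = seed, profile = profile)
  end_year <- start_year + years - 1L
  co2 <- co2_series(start_year, end_year, co2_base, co2_growth, co2_type)
  if (is.null(reference_rates)) {
    set.seed(seed + 1L)
    reference_rates <- data.frame(
      organic = stats::runif(nrow(grid), 5, 20),
      mineral = stats::runif(nrow(grid), 20, 80),
      deposition = stats::runif(nrow(grid), 5, 15)
    )
  }
  drivers <- nitrogen_timeline(grid, reference_rates, start_year, end_year)
  n_amount <- matrix(drivers$n_amount[order(drivers$year, drivers$cell)],
                     years, nrow(grid), byrow = TRUE)
  list(meteo = meteo, co2 = unname(co2), n_amount = n_amount,
       drivers = drivers, start_year = start_year)
}

#' Tile one or more forcing years into a longer stationary series
#'
#' Repeats the days of an existing `daily_meteo` object to build a longer
#' record whose climate is exactly stationary (every block identical) —
#' the standard construction for equilibrium and single-driver experiments.
#'
#' @param meteo a `daily_meteo`
#' @param years total number of years in the tiled record
#' @param source_years which years of `meteo` to recycle (default all)
#' @return a `daily_meteo` with `years` years
#' @export
tile_meteo <- function(meteo, years, source_years = seq_len(meteo$years)) {
  pick <- as.integer(rep(source_years, length.out = years))
  rows <- as.vector(vapply(pick, function(y) (y - 1L) * 365L + seq_len(365L),
                           integer(365L)))
  structure(list(temp = meteo$temp[rows, , drop = FALSE],
                 precip = meteo$precip[rows, , drop = FALSE],
                 rad = meteo$rad[rows, , drop = FALSE],
                 rh = meteo$rh[rows, , drop = FALSE],
                 years = years,
                 doy = rep(seq_len(365L), years),
                 year = rep(seq_len(years), each = 365L)),
            class = "daily_meteo")
}
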