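#' Protocol configuration
#'
#' Windows are integer year indices into the forcing (1-based); labels are
#' calendar years. The default desk-scale protocol spins up on a recycled
#' early window, fixes the reference farm optimum on that window, runs a
#' historical transient, and then the analysis transient from which trends
#' are estimated.
#'
#' @param spinup_window year indices recycled during spin-up
#' @param hist_window,analysis_window year indices of the historical and
#'   analysis transients
#' @param start_year calendar year of forcing index 1
#' @param spinup_co2 CO2 during spin-up and reference optimization (ppm)
#' @param equil_tol spin-up equilibrium tolerance on |mean annual NEE|
#'   (g C m-2 yr-1, > 0)
#' @param max_loops spin-up loop cap
#' @param climatology_years number of leading analysis years recycled in the
#'   fixed-climate run
#' @param opt_tol feed-balance tolerance of the reference optimization
#'   (kg DM ha-1)
#' @return a `protocol_config` list
#' @export
protocol_config <- function(spinup_window = 1:5, hist_window = 6:15,
                            analysis_window = 16:65, start_year = 1901,
                            spinup_co2 = 296, equil_tol = 1, max_loops = 30,
                            climatology_years = 5, opt_tol = 0.5) {
  stopifnot(equil_tol >= 0, length(spinup_window) >= 1)
  structure(as.list(environment()), class = "protocol_config")
}

#' Spin up carbon pools to equilibrium
#'
#' Recycles a forcing window until the long-term NEE proxy of every cell is
#' below tolerance (equilibrated litter and biomass pools). After each loop
#' the litter pool is rescaled by the ratio of mean litter input to mean
#' decomposition over the loop — an accelerated fixed-point update that cuts
#' the number of loops for the linear pool.
#'
#' @param state initial `grass_state`
#' @param meteo a `daily_meteo`
#' @param window integer year indices recycled each loop
#' @param co2 ppm during spin-up
#' @param n_amount per-cell annual N addition (kg N ha-1 yr-1)
#' @param pp,pg parameter sets
#' @param tol equilibrium tolerance on |mean annual NEE| (g C m-2 yr-1)
#' @param max_loops loop cap; exceeding it is an error
#' @param accelerate logical, apply the litter rescaling
#' @return list: `state`, `loops`, `nee` (per-cell mean annual NEE of the
#'   last loop), `converged` (TRUE)
#' @export
spinup <- function(state, meteo, window, co2, n_amount,
                   pp = photosynthesis_params(), pg = growth_params(),
                   tol = 1, max_loops = 30, accelerate = TRUE) {
  n <- length(state$shoot)
  for (loop in seq_len(max_loops)) {
    litter0 <- state$litter
    nee <- rep(0, n)
    npp <- rep(0, n)
    for (y in window) {
      days <- (y - 1L) * 365L + seq_len(365L)
      res <- simulate_growth_year(state, meteo, days, co2, n_amount, pp, pg)
      state <- res$state
      nee <- nee + res$nee
      npp <- npp + res$npp
    }
    mean_nee <- nee / length(window)
    if (all(abs(mean_nee) < tol)) {
      return(list(state = state, loops = loop, nee = mean_nee,
                  converged = TRUE))
    }
    if (accelerate) {
      rh_tot <- nee + npp                      # total heterotrophic resp.
      dlitter <- state$litter - litter0
      scale <- ifelse(rh_tot > 0, (dlitter + rh_tot) / rh_tot, 1)
      state$litter <- state$litter * pmax(scale, 0)
    }
  }
  stop("spin-up did not converge within ", max_loops,
       " loops (|NEE| tolerance ", tol, " g C m-2 yr-1)")
}

#' Run the full simulation protocol
#'
#' Spin-up without management (recycled window, fixed CO2); reference
#' optimization of stocking rate and grazed fraction on the same window; a
#' historical adaptive transient; and the analysis transient plus its three
#' fixed-driver variants branching from the end of the historical run:
#' CO2 fixed at the first analysis year, climate recycled over the leading
#' analysis years, and nitrogen fixed at the first analysis year. Trend
#' differences between the full analysis run and each fixed-driver run
#' isolate that driver's contribution.
#'
#' @param grid a `forcing_grid`
#' @param forcing list with `meteo` (a `daily_meteo`), `co2` (ppm per forcing
#'   year), `n_amount` (matrix years x cells)
#' @param config a [protocol_config()]
#' @param mp,pp,pg parameter sets
#' @param experiments character subset of `c("e4","e5","e6","e7")` to run in
#'   the analysis window
#' @return list: `spinup` diagnostics, `farm_ref` (reference optimum),
#'   `e3` historical trajectory, and one trajectory per requested analysis
#'   experiment
#' @export
run_protocol <- function(grid, forcing, config = protocol_config(),
                         mp = management_params(),
                         pp = photosynthesis_params(),
                         pg = growth_params(),
                         experiments = c("e4", "e5", "e6", "e7")) {
  meteo <- forcing$meteo
  nyears <- meteo$years
  need <- max(config$analysis_window)
  if (need > nyears) stop("forcing is missing years (need ", need, ")")
  co2 <- rep_len(forcing$co2, nyears)
  n <- nrow(grid)
  n_amount <- forcing$n_amount
  if (is.null(n_amount)) n_amount <- matrix(0, nyears, n)
  if (!is.matrix(n_amount)) n_amount <- matrix(rep(n_amount, length.out = n),
                                               nyears, n, byrow = TRUE)
  yr_label <- config$start_year + seq_len(nyears) - 1L

  sp <- spinup(grass_state(n, gp = pg), meteo, config$spinup_window,
               config$spinup_co2, n_amount[config$spinup_window[1], ],
               pp, pg, tol = config$equil_tol, max_loops = config$max_loops)

  farm_ref <- solve_optimum(sp$state, meteo, config$spinup_window,
                            config$spinup_co2,
                            n_amount[config$spinup_window[1], ],
                            mp, pp, pg, tol = config$opt_tol)

  hw <- config$hist_window
  e3 <- run_adaptive(sp$state, farm_ref, meteo, hw, co2[hw],
                     n_amount[hw, , drop = FALSE], mp, pp, pg,
                     labels = yr_label[hw])

  aw <- config$analysis_window
  a1 <- aw[1]
  clim <- rep(aw[seq_len(min(config$climatology_years, length(aw)))],
              length.out = length(aw))
  runs <- list(
    e4 = list(years = aw, co2 = co2[aw], n = n_amount[aw, , drop = FALSE]),
    e5 = list(years = aw, co2 = rep(co2[a1], length(aw)),
              n = n_amount[aw, , drop = FALSE]),
    e6 = list(years = clim, co2 = co2[aw], n = n_amount[aw, , drop = FALSE]),
    e7 = list(years = aw, co2 = co2[aw],
              n = n_amount[rep(a1, length(aw)), , drop = FALSE])
  )
  out <- list(spinup = sp, farm_ref = farm_ref, e3 = e3)
  for (nm in intersect(c("e4", "e5", "e6", "e7"), experiments)) {
    r <- runs[[nm]]
    out[[nm]] <- run_adaptive(e3$state_cut, e3$farm, meteo, r$years, r$co2,
                              r$n, mp, pp, pg, labels = yr_label[aw],
                              state_graze = e3$state_graze)
  }
  out
}

#' Area-weighted annual productivity series from a trajectory
#'
#' Productivity is the annual forage production per hectare of cut grassland
#' (`y_cut`), averaged over cells with grassland-area weights and converted
#' to t DM ha-1 yr-1.
#'
#' @param trajectory a `run_adaptive()` trajectory data.frame
#' @param grid the matching `forcing_grid`
#' @return data.frame with columns `year`, `productivity` (t DM ha-1 yr-1)
#' @export
productivity_series <- function(trajectory, grid) {
  w <- grid$area_ha * grid$grass_frac
  agg <- vapply(split(trajectory, trajectory$year), function(df) {
    stats::weighted.mean(df$y_cut[order(df$cell)], w) / 1000
  }, numeric(1))
  data.frame(year = as.numeric(names(agg)), productivity = unname(agg))
}

#' Ordinary least-squares trend of an annual series
#'
#' @param values annual values (>= 3 years)
#' @param years corresponding years; defaults to `seq_along(values)`
#' @return list: `slope` (units/yr), `percent_per_year` (100 * slope / mean),
#'   `p_value` (two-sided, for slope != 0; 1 for a constant series)
#' @export
trend <- function(values, years = seq_along(values)) {
  if (length(values) < 3) stop("need at least 3 years")
  if (stats::sd(values) == 0) {
    return(list(slope = 0, percent_per_year = 0, p_value = 1))
  }
  fit <- stats::lm(values ~ years)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm["years", "Estimate"]),
       percent_per_year = 100 * unname(sm["years", "Estimate"]) / mean(values),
       p_value = unname(sm["years", "Pr(>|t|)"]))
}

#' Factorial attribution of a productivity trend
#'
#' Decomposes the full-run trend `t_e4` into driver contributions by
#' differencing against the fixed-driver runs: CO2 (`t_e4 - t_e5`), climate
#' (`t_e4 - t_e6`) and nitrogen (`t_e4 - t_e7`), each also expressed as a
#' percentage of `t_e4`. The drivers are not independent, so the total
#' contribution can exceed 100\%.
#'
#' @param t_e4,t_e5,t_e6,t_e7 trends (e.g. t DM ha-1 yr-2)
#' @return an `attribution` list: `trends`, `contributions` (named co2 /
#'   climate / nitrogen), `percentages`, `total`, `total_percent`,
#'   `undefined` flag (TRUE when `t_e4` is zero and percentages are NA)
#' @export
attribute <- function(t_e4, t_e5, t_e6, t_e7) {
  contrib <- c(co2 = t_e4 - t_e5, climate = t_e4 - t_e6,
               nitrogen = t_e4 - t_e7)
  undefined <- t_e4 == 0
  pct <- if (undefined) rep(NA_real_, 3) else 100 * contrib / t_e4
  names(pct) <- names(contrib)
  structure(list(trends = c(e4 = t_e4, e5 = t_e5, e6 = t_e6, e7 = t_e7),
                 contributions = contrib, percentages = pct,
                 total = sum(contrib),
                 total_percent = if (undefined) NA_real_ else
                   100 * sum(contrib) / t_e4,
                 undefined = undefined),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat("trend attribution (full-run trend ", format(x$trends["e4"]), ")\n",
      sep = "")
  for (nm in names(x$contributions)) {
    cat(sprintf("  %-9s %+.4g (%s%%)\n", nm, x$contributions[[nm]],
                format(round(x$percentages[[nm]]))))
  }
  cat(sprintf("  total     %+.4g (%s%%)\n", x$total,
              format(round(x$total_percent))))
  if (x$undefined) cat("  (percentages undefined: zero reference trend)\n")
  invisible(x)
}

#' Two-level factorial parameter-uncertainty ensemble
#'
#' Builds the 2^4 = 16 member parameter sets from four binary factors: the
#' response-curve shape constant `a` and the capacities `vcmax/jmax` (moved
#' jointly) and `sla_max` at +/-20\% of their standard values, and the
#' asymptote `n_addmax` at +/-0.20 absolute.
#'
#' @param standard a [photosynthesis_params()] set
#' @return an `ensemble_design` list: `design` (16-row data.frame of factor
#'   levels), `members` (list of 16 parameter sets)
#' @export
build_ensemble <- function(standard = photosynthesis_params()) {
  levels <- list(
    a = c(min = standard$a * 0.8, max = standard$a * 1.2),
    n_addmax = c(min = standard$n_addmax - 0.2,
                 max = standard$n_addmax + 0.2),
    capacity = c(min = 0.8, max = 1.2),   # joint vcmax/jmax multiplier
    sla_max = c(min = standard$sla_max * 0.8, max = standard$sla_max * 1.2)
  )
  levels <- lapply(levels, unname)
  design <- expand.grid(a = levels$a, n_addmax = levels$n_addmax,
                        capacity = levels$capacity, sla_max = levels$sla_max,
                        KEEP.OUT.ATTRS = FALSE)
  members <- lapply(seq_len(nrow(design)), function(i) {
    photosynthesis_params(
      vcmax_base = standard$vcmax_base * design$capacity[i],
      jmax_base = standard$jmax_base * design$capacity[i],
      sla_max = design$sla_max[i],
      a = design$a[i],
      n_addmax = design$n_addmax[i])
  })
  structure(list(design = design, members = members),
            class = "ensemble_design")
}

#' Apply a function over ensemble members and summarize spread
#'
#' @param ensemble an [build_ensemble()] design
#' @param fun function taking a `photosynthesis_params` member and returning
#'   a numeric scalar (e.g. a productivity or trend estimate)
#' @return list: `values` (length 16), `mean`, `sd` (1-sigma across members)
#' @export
ensemble_apply <- function(ensemble, fun) {
  values <- vapply(ensemble$members, fun, numeric(1))
  list(values = values, mean = mean(values), sd = stats::sd(values))
}
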