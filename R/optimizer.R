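#' Construct a farm-optimum record
#'
#' @param s_opt stocking rate on grazed land (LSU ha-1)
#' @param f_opt grazed fraction of the cell's grassland, in [0,1]
#' @param d_opt potential livestock density per hectare of total grassland,
#'   `s_opt * f_opt`
#' @param y_cut,y_graze annual yields (kg DM ha-1 yr-1)
#' @param t_farm indoor feeding period (days)
#' @param residual_cut,residual_graze balance residuals of the winter-feed
#'   and grazing-season equations (kg DM ha-1)
#' @param converged logical
#' @return a `farm_optimum` list
#' @export
farm_optimum <- function(s_opt, f_opt, d_opt = s_opt * f_opt,
                         y_cut = NA_real_, y_graze = NA_real_,
                         t_farm = NA_real_, residual_cut = NA_real_,
                         residual_graze = NA_real_, converged = TRUE) {
  stopifnot(all(s_opt >= 0), all(f_opt >= -1e-12 & f_opt <= 1 + 1e-12))
  structure(list(s_opt = s_opt, f_opt = pmin(pmax(f_opt, 0), 1),
                 d_opt = d_opt, y_cut = y_cut, y_graze = y_graze,
                 t_farm = t_farm, residual_cut = residual_cut,
                 residual_graze = residual_graze, converged = converged),
            class = "farm_optimum")
}

#' @export
print.farm_optimum <- function(x, ...) {
  cat("farm optimum (", length(x$s_opt), " cell(s))\n", sep = "")
  cat("  S_opt (LSU/grazed ha):", format(x$s_opt, digits = 4), "\n")
  cat("  F_opt (grazed fraction):", format(x$f_opt, digits = 4), "\n")
  cat("  D_opt (LSU/ha):", format(x$d_opt, digits = 4), "\n")
  invisible(x)
}

# grazed fraction balancing winter feed: IC*Tfarm*S*F = Ycut*(1-F)
f_from_balance <- function(y_cut, ic, t_farm, s) {
  denom <- ic * t_farm * s + y_cut
  ifelse(denom > 0, y_cut / denom, 0)
}

#' Core stocking-rate solver on yield functions
#'
#' Finds the largest stocking rate S whose grazing-season feed demand
#' `IC * (365 - T_farm) * S` is still met by the simulated ingestion
#' `Y_graze(S)` (residual below `tol`), by a geometric outer sweep followed
#' by bisection on the feasibility boundary; the grazed fraction then follows
#' from the winter-feed balance `IC * T_farm * S * F = Y_cut * (1 - F)`.
#'
#' @param y_graze_fun function(S) returning annual ingested DM per grazed ha
#' @param y_cut annual cut yield per mown ha (kg DM ha-1 yr-1)
#' @param t_farm indoor period (days)
#' @param mp [management_params()] (supplies IC)
#' @param tol feed-balance tolerance (kg DM ha-1)
#' @param max_iter iteration cap for sweep plus bisection
#' @param s_init initial stocking rate for the sweep
#' @return a `farm_optimum` (scalar fields)
#' @export
optimize_stocking <- function(y_graze_fun, y_cut, t_farm,
                              mp = management_params(), tol = 1e-6,
                              max_iter = 200, s_init = 0.25) {
  stopifnot(tol > 0)
  t_graze <- 365 - t_farm
  residual <- function(s) mp$ic * t_graze * s - y_graze_fun(s)

  # no grazing season, or a barren cell: no livestock can be carried
  if (t_graze <= 0 || (y_graze_fun(s_init) <= 0 && y_cut <= 0)) {
    return(farm_optimum(0, 0, 0, y_cut = max(y_cut, 0), y_graze = 0,
                        t_farm = t_farm, residual_cut = 0,
                        residual_graze = 0))
  }

  iter <- 0L
  s_lo <- 0
  s_hi <- s_init
  # geometric sweep: increase S until demand can no longer be met
  while (residual(s_hi) <= tol) {
    s_lo <- s_hi
    s_hi <- s_hi * 1.25
    iter <- iter + 1L
    if (iter >= max_iter) {
      return(farm_optimum(0, 0, 0, y_cut = y_cut, y_graze = y_graze_fun(s_lo),
                          t_farm = t_farm, residual_cut = NA_real_,
                          residual_graze = residual(s_lo), converged = FALSE))
    }
  }
  # bisect the boundary of {S : residual(S) <= tol}; residual(0) <= 0 so
  # the bracket [s_lo, s_hi] always straddles the boundary
  while (iter < max_iter &&
         (s_hi - s_lo) > 1e-10 * max(1, s_hi)) {
    mid <- (s_lo + s_hi) / 2
    if (residual(mid) <= tol) s_lo <- mid else s_hi <- mid
    iter <- iter + 1L
  }
  s_opt <- s_lo
  y_graze <- y_graze_fun(s_opt)
  f_opt <- f_from_balance(y_cut, mp$ic, t_farm, s_opt)
  farm_optimum(s_opt, f_opt, s_opt * f_opt, y_cut = y_cut,
               y_graze = y_graze, t_farm = t_farm,
               residual_cut = mp$ic * t_farm * s_opt * f_opt -
                 y_cut * (1 - f_opt),
               residual_graze = residual(s_opt),
               converged = iter < max_iter)
}

#' Solve the per-cell farm optimum from simulated yields
#'
#' For every grid cell: simulates the cut-side year(s) once (cut land is
#' animal-free), derives the indoor period from the cut-side growth trace,
#' and solves for the largest sustainable stocking rate by re-simulating the
#' grazed side at each candidate S with [simulate_grazed_year()]. Yields are
#' averaged over the supplied forcing years.
#'
#' @param state initial `grass_state` (one entry per cell)
#' @param meteo a `daily_meteo`
#' @param years integer vector of year indices of `meteo` to use
#' @param co2 ppm, scalar or vector over `years`
#' @param n_amount per-cell annual nitrogen addition (kg N ha-1 yr-1), vector
#'   or matrix years x cells
#' @param mp,pp,pg parameter sets
#' @param tol feed-balance tolerance (kg DM ha-1)
#' @param max_iter per-cell iteration cap
#' @return a `farm_optimum` with per-cell vector fields
#' @export
solve_optimum <- function(state, meteo, years, co2, n_amount,
                          mp = management_params(),
                          pp = photosynthesis_params(),
                          pg = growth_params(),
                          tol = 0.5, max_iter = 200) {
  n <- length(state$shoot)
  co2 <- rep_len(co2, length(years))
  n_amount <- if (is.matrix(n_amount)) n_amount else
    matrix(rep(n_amount, length.out = n), length(years), n, byrow = TRUE)

  run_cut <- function(st) {
    y <- numeric(n); tf <- numeric(n); windows <- vector("list", length(years))
    for (i in seq_along(years)) {
      days <- (years[i] - 1L) * 365L + seq_len(365L)
      res <- simulate_cut_year(st, meteo, days, co2[i], n_amount[i, ],
                               mp, pp, pg)
      st <- res$state
      y <- y + res$y_cut
      gw <- graze_window(vegetation_mask(res$growth), res$shoot,
                         mp$graze_threshold)
      windows[[i]] <- gw$window
      tf <- tf + gw$t_farm
    }
    list(y_cut = y / length(years), t_farm = tf / length(years),
         windows = windows, state = st)
  }
  cut <- run_cut(state)
  run_graze <- function(st0, s) {
    y <- numeric(n)
    st <- st0
    for (i in seq_along(years)) {
      days <- (years[i] - 1L) * 365L + seq_len(365L)
      res <- simulate_grazed_year(st, meteo, days, co2[i], n_amount[i, ], s,
                                  mp, pp, pg, veg_mask = cut$windows[[i]])
      st <- res$state
      y <- y + res$y_graze
    }
    y / length(years)
  }

  # vectorized sweep + bisection over all cells at once (each residual
  # evaluation is a full multi-year grazing simulation)
  t_graze <- pmax(365 - cut$t_farm, 0)
  resid <- function(s) mp$ic * t_graze * s - run_graze(state, s)
  s_lo <- rep(0, n)
  s_hi <- rep(0.25, n)
  for (iter in seq_len(40)) {
    r <- resid(s_hi)
    grow <- r <= tol
    if (!any(grow)) break
    s_lo[grow] <- s_hi[grow]
    s_hi[grow] <- s_hi[grow] * 1.6
  }
  for (iter in seq_len(25)) {
    mid <- (s_lo + s_hi) / 2
    ok <- resid(mid) <= tol
    s_lo[ok] <- mid[ok]
    s_hi[!ok] <- mid[!ok]
  }
  s_opt <- s_lo
  y_graze <- run_graze(state, s_opt)
  barren <- cut$y_cut <= 0 & y_graze <= 0
  s_opt[barren] <- 0
  f_opt <- f_from_balance(cut$y_cut, mp$ic, cut$t_farm, s_opt)
  f_opt[barren] <- 0
  farm_optimum(s_opt, f_opt, s_opt * f_opt, y_cut = cut$y_cut,
               y_graze = y_graze, t_farm = cut$t_farm,
               residual_cut = mp$ic * cut$t_farm * s_opt * f_opt -
                 cut$y_cut * (1 - f_opt),
               residual_graze = mp$ic * t_graze * s_opt - y_graze,
               converged = TRUE)
}

#' Exhaustive lattice oracle for the farm optimum
#'
#' Brute-force search over an (S, F) lattice maximizing D = S * F subject to
#' both feed balances holding as demand <= supply: winter demand
#' `IC * T_farm * S * F <= Y_cut * (1 - F)` and grazing-season demand
#' `IC * (365 - T_farm) * S <= Y_graze(S)` (within `tol`). Intended as an
#' independent verification oracle for [optimize_stocking()].
#'
#' @param y_graze_fun function(S) returning annual ingested DM per grazed ha
#' @param y_cut annual cut yield per mown ha
#' @param t_farm indoor period (days)
#' @param mp [management_params()]
#' @param s_max,resolution lattice extent and step for both S and F
#' @param tol slack on the grazing-season balance (kg DM ha-1)
#' @return a `farm_optimum`
#' @export
oracle_optimum <- function(y_graze_fun, y_cut, t_farm,
                           mp = management_params(), s_max = 10,
                           resolution = 0.01, tol = 1e-9) {
  s_grid <- seq(0, s_max, by = resolution)
  f_grid <- seq(0, 1, by = resolution)
  t_graze <- 365 - t_farm
  best <- c(d = 0, s = 0, f = 0)
  for (s in s_grid) {
    if (mp$ic * t_graze * s - y_graze_fun(s) > tol) next
    # winter feasibility: F <= Ycut / (IC*Tfarm*S + Ycut)
    feas <- mp$ic * t_farm * s * f_grid <= y_cut * (1 - f_grid) + tol
    if (!any(feas)) next
    f <- max(f_grid[feas])
    if (s * f > best["d"]) best <- c(d = s * f, s = s, f = f)
  }
  farm_optimum(best[["s"]], best[["f"]], best[["d"]], y_cut = y_cut,
               y_graze = y_graze_fun(best[["s"]]), t_farm = t_farm)
}
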