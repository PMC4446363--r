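#' Convert animal head counts to livestock units
#'
#' @param heads named numeric vector of head counts by species/class
#' @param coefficients named numeric vector of LSU per head; defaults follow
#'   the standard census coefficients (dairy cows 1, heifers/other cattle
#'   0.8, sheep and goats 0.1)
#' @return total LSU
#' @export
lsu_convert <- function(heads,
                        coefficients = c(dairy = 1, cattle = 0.8,
                                         heifers = 0.8, sheep = 0.1,
                                         goats = 0.1)) {
  if (any(heads < 0)) stop("head counts must be non-negative")
  missing <- setdiff(names(heads), names(coefficients))
  if (length(missing)) {
    stop("no LSU coefficient for: ", paste(missing, collapse = ", "))
  }
  sum(heads * coefficients[names(heads)])
}

#' Grass-fed livestock from census statistics
#'
#' Weighted sum of the regional livestock units by the grass fraction of
#' each animal type's diet:
#' `N_obs = N_beef*F_beef + N_dairy*F_dairy + N_sheep*F_sheep +
#' N_goats*F_goats`.
#'
#' @param region list or one-row data.frame with LSU counts `n_beef`,
#'   `n_dairy`, `n_sheep`, `n_goats` and diet grass fractions `f_beef`,
#'   `f_dairy`, `f_sheep`, `f_goats` (each in [0,1])
#' @return N_obs (LSU)
#' @export
grass_fed_observed <- function(region) {
  with(region, n_beef * f_beef + n_dairy * f_dairy +
         n_sheep * f_sheep + n_goats * f_goats)
}

#' Aggregate cell densities to regional densities
#'
#' Area-weighted mean of per-cell potential livestock density over each
#' region's cells, weighted by actual grassland area.
#'
#' @param d_opt per-cell densities (LSU ha-1)
#' @param weights per-cell grassland areas (ha, >= 0)
#' @param region per-cell region ids
#' @return named numeric vector of `D_reg` per region; a region whose total
#'   weight is zero is an error
#' @export
aggregate_density <- function(d_opt, weights, region) {
  stopifnot(length(d_opt) == length(weights),
            length(d_opt) == length(region))
  if (any(weights < 0)) stop("weights must be non-negative")
  wtot <- tapply(weights, region, sum)
  if (any(wtot == 0)) {
    stop("region(s) with zero grassland area: ",
         paste(names(wtot)[wtot == 0], collapse = ", "))
  }
  wsum <- tapply(d_opt * weights, region, sum)
  stats::setNames(as.numeric(wsum / wtot), names(wtot))
}

#' Grass-fed livestock from the model
#'
#' Combines the regional model density with statistical grassland areas by
#' type: `N_sim = f_temp*D_reg*A_temp + f_perm*D_reg*A_perm +
#' f_rough*D_reg*A_rough`, where the support fractions state how much of the
#' potential density each grassland type sustains (temporary 100\%,
#' permanent 80\%, rough grazing 10\% by default).
#'
#' @param region list or one-row data.frame with `d_reg` (LSU ha-1) and
#'   areas `a_temp`, `a_perm`, `a_rough` (ha)
#' @param support named fractions `c(temp=, perm=, rough=)`
#' @return N_sim (LSU)
#' @export
grass_fed_simulated <- function(region,
                                support = c(temp = 1.0, perm = 0.8,
                                            rough = 0.1)) {
  with(region, support[["temp"]] * d_reg * a_temp +
         support[["perm"]] * d_reg * a_perm +
         support[["rough"]] * d_reg * a_rough)
}

#' Livestock density per unit of grassland productivity
#'
#' @param density LSU ha-1
#' @param productivity t DM ha-1 yr-1 (> 0)
#' @return LSU per 10 t DM
#' @export
density_productivity_ratio <- function(density, productivity) {
  if (any(productivity <= 0)) stop("productivity must be positive")
  10 * density / productivity
}

#' Remove a fitted linear trend from a series
#'
#' @param values numeric series
#' @param years time axis
#' @return detrended series (OLS residuals plus the series mean)
#' @export
detrend <- function(values, years = seq_along(values)) {
  stats::residuals(stats::lm(values ~ years)) + mean(values)
}

#' Model-data agreement statistics
#'
#' Pearson product-moment correlation (optionally on linearly detrended
#' series) with its two-sided p-value from the t transform, coefficients of
#' variation, and a through-origin regression of model on observations
#' (slope = sum(P*O)/sum(O^2)) with its uncentered R-squared.
#'
#' @param model,obs equal-length numeric series (n >= 3)
#' @param detrend_flag remove linear trends before correlating
#' @return an `agreement` list: `r`, `p_value`, `cv_model`, `cv_obs` (%),
#'   `slope`, `r_squared`, `detrended` (logical), `model`, `obs` (the series
#'   as correlated)
#' @export
agreement <- function(model, obs, detrend_flag = FALSE) {
  stopifnot(length(model) == length(obs), length(model) >= 3)
  m <- model
  o <- obs
  if (detrend_flag) {
    m <- detrend(m)
    o <- detrend(o)
  }
  ct <- suppressWarnings(stats::cor.test(m, o))
  slope <- sum(model * obs) / sum(obs^2)
  r2 <- 1 - sum((model - slope * obs)^2) / sum(model^2)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 cv_model = 100 * stats::sd(model) / mean(model),
                 cv_obs = 100 * stats::sd(obs) / mean(obs),
                 slope = slope, r_squared = r2, detrended = detrend_flag,
                 model = m, obs = o),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("agreement: r = %.3f (p = %.3g)%s\n", x$r, x$p_value,
              if (x$detrended) ", detrended" else ""))
  cat(sprintf("  through-origin slope = %.3f (R2 = %.3f)\n",
              x$slope, x$r_squared))
  cat(sprintf("  CV model = %.1f%%, CV obs = %.1f%%\n",
              x$cv_model, x$cv_obs))
  invisible(x)
}

#' Regional evaluation table
#'
#' Convenience wrapper: aggregates cell densities to regions, then computes
#' observed and simulated grass-fed livestock numbers per region.
#'
#' @param regions data.frame with one row per region: `region`, areas
#'   `a_temp`, `a_perm`, `a_rough`, LSU counts `n_beef`, `n_dairy`,
#'   `n_sheep`, `n_goats`, diet fractions `f_beef`, `f_dairy`, `f_sheep`,
#'   `f_goats`
#' @param d_opt,weights,cell_region per-cell model density, grassland area
#'   and region id
#' @param support support fractions, see [grass_fed_simulated()]
#' @return `regions` with added columns `d_reg`, `n_obs`, `n_sim`
#' @export
evaluate_regions <- function(regions, d_opt, weights, cell_region,
                             support = c(temp = 1.0, perm = 0.8,
                                         rough = 0.1)) {
  d_reg <- aggregate_density(d_opt, weights, cell_region)
  regions$d_reg <- as.numeric(d_reg[as.character(regions$region)])
  regions$n_obs <- grass_fed_observed(regions)
  regions$n_sim <- grass_fed_simulated(regions, support)
  regions
}
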