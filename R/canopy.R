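#' Beer's-law fraction of intercepted PAR
#'
#' @param k Canopy light-extinction coefficient (0.36 for both switchgrass
#'   ecotypes).
#' @param lai Leaf area index, non-negative.
#' @return Fraction of incident PAR intercepted, in `[0, 1)`.
#' @export
#' @examples
#' fraction_intercepted(0.36, 12)
fraction_intercepted <- function(k, lai) {
  if (any(lai < 0)) stop("lai must be non-negative")
  1 - exp(-k * lai)
}

#' Temperature variation factor of radiation-use efficiency
#'
#' A bivariate Gaussian response, normalised to 1 at the genotype's optimum:
#' `exp(-((t_day - t_opt)^2 + (t_leaf - t_opt)^2) / (2 sigma^2))`, combining
#' the temperature of the day with the mean temperature over the period of
#' leaf formation.
#'
#' @param t_day Daily mean temperature (degrees C).
#' @param t_leaf Mean temperature over the leaf-formation period (degrees C).
#' @param t_opt Optimal growing-season temperature (28 lowland, 23 upland).
#' @param sigma Breadth of the response (degrees C), default 8.
#' @return Factor in `(0, 1]`; equals 1 iff both temperatures sit at `t_opt`.
#' @export
temperature_variation_factor <- function(t_day, t_leaf, t_opt, sigma = 8) {
  if (sigma <= 0) stop("sigma must be positive")
  exp(-((t_day - t_opt)^2 + (t_leaf - t_opt)^2) / (2 * sigma^2))
}

#' Daily leaf-area-index update
#'
#' Stage-dependent LAI dynamics: during shoot emergence and leaf expansion
#' (stages 1-2) LAI grows by the genotype DD factor times the day's DD0
#' increment, throttled by the leaf-expansion water-stress factor and capped
#' at `lai_max`; from the onset of leaf senescence through repartition
#' (stages 3-4) it declines linearly by `lai_senescence_rate` times the
#' attained peak per day (or exponentially if configured); dormant and
#' drying stages carry no green leaf.
#'
#' @param state A `plant_state` with current `stage`, `lai`, `peak_lai`.
#' @param dd0_today Today's degree-day increment above 0 C.
#' @param water_factor_lai Leaf-expansion downregulation factor in `[0, 1]`.
#' @param params Genotype parameter list (uses `dd_lai_factor`, `lai_max`,
#'   `lai_senescence_rate`, `senescence_mode`).
#' @return The updated `plant_state`.
#' @export
update_lai <- function(state, dd0_today, water_factor_lai, params) {
  s <- state$stage
  if (s %in% c(1L, 2L)) {
    state$lai <- min(params$lai_max,
                     state$lai + params$dd_lai_factor * dd0_today * water_factor_lai)
    state$peak_lai <- max(state$peak_lai, state$lai)
  } else if (s %in% c(3L, 4L)) {
    drop <- if (identical(params$senescence_mode, "exponential")) {
      params$lai_senescence_rate * state$lai
    } else {
      params$lai_senescence_rate * state$peak_lai
    }
    state$lai <- max(0, state$lai - drop)
  } else {
    state$lai <- 0
  }
  state
}

#' Daily dry-matter increment
#'
#' Radiation-use-efficiency production: intercepted PAR times the effective
#' RUE, `rue_max * TVF * f_w`, in g DM m-2, converted (x 0.01) to Mg ha-1.
#'
#' @param rue_max Maximum radiation-use efficiency (g DM per MJ intercepted
#'   PAR).
#' @param tvf Temperature variation factor in `(0, 1]`.
#' @param water_factor_rue Photosynthesis downregulation factor in `[0, 1]`.
#' @param fipar Fraction of PAR intercepted, in `[0, 1)`.
#' @param par Incident PAR (MJ m-2 day-1).
#' @return Dry-matter increment (Mg ha-1 day-1), non-negative.
#' @export
#' @examples
#' daily_dm_increment(5.05, 1, 1, fraction_intercepted(0.36, 12), 8)
daily_dm_increment <- function(rue_max, tvf, water_factor_rue, fipar, par) {
  stopifnot(tvf >= 0, tvf <= 1, water_factor_rue >= 0, water_factor_rue <= 1,
            fipar >= 0, fipar < 1, par >= 0)
  rue_max * tvf * water_factor_rue * fipar * par * 0.01
}
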