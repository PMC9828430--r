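#' Physiostat degree-day thresholds
#'
#' Cumulative DD10 values (degree days above a 10 C base since the annual
#' reset) that trigger growth stages 1-5.
#'
#' @param dd_stage Numeric vector of five strictly increasing positive
#'   thresholds.
#' @return A `physiostat_thresholds` object.
#' @export
physiostat_thresholds <- function(dd_stage) {
  if (length(dd_stage) != 5L) stop("exactly five stage thresholds required")
  if (any(dd_stage <= 0) || any(diff(dd_stage) <= 0)) {
    stop("stage thresholds must be positive and strictly increasing")
  }
  structure(as.numeric(dd_stage), class = "physiostat_thresholds")
}

#' Fresh plant state
#'
#' The evolving plant record: physiostat stage (0 dormant, 1 shoot emergence,
#' 2 leaf expansion, 3 onset of leaf senescence, 4 plant senescence and
#' repartition, 5 above-ground drying), the two degree-day clocks, leaf area
#' index, above-ground dry matter and its seasonal peak, the running
#' leaf-formation temperature, and establishment status.
#'
#' @param alive Establishment status, default `TRUE`.
#' @return A `plant_state` list.
#' @export
new_plant_state <- function(alive = TRUE) {
  structure(list(stage = 0L, dd10 = 0, dd0 = 0,
                 lai = 0, peak_lai = 0,
                 dm = 0, peak_dm = 0,
                 t_leaf = NA_real_,
                 alive = alive,
                 stage4_onset = as.Date(NA)),
            class = "plant_state")
}

#' Advance the physiostat state machine by one day
#'
#' Applies the stage-transition rules for the current day, cascading forward
#' if several thresholds are crossed at once but never moving backwards
#' within a season:
#' * 0 to 1 when `dd10 >= dd_stage[1]`, the soil is moist enough for
#'   emergence (`psi >= psi_emergence`) and there is no frost that day;
#' * 1 to 2 at `dd_stage[2]`;
#' * 2 to 3 at `dd_stage[3]`, or when LAI reaches its maximum, on a frost
#'   day, when the potential falls below the leaf-expansion stop, or (if the
#'   photoperiod brake is enabled) when post-solstice day length drops below
#'   the configured threshold;
#' * 3 to 4 at `dd_stage[4]` or on a killing frost, recording the seasonal
#'   peak dry matter and the onset date;
#' * 4 to 5 at `dd_stage[5]`.
#'
#' @param state A [new_plant_state()] with up-to-date degree-day clocks.
#' @param triggers List with elements `psi` (kPa), `tmean`, `frost_today`,
#'   `killing_frost`, `day_length` (h), `after_solstice`, `date`.
#' @param thresholds A [physiostat_thresholds()] object.
#' @param genotype A [genotype_defaults()] parameter set (supplies
#'   `psi_emergence`, `psi_stop_lai`, `lai_max`, photoperiod settings).
#' @return The updated `plant_state`.
#' @export
advance_physiostat <- function(state, triggers, thresholds, genotype) {
  stopifnot(inherits(state, "plant_state"))
  thr <- unclass(thresholds)
  repeat {
    s <- state$stage
    if (s == 0L) {
      if (state$dd10 >= thr[1] &&
          triggers$psi >= genotype$psi_emergence &&
          !isTRUE(triggers$frost_today)) {
        state$stage <- 1L
        next
      }
    } else if (s == 1L) {
      if (state$dd10 >= thr[2]) {
        state$stage <- 2L
        next
      }
    } else if (s == 2L) {
      photoperiod_brake <- isTRUE(genotype$photoperiod_enabled) &&
        isTRUE(triggers$after_solstice) &&
        triggers$day_length < genotype$photoperiod_hours
      if (state$dd10 >= thr[3] ||
          state$lai >= genotype$lai_max - 1e-12 ||
          isTRUE(triggers$frost_today) ||
          triggers$psi < genotype$psi_stop_lai ||
          photoperiod_brake) {
        state$stage <- 3L
        next
      }
    } else if (s == 3L) {
      if (state$dd10 >= thr[4] || isTRUE(triggers$killing_frost)) {
        state$stage <- 4L
        state$peak_dm <- state$dm
        state$stage4_onset <- triggers$date
        next
      }
    } else if (s == 4L) {
      if (state$dd10 >= thr[5]) {
        state$stage <- 5L
        next
      }
    }
    break
  }
  state
}

#' Annual reset of the perennial cycle
#'
#' Zeroes the degree-day clocks, leaf area and dry matter, and returns the
#' plant to the dormant stage while preserving establishment status.
#' Idempotent.
#'
#' @param state A `plant_state`.
#' @param date Optional reset date (unused bookkeeping hook).
#' @return The reset `plant_state`.
#' @export
annual_reset <- function(state, date = NULL) {
  stopifnot(inherits(state, "plant_state"))
  state$stage <- 0L
  state$dd10 <- 0
  state$dd0 <- 0
  state$lai <- 0
  state$peak_lai <- 0
  state$dm <- 0
  state$peak_dm <- 0
  state$t_leaf <- NA_real_
  state$stage4_onset <- as.Date(NA)
  state
}
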