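#' Kill-event rules
#'
#' Thresholds governing winter kill, drought kill and in-season frost kill.
#' The default winter rule counts dormant-season days whose minimum
#' temperature falls below the ecotype's absolute tolerated minimum
#' (-23.3 C lowland, -34.4 C upland) and kills the stand when the count
#' reaches `kill_day_threshold` (60). An alternative chill-day rule counts
#' days below `chill_temp` instead.
#'
#' @param t_kill Absolute minimum tolerated temperature (degrees C).
#' @param kill_day_threshold Number of qualifying winter days that kills,
#'   default 60.
#' @param chill_temp Threshold of the alternative chill-day rule (degrees C),
#'   default 0.
#' @param winterkill_mode `"absolute"` (default) or `"chill"`.
#' @param drought_kill_days Consecutive growing-season days below the wilt
#'   point that terminate the season (shoot death), default 30.
#' @param frost_soil_temp Soil temperature at 10 cm below which in-season
#'   frost damage accrues (degrees C), default 0.
#' @param frost_days Consecutive qualifying frost days forcing premature
#'   senescence, default 5.
#' @param soil_damping Daily damping of the air-to-soil temperature filter,
#'   default 0.2.
#' @return A `kill_rules` list.
#' @export
kill_rules <- function(t_kill, kill_day_threshold = 60, chill_temp = 0,
                       winterkill_mode = c("absolute", "chill"),
                       drought_kill_days = 30,
                       frost_soil_temp = 0, frost_days = 5,
                       soil_damping = 0.2) {
  winterkill_mode <- match.arg(winterkill_mode)
  if (!(t_kill < chill_temp)) stop("t_kill must be below chill_temp")
  if (kill_day_threshold < 1 || drought_kill_days < 1 || frost_days < 1) {
    stop("day thresholds must be >= 1")
  }
  structure(list(t_kill = t_kill, kill_day_threshold = kill_day_threshold,
                 chill_temp = chill_temp, winterkill_mode = winterkill_mode,
                 drought_kill_days = drought_kill_days,
                 frost_soil_temp = frost_soil_temp, frost_days = frost_days,
                 soil_damping = soil_damping),
            class = "kill_rules")
}

#' Winter-kill check over a dormant season
#'
#' Count-based (order-invariant within the window): under the default
#' absolute rule the stand is killed when the number of days with
#' `tmin < t_kill` reaches `kill_day_threshold`; under the chill rule the
#' count is of days with `tmin < chill_temp`.
#'
#' @param winter_tmin Daily minimum temperatures over one dormant season
#'   (degrees C).
#' @param rules A [kill_rules()] object.
#' @return List with `killed` (logical), `cause` (`"winter_kill"` or
#'   `"none"`) and `days` (the qualifying-day count).
#' @export
check_winter_kill <- function(winter_tmin, rules) {
  stopifnot(inherits(rules, "kill_rules"))
  threshold <- switch(rules$winterkill_mode,
                      absolute = rules$t_kill,
                      chill = rules$chill_temp)
  n <- sum(winter_tmin < threshold)
  killed <- n >= rules$kill_day_threshold
  list(killed = killed,
       cause = if (killed) "winter_kill" else "none",
       days = n)
}

#' Drought-kill check over a growing season
#'
#' Two levels of damage: a spell of `drought_kill_days` consecutive days with
#' the matric potential below the wilt point (-2 MPa) terminates the season
#' (shoot death; the stand regrows next year), while any day at or below the
#' necrosis potential (-11 MPa) kills the plant outright.
#'
#' @param psi Growing-season matric potential series (kPa, negative).
#' @param rules A [kill_rules()] object.
#' @param psi_wp Wilt-point potential (kPa), default -2000.
#' @param psi_floor Necrosis potential (kPa), default -11000.
#' @return `"plant_death"`, `"shoot_death"` or `"none"`.
#' @export
check_drought_kill <- function(psi, rules, psi_wp = -2000, psi_floor = -11000) {
  stopifnot(inherits(rules, "kill_rules"))
  if (any(psi <= psi_floor)) return("plant_death")
  below <- psi < psi_wp
  if (max_run_length(below) >= rules$drought_kill_days) return("shoot_death")
  "none"
}

#' In-season frost-kill check
#'
#' Premature senescence when the 10-cm soil temperature stays below the
#' frost threshold for at least `frost_days` consecutive days during the
#' growing season.
#'
#' @param soil_t10 Daily soil temperature at 10 cm (degrees C).
#' @param rules A [kill_rules()] object.
#' @return List with `senescence` (logical) and the longest qualifying run.
#' @export
check_frost_kill <- function(soil_t10, rules) {
  stopifnot(inherits(rules, "kill_rules"))
  run <- max_run_length(soil_t10 < rules$frost_soil_temp)
  list(senescence = run >= rules$frost_days, run = run)
}

#' Soil temperature at 10 cm from air temperature
#'
#' Exponentially damped running mean of daily mean air temperature,
#' `T_s[i] = T_s[i-1] + damping * (tmean[i] - T_s[i-1])`, standing in for an
#' unobserved shallow soil temperature.
#'
#' @param tmean Daily mean air temperature series (degrees C).
#' @param damping Daily damping coefficient, default 0.2.
#' @param init Initial soil temperature; defaults to the first air value.
#' @return Soil temperature series (degrees C).
#' @export
soil_temperature_10cm <- function(tmean, damping = 0.2, init = tmean[1]) {
  as.numeric(stats::filter(damping * tmean, 1 - damping,
                           method = "recursive", init = init))
}

#' Harvest parameters
#'
#' @param harvest_ratio Harvestable fraction of peak dry matter after
#'   over-winter repartition and leaf fall, default 0.832 for both ecotypes.
#' @param harvest_month,harvest_day Calendar harvest date (default 1 March).
#' @return A `harvest_params` list.
#' @export
harvest_params <- function(harvest_ratio = 0.832,
                           harvest_month = 3, harvest_day = 1) {
  if (harvest_ratio <= 0 || harvest_ratio > 1) {
    stop("harvest_ratio must lie in (0, 1]")
  }
  structure(list(harvest_ratio = harvest_ratio,
                 harvest_month = harvest_month, harvest_day = harvest_day),
            class = "harvest_params")
}

#' Spring-harvestable yield from peak dry matter
#'
#' After the onset of plant senescence the standing dry matter declines
#' linearly until the March harvest; the harvested yield is the repartition
#' ratio times the seasonal peak.
#'
#' @param peak_dm Peak above-ground dry matter (Mg ha-1), non-negative.
#' @param harvest_ratio Repartition ratio, default 0.832.
#' @return Harvestable yield (Mg ha-1).
#' @export
#' @examples
#' harvestable_yield(10)     # 8.32
harvestable_yield <- function(peak_dm, harvest_ratio = 0.832) {
  if (any(peak_dm < 0)) stop("peak_dm must be non-negative")
  harvest_ratio * peak_dm
}

# longest run of TRUE in a logical vector
max_run_length <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
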