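#' Run a multi-year single-site simulation
#'
#' The daily orchestration loop: meteorological derivation, soil-water bucket
#' update, physiostat advancement, canopy/dry-matter dynamics and kill-event
#' monitoring, in that order, producing a daily trajectory and one annual
#' record per completed season. Seasons run from the annual reset (the
#' calendar harvest date, 1 March by default) to the following harvest, when
#' the spring-harvestable yield (`harvest_ratio` times the seasonal peak dry
#' matter, zero after plant death) is recorded.
#'
#' Kill handling: winter kill (counted over the dormant window from 1
#' November to harvest) and drought necrosis are plant deaths - the season's
#' yield is zero, the stand is replanted and the following establishment
#' season is flagged and also yields zero. A 30-day consecutive spell below
#' the wilt point is a shoot death: the season is terminated early (stage 4)
#' but the accumulated peak is still harvested. Sustained in-season soil
#' frost forces premature senescence.
#'
#' @param weather A [as_daily_weather()] series (or plain data frame
#'   accepted by it) covering the requested period contiguously. Supply
#'   weather through the harvest date following the last season of interest.
#' @param site A [site_info()].
#' @param soil A [soil_profile()].
#' @param params A [genotype_defaults()] parameter set.
#' @param pet_method `"auto"` (Penman-Monteith when wind and humidity are
#'   present, else Thornthwaite), or one of the two methods explicitly.
#'   Ignored when the weather already carries a `pet` column.
#' @param init_swc Initial soil store (mm), default field capacity.
#' @return A `site_simulation` list: `daily` trajectory data frame
#'   (`date, stage, dd10, lai, dm, swc, psi, aet, drainage, soil_t10`),
#'   `annual` records (`year, peak_dm, yield, kill, establishment, replant`),
#'   `events` log, and `meta`.
#' @export
run_site <- function(weather, site, soil, params,
                     pet_method = c("auto", "penman_monteith", "thornthwaite"),
                     init_swc = NULL) {
  pet_method <- match.arg(pet_method)
  if (!inherits(weather, "daily_weather")) weather <- as_daily_weather(weather)
  stopifnot(inherits(site, "site_info"), inherits(soil, "soil_profile"),
            inherits(params, "genotype_params"))

  wx <- prepare_forcing(weather, site, pet_method)
  n <- nrow(wx)
  dates <- wx$date
  doy <- as.integer(format(dates, "%j"))
  mon <- as.integer(format(dates, "%m"))
  mday <- as.integer(format(dates, "%d"))
  yr <- as.integer(format(dates, "%Y"))

  ret <- campbell_parameters(soil)
  depth <- soil$depth
  sw <- soil_water_state(ret, depth, init_swc)
  swc_initial <- sw$swc
  thr <- physiostat_thresholds(params$dd_stage)

  plant <- new_plant_state()
  soil_t <- wx$tmean[1]
  season_year <- NA_integer_
  season_kill <- "none"
  zero_this_season <- FALSE    # establishment season following a plant death
  zero_next <- FALSE
  establishment <- TRUE        # planting-year flag for the first season
  replant <- FALSE
  dr_run <- 0L; fr_run <- 0L
  wk_days_abs <- 0L; wk_days_chill <- 0L
  tleaf_buf <- numeric(0)
  next_harvest <- NULL
  daylen <- day_length(site$latitude, doy)
  lg_full <- log(-params$psi_full)
  lg_stop_lai <- log(-params$psi_stop_lai)

  annual <- list(); events <- list()
  o_stage <- integer(n)
  o_dd10 <- o_dd0 <- o_lai <- o_dm <- o_swc <- o_psi <-
    o_aet <- o_drain <- o_soilt <- numeric(n)
  rules <- kill_rules(params$t_kill, params$kill_day_threshold,
                      params$chill_temp, params$winterkill_mode,
                      params$drought_kill_days, params$frost_soil_temp,
                      params$frost_days, params$soil_damping)

  log_event <- function(date, what, detail = "") {
    events[[length(events) + 1L]] <<- data.frame(
      date = date, event = what, detail = detail, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    d <- dates[i]

    # ---- season boundary: harvest then reset -------------------------------
    if (mon[i] == params$harvest_month && mday[i] == params$harvest_day) {
      if (!is.na(season_year)) {
        wk <- list(killed = switch(rules$winterkill_mode,
                                   absolute = wk_days_abs >= rules$kill_day_threshold,
                                   chill = wk_days_chill >= rules$kill_day_threshold))
        cause <- season_kill
        if (wk$killed) cause <- "winter_kill"
        plant_death <- cause %in% c("winter_kill", "drought_plant_death")
        # season ended before plant senescence onset: harvest from standing DM
        if (plant$stage < 4L && plant$alive) plant$peak_dm <- plant$dm
        yield <- if (plant_death || zero_this_season) 0 else {
          harvestable_yield(plant$peak_dm, params$harvest_ratio)
        }
        annual[[length(annual) + 1L]] <- data.frame(
          year = season_year, peak_dm = plant$peak_dm, yield = yield,
          kill = cause, establishment = establishment, replant = replant,
          stringsAsFactors = FALSE)
        if (wk$killed) log_event(d, "winter_kill",
                                 sprintf("%d qualifying days", switch(
                                   rules$winterkill_mode,
                                   absolute = wk_days_abs, chill = wk_days_chill)))
        if (plant_death) log_event(d, "replant", cause)
        zero_next <- plant_death
        replant <- plant_death
        establishment <- plant_death
      } else {
        replant <- FALSE
      }
      plant <- annual_reset(plant, d)
      plant$alive <- TRUE
      season_year <- yr[i]
      season_kill <- "none"
      zero_this_season <- zero_next
      zero_next <- FALSE
      dr_run <- 0L; fr_run <- 0L
      tleaf_buf <- numeric(0)
      next_harvest <- next_calendar_date(d, params$harvest_month,
                                         params$harvest_day)
    }

    # ---- dormant-window winter-kill counters -------------------------------
    if (mon[i] == 11L && mday[i] == 1L) {
      wk_days_abs <- 0L
      wk_days_chill <- 0L
    }
    if (wx$tmin[i] < rules$t_kill) wk_days_abs <- wk_days_abs + 1L
    if (wx$tmin[i] < rules$chill_temp) wk_days_chill <- wk_days_chill + 1L

    in_season <- !is.na(season_year)

    # ---- degree-day clocks -------------------------------------------------
    dd10_inc <- 0; dd0_inc <- 0
    if (in_season && plant$alive) {
      dd10_inc <- max(0, wx$tmean[i] - params$base_temp)
      dd0_inc <- max(0, wx$tmean[i] - params$base_temp_lai)
      plant$dd10 <- plant$dd10 + dd10_inc
      plant$dd0 <- plant$dd0 + dd0_inc
    }

    # ---- soil water --------------------------------------------------------
    wb <- update_water_balance(sw, wx$precip[i], wx$pet[i],
                               if (plant$alive) plant$lai else 0,
                               ret, depth,
                               params$psi_full, params$psi_stop_rue,
                               params$e_s, params$k_aet)
    sw <- wb$state
    soil_t <- soil_t + rules$soil_damping * (wx$tmean[i] - soil_t)

    if (in_season && plant$alive) {
      # ---- phenology -------------------------------------------------------
      triggers <- list(psi = sw$psi, tmean = wx$tmean[i],
                       frost_today = wx$tmin[i] < 0,
                       killing_frost = wx$tmin[i] < params$t_killing_frost,
                       day_length = daylen[i],
                       after_solstice = doy[i] > 172,
                       date = d)
      prev_stage <- plant$stage
      plant <- advance_physiostat(plant, triggers, thr, params)
      if (plant$stage != prev_stage) {
        log_event(d, "stage_transition",
                  sprintf("%d->%d at DD10 %.1f", prev_stage, plant$stage,
                          plant$dd10))
      }

      # ---- canopy ----------------------------------------------------------
      if (plant$stage >= 1L && plant$stage <= 3L) {
        tleaf_buf <- c(tleaf_buf, wx$tmean[i])
        if (length(tleaf_buf) > params$t_leaf_window) {
          tleaf_buf <- tleaf_buf[-1]
        }
        plant$t_leaf <- mean(tleaf_buf)
      }
      wf_lai <- (lg_stop_lai - log(-sw$psi)) / (lg_stop_lai - lg_full)
      wf_lai <- if (wf_lai < 0) 0 else if (wf_lai > 1) 1 else wf_lai
      plant <- update_lai(plant, dd0_inc, wf_lai, params)

      if (plant$stage == 2L || plant$stage == 3L) {
        tvf <- temperature_variation_factor(
          wx$tmean[i], if (is.na(plant$t_leaf)) wx$tmean[i] else plant$t_leaf,
          params$t_opt, params$tvf_sigma)
        lg_stop_rue <- log(-params$psi_stop_rue)
        wf_rue <- (lg_stop_rue - log(-sw$psi)) / (lg_stop_rue - lg_full)
        wf_rue <- if (wf_rue < 0) 0 else if (wf_rue > 1) 1 else wf_rue
        fi <- fraction_intercepted(params$k, plant$lai)
        plant$dm <- plant$dm +
          daily_dm_increment(params$rue_max, tvf, wf_rue, fi, wx$par[i])
      } else if (plant$stage >= 4L && !is.na(plant$stage4_onset)) {
        # linear repartition decline from peak to the spring-harvest ratio
        span <- as.numeric(next_harvest - plant$stage4_onset)
        frac <- if (span > 0) {
          min(1, as.numeric(d - plant$stage4_onset) / span)
        } else 1
        plant$dm <- plant$peak_dm * (1 - (1 - params$harvest_ratio) * frac)
      }

      # ---- kill events -----------------------------------------------------
      if (plant$stage >= 1L && plant$stage <= 4L) {
        if (sw$psi <= params$psi_floor + 1e-9) {
          plant$alive <- FALSE
          plant$lai <- 0
          season_kill <- "drought_plant_death"
          log_event(d, "drought_plant_death",
                    sprintf("psi %.0f kPa", sw$psi))
        } else {
          dr_run <- if (sw$psi < params$psi_stop_rue) dr_run + 1L else 0L
          if (dr_run >= rules$drought_kill_days && plant$stage <= 3L) {
            plant$stage <- 4L
            plant$peak_dm <- plant$dm
            plant$stage4_onset <- d
            season_kill <- "drought_shoot_death"
            log_event(d, "drought_shoot_death",
                      sprintf("%d days below wilt point", dr_run))
          }
          fr_run <- if (soil_t < rules$frost_soil_temp &&
                        plant$stage <= 3L) fr_run + 1L else 0L
          if (fr_run >= rules$frost_days && plant$stage <= 3L) {
            plant$stage <- 4L
            plant$peak_dm <- plant$dm
            plant$stage4_onset <- d
            if (season_kill == "none") season_kill <- "frost_senescence"
            log_event(d, "frost_senescence",
                      sprintf("%d days of soil frost", fr_run))
          }
        }
      }
    }

    o_stage[i] <- plant$stage
    o_dd10[i] <- plant$dd10
    o_dd0[i] <- plant$dd0
    o_lai[i] <- plant$lai
    o_dm[i] <- plant$dm
    o_swc[i] <- sw$swc
    o_psi[i] <- sw$psi
    o_aet[i] <- wb$aet
    o_drain[i] <- wb$drainage
    o_soilt[i] <- soil_t
  }
  out <- data.frame(date = dates, stage = o_stage, dd10 = o_dd10,
                    dd0 = o_dd0, lai = o_lai, dm = o_dm, swc = o_swc,
                    psi = o_psi, aet = o_aet, drainage = o_drain,
                    soil_t10 = o_soilt, pet = wx$pet)

  annual <- if (length(annual)) do.call(rbind, annual) else
    data.frame(year = integer(), peak_dm = numeric(), yield = numeric(),
               kill = character(), establishment = logical(),
               replant = logical())
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(date = as.Date(character()), event = character(),
               detail = character())
  structure(list(daily = out, annual = annual, events = events,
                 meta = list(genotype = params$name, ecotype = params$ecotype,
                             site = site, soil = soil,
                             pet_method = attr(wx, "pet_method"),
                             init_swc = swc_initial)),
            class = "site_simulation")
}

#' @export
print.site_simulation <- function(x, ...) {
  cat("<site_simulation> ", x$meta$genotype, " (", x$meta$ecotype, "), ",
      nrow(x$daily), " days, ", nrow(x$annual), " season(s)\n", sep = "")
  if (nrow(x$annual)) {
    cat(sprintf("  mean yield %.2f Mg/ha  (PET: %s)\n",
                mean(x$annual$yield), x$meta$pet_method))
  }
  invisible(x)
}

#' Mean annual harvestable yield
#'
#' Arithmetic mean of the seasonal harvest yields over a year range.
#' Kill-year zeros are included by default; establishment seasons that follow
#' a plant death (replant years) are excluded, as are ordinary establishment
#' years when `include_establishment = FALSE`.
#'
#' @param result A [run_site()] result.
#' @param period Optional integer year range (e.g. `2006:2016`).
#' @param include_establishment Keep the ordinary planting-year season,
#'   default `TRUE`.
#' @return Mean yield (Mg ha-1).
#' @export
mean_annual_yield <- function(result, period = NULL,
                              include_establishment = TRUE) {
  stopifnot(inherits(result, "site_simulation"))
  a <- result$annual
  if (!is.null(period)) a <- a[a$year %in% period, , drop = FALSE]
  a <- a[!a$replant, , drop = FALSE]
  if (!include_establishment) a <- a[!a$establishment, , drop = FALSE]
  if (!nrow(a)) stop("no seasons in the requested period")
  mean(a$yield)
}

# Attach tmean/par/pet forcing columns, choosing the PET method.
prepare_forcing <- function(weather, site, pet_method) {
  wx <- as.data.frame(weather)
  doy <- as.integer(format(wx$date, "%j"))
  method <- "supplied"
  if (is.null(wx$pet) || all(is.na(wx$pet))) {
    has_pm <- !is.null(wx$wind) && !all(is.na(wx$wind)) &&
      !is.null(wx$rh) && !all(is.na(wx$rh))
    use_pm <- switch(pet_method,
                     auto = has_pm,
                     penman_monteith = TRUE,
                     thornthwaite = FALSE)
    if (use_pm) {
      wx$pet <- pet_penman_monteith(wx$tmin, wx$tmax, wx$solar, wx$wind,
                                    doy, site$latitude, site$elevation,
                                    rh = wx$rh)
      method <- "penman_monteith"
    } else {
      wx$pet <- pet_thornthwaite(wx$tmean, wx$date, site$latitude)
      method <- "thornthwaite"
    }
  }
  attr(wx, "pet_method") <- method
  wx
}

# First occurrence of month/day strictly after `date`.
next_calendar_date <- function(date, month, day) {
  y <- as.integer(format(date, "%Y"))
  cand <- as.Date(sprintf("%d-%02d-%02d", y, month, day))
  if (cand <= date) cand <- as.Date(sprintf("%d-%02d-%02d", y + 1L, month, day))
  cand
}
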