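#' Default genotype parameter sets
#'
#' The complete ecotype-specific constant registry driving the simulator.
#' The lowland set is parameterised on Alamo, the upland set on Cave-in-Rock
#' (CIR):
#'
#' * physiostat DD10 thresholds: 105/168/1174/1566/1694 (lowland),
#'   80/125/1085/1395/1488 (upland);
#' * canopy: extinction coefficient `k = 0.36` for both ecotypes, maximum LAI
#'   12 vs 7, leaf-expansion DD0 factor 0.004 vs 0.006, LAI senescence rate
#'   0.03 vs 0.049 day-1;
#' * radiation-use efficiency: maximum 5.05 vs 3.19 g DM per MJ intercepted
#'   PAR, optimal growing-season temperature 28 vs 23 C;
#' * water stress: full supply at -10 kPa, leaf expansion stops at -1 MPa,
#'   photosynthesis at -2 MPa, emergence requires at least -0.3 MPa,
#'   necrosis at -11 MPa;
#' * kill rules: absolute winter minimum -23.3 vs -34.4 C sustained for 60
#'   days; 30 consecutive days below the wilt point terminate the season;
#' * harvest: spring harvest (1 March) at 0.832 of the seasonal peak dry
#'   matter for both ecotypes.
#'
#' @param ecotype `"lowland"` or `"upland"`.
#' @return A `genotype_params` list; see [genotype_params()] for overriding
#'   individual entries.
#' @export
#' @examples
#' genotype_defaults("lowland")$rue_max   # 5.05
genotype_defaults <- function(ecotype = c("lowland", "upland")) {
  ecotype <- match.arg(ecotype)
  base <- list(
    # canopy / RUE
    k = 0.36, tvf_sigma = 8, t_leaf_window = 30, senescence_mode = "linear",
    # degree-day bases
    base_temp = 10, base_temp_lai = 0,
    # water-stress anchors (kPa)
    psi_full = -10, psi_stop_lai = -1000, psi_stop_rue = -2000,
    psi_emergence = -300, psi_floor = -11000,
    # AET canopy factor
    e_s = 0.2, k_aet = 0.36,
    # kill rules shared across ecotypes
    kill_day_threshold = 60, chill_temp = 0, winterkill_mode = "absolute",
    drought_kill_days = 30, frost_soil_temp = 0, frost_days = 5,
    soil_damping = 0.2, t_killing_frost = -5,
    # harvest
    harvest_ratio = 0.832, harvest_month = 3, harvest_day = 1,
    # photoperiod brake (inert unless enabled)
    photoperiod_hours = 12.5, photoperiod_enabled = FALSE
  )
  eco <- if (ecotype == "lowland") {
    list(name = "Alamo", ecotype = "lowland",
         dd_stage = c(105, 168, 1174, 1566, 1694),
         lai_max = 12, dd_lai_factor = 0.004, lai_senescence_rate = 0.03,
         rue_max = 5.05, t_opt = 28, t_kill = -23.3)
  } else {
    list(name = "Cave-in-Rock", ecotype = "upland",
         dd_stage = c(80, 125, 1085, 1395, 1488),
         lai_max = 7, dd_lai_factor = 0.006, lai_senescence_rate = 0.049,
         rue_max = 3.19, t_opt = 23, t_kill = -34.4)
  }
  genotype_params(c(eco, base))
}

#' Construct or override a genotype parameter set
#'
#' Validates the self-consistency of a full parameter list, or applies
#' overrides to an existing set so new cultivars can be parameterised
#' without code changes.
#'
#' @param params Named list with the full field set (see
#'   [genotype_defaults()]), or an existing `genotype_params` object when
#'   `...` overrides are given.
#' @param ... Named overrides, e.g. `rue_max = 4.7`.
#' @return A validated `genotype_params` list.
#' @export
genotype_params <- function(params, ...) {
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(params))
    if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    params <- utils::modifyList(params, over)
  }
  p <- params
  physiostat_thresholds(p$dd_stage)       # validates ordering
  stopifnot(p$k > 0, p$lai_max >= 1, p$dd_lai_factor > 0,
            p$lai_senescence_rate > 0, p$rue_max > 0, p$tvf_sigma > 0)
  if (!(p$psi_stop_rue < p$psi_stop_lai && p$psi_stop_lai < p$psi_full &&
        p$psi_full < 0)) {
    stop("stress anchors must order psi_stop_rue < psi_stop_lai < psi_full < 0")
  }
  if (p$psi_floor >= p$psi_stop_rue) stop("psi_floor must be below psi_stop_rue")
  kill_rules(p$t_kill, p$kill_day_threshold, p$chill_temp, p$winterkill_mode,
             p$drought_kill_days, p$frost_soil_temp, p$frost_days,
             p$soil_damping)              # validates kill thresholds
  harvest_params(p$harvest_ratio, p$harvest_month, p$harvest_day)
  structure(p, class = "genotype_params")
}

#' @export
print.genotype_params <- function(x, ...) {
  cat("<genotype_params> ", x$name, " (", x$ecotype, ")\n", sep = "")
  cat("  DD10 stages:", paste(x$dd_stage, collapse = "/"), "\n")
  cat(sprintf("  k %.2f  LAImax %g  DD-LAI %.3f  senescence %.3f /day\n",
              x$k, x$lai_max, x$dd_lai_factor, x$lai_senescence_rate))
  cat(sprintf("  RUEmax %.2f g/MJ  Topt %g C  t_kill %.1f C  harvest ratio %.3f\n",
              x$rue_max, x$t_opt, x$t_kill, x$harvest_ratio))
  invisible(x)
}
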