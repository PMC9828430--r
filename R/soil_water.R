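#' Soil profile description
#'
#' Texture mass fractions, organic carbon, bulk density and rooted depth of
#' the single-layer soil bucket.
#'
#' @param sand,silt,clay Mass fractions, must sum to 1 within 0.01.
#' @param soc Soil organic carbon mass fraction.
#' @param bulk_density Dry bulk density (g cm-3), in (0.5, 2.2).
#' @param depth Rooted profile depth (mm), default 1000.
#' @return A `soil_profile` list.
#' @export
#' @examples
#' soil_profile(0.40, 0.40, 0.20)   # loam
soil_profile <- function(sand, silt, clay, soc = 0.01,
                         bulk_density = 1.3, depth = 1000) {
  fr <- c(sand, silt, clay)
  if (any(fr < 0) || any(fr > 1)) stop("texture fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 0.01) stop("sand + silt + clay must sum to 1 (+- 0.01)")
  if (soc < 0 || soc > 0.6) stop("soc fraction out of range")
  if (bulk_density <= 0.5 || bulk_density >= 2.2) {
    stop("bulk_density must lie in (0.5, 2.2) g cm-3")
  }
  if (depth <= 0) stop("depth must be positive")
  structure(list(sand = sand, silt = silt, clay = clay, soc = soc,
                 bulk_density = bulk_density, depth = depth),
            class = "soil_profile")
}

#' Campbell retention-curve parameters from a soil profile
#'
#' Pedotransfer parameterisation of the Campbell water-retention curve
#' `theta(psi) = theta_s * (psi/psi_e)^(-1/b)`. Saturated content comes from
#' bulk density with an organic-matter particle-density correction; the
#' exponent `b` and air-entry potential `psi_e` come from the Cosby et al.
#' sand/clay regressions. Field capacity, wilt point and the extractable-water
#' floor are the curve evaluated at -10 kPa, -2 MPa and -11 MPa.
#'
#' @param profile A [soil_profile()].
#' @return A `retention_params` list with `theta_s`, `psi_e` (kPa, negative),
#'   `b`, `theta_fc`, `theta_wp`, `theta_floor`.
#' @export
campbell_parameters <- function(profile) {
  stopifnot(inherits(profile, "soil_profile"))
  # particle density of the mineral/organic mixture (g cm-3)
  rho_p <- 1 / (profile$soc / 1.3 + (1 - profile$soc) / 2.65)
  theta_s <- 1 - profile$bulk_density / rho_p
  if (theta_s <= 0.05 || theta_s >= 1) stop("implausible porosity from bulk density")
  sandpct <- profile$sand * 100
  claypct <- profile$clay * 100
  b <- 3.10 + 0.157 * claypct - 0.003 * sandpct
  # Cosby air-entry head in cm H2O -> kPa (1 cm H2O = 0.0980665 kPa)
  psi_e <- -0.0980665 * 10^(1.88 - 0.0131 * sandpct)
  theta_at <- function(psi) {
    ifelse(abs(psi) <= abs(psi_e), theta_s,
           theta_s * (psi / psi_e)^(-1 / b))
  }
  out <- list(theta_s = theta_s, psi_e = psi_e, b = b,
              theta_fc = theta_at(-10),
              theta_wp = theta_at(-2000),
              theta_floor = theta_at(-11000))
  if (!(0 < out$theta_floor && out$theta_floor < out$theta_wp &&
        out$theta_wp < out$theta_fc && out$theta_fc < out$theta_s)) {
    stop("retention parameters violate theta_floor < theta_wp < theta_fc < theta_s")
  }
  class(out) <- "retention_params"
  out
}

#' Volumetric water content at a matric potential
#'
#' The Campbell curve evaluated at `psi`; contents at potentials wetter than
#' the air-entry value saturate at `theta_s`.
#'
#' @param psi Matric potential (kPa, negative), vectorised.
#' @param params A [campbell_parameters()] object.
#' @return Volumetric water content (m3 m-3).
#' @export
theta_at_potential <- function(psi, params) {
  if (any(psi >= 0)) stop("matric potential must be negative")
  ifelse(abs(psi) <= abs(params$psi_e), params$theta_s,
         params$theta_s * (psi / params$psi_e)^(-1 / params$b))
}

#' Matric potential of the soil store
#'
#' Inverts the Campbell curve for the current bucket store:
#' `psi = psi_e * (theta/theta_s)^(-b)` with `theta = swc/depth`. Contents
#' outside the physical range are clamped and flagged via the
#' `"clamped"` attribute.
#'
#' @param swc Stored water over the profile (mm).
#' @param params A [campbell_parameters()] object.
#' @param depth Profile depth (mm).
#' @return Matric potential (kPa, negative); more water gives a less negative
#'   potential.
#' @export
water_potential <- function(swc, params, depth) {
  theta <- swc / depth
  clamped <- theta < 1e-6 | theta > params$theta_s
  theta <- pmin(pmax(theta, 1e-6), params$theta_s)
  psi <- params$psi_e * (theta / params$theta_s)^(-params$b)
  attr(psi, "clamped") <- any(clamped)
  psi
}

#' Log-linear water-stress downregulation factor
#'
#' The multiplicative stress factor applied to leaf expansion and to
#' radiation-use efficiency: linear in `ln|psi|` between the full-supply
#' anchor (field capacity, -10 kPa, factor 1) and the process-specific stop
#' potential (factor 0), clipped to `[0, 1]`.
#'
#' @param psi Matric potential (kPa, negative), vectorised.
#' @param psi_full Potential at which the factor is 1 (default -10 kPa).
#' @param psi_stop Potential at which the process ceases (-1000 kPa for leaf
#'   expansion, -2000 kPa for photosynthesis).
#' @return Dimensionless factor in `[0, 1]`.
#' @export
#' @examples
#' downregulation_factor(-141.42, psi_stop = -2000)  # log-midpoint: 0.5
downregulation_factor <- function(psi, psi_full = -10, psi_stop = -2000) {
  if (any(c(psi, psi_full, psi_stop) >= 0)) {
    stop("potentials must be negative (kPa)")
  }
  if (!(abs(psi_full) < abs(psi_stop))) {
    stop("psi_full must be wetter (less negative) than psi_stop")
  }
  f <- (log(abs(psi_stop)) - log(abs(psi))) /
    (log(abs(psi_stop)) - log(abs(psi_full)))
  pmin(1, pmax(0, f))
}

#' Actual evapotranspiration
#'
#' AET as a proportion of PET set by the interaction of canopy development
#' and soil moisture: `AET = PET * C(LAI) * f_w(psi)` with canopy factor
#' `C = e_s + (1 - e_s) * (1 - exp(-k_aet * LAI))` (a bare-soil evaporative
#' fraction plus intercepted-cover transpiration) and `f_w` the
#' photosynthesis water-stress factor, so AET falls to zero at the stop
#' potential and approaches PET under a closed canopy at field capacity.
#'
#' @param pet Potential evapotranspiration (mm day-1), non-negative.
#' @param lai Leaf area index, non-negative.
#' @param psi Matric potential (kPa, negative).
#' @param psi_full,psi_stop Stress anchors passed to
#'   [downregulation_factor()].
#' @param e_s Bare-soil evaporative fraction of PET, default 0.2.
#' @param k_aet Canopy extinction coefficient for the cover factor,
#'   default 0.36.
#' @return AET (mm day-1), `0 <= AET <= PET`.
#' @export
actual_evapotranspiration <- function(pet, lai, psi,
                                      psi_full = -10, psi_stop = -2000,
                                      e_s = 0.2, k_aet = 0.36) {
  if (any(pet < 0)) stop("pet must be non-negative")
  if (any(lai < 0)) stop("lai must be non-negative")
  cover <- e_s + (1 - e_s) * (1 - exp(-k_aet * lai))
  pet * cover * downregulation_factor(psi, psi_full, psi_stop)
}

#' Initialise the soil-water bucket state
#'
#' @param params A [campbell_parameters()] object.
#' @param depth Profile depth (mm).
#' @param swc Initial store (mm); defaults to field capacity.
#' @return A `soil_water_state` list with `swc`, `psi`, `swd`.
#' @export
soil_water_state <- function(params, depth, swc = NULL) {
  if (is.null(swc)) swc <- params$theta_fc * depth
  psi <- water_potential(swc, params, depth)
  structure(list(swc = swc,
                 psi = as.numeric(psi),
                 swd = max(0, params$theta_fc * depth - swc)),
            class = "soil_water_state")
}

#' Daily soil-water bucket update
#'
#' Free-draining single-layer bucket: the store gains precipitation, loses
#' AET (capped so the store never drops below the extractable-water floor at
#' -11 MPa) and drains instantaneously above field capacity. Conservation is
#' exact: `precip - aet - drainage = swc' - swc`.
#'
#' @param state A [soil_water_state()].
#' @param precip Precipitation (mm).
#' @param pet Potential evapotranspiration (mm).
#' @param lai Leaf area index of the current canopy.
#' @param params A [campbell_parameters()] object.
#' @param depth Profile depth (mm).
#' @param psi_full,psi_stop,e_s,k_aet Passed to
#'   [actual_evapotranspiration()].
#' @return List with updated `state`, realised `aet` (mm) and `drainage` (mm).
#' @export
update_water_balance <- function(state, precip, pet, lai, params, depth,
                                 psi_full = -10, psi_stop = -2000,
                                 e_s = 0.2, k_aet = 0.36) {
  stopifnot(inherits(state, "soil_water_state"))
  floor_mm <- params$theta_floor * depth
  fc_mm <- params$theta_fc * depth
  # scalar fast path of actual_evapotranspiration()
  cover <- e_s + (1 - e_s) * (1 - exp(-k_aet * lai))
  fw <- (log(-psi_stop) - log(-state$psi)) / (log(-psi_stop) - log(-psi_full))
  fw <- if (fw < 0) 0 else if (fw > 1) 1 else fw
  aet <- pet * cover * fw
  avail <- state$swc + precip - floor_mm
  if (aet > avail) aet <- if (avail > 0) avail else 0
  drainage <- state$swc + precip - aet - fc_mm
  if (drainage < 0) drainage <- 0
  swc2 <- state$swc + precip - aet - drainage
  theta <- swc2 / depth
  if (theta > params$theta_s) theta <- params$theta_s
  if (theta < 1e-6) theta <- 1e-6
  psi2 <- params$psi_e * (theta / params$theta_s)^(-params$b)
  swd <- fc_mm - swc2
  list(state = structure(list(swc = swc2, psi = psi2,
                              swd = if (swd > 0) swd else 0),
                         class = "soil_water_state"),
       aet = aet, drainage = drainage)
}
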