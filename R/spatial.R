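#' Yield raster container
#'
#' A lightweight matrix-backed, north-up geographic raster: cell values are
#' mean harvestable yields (Mg ha-1) with `NA` for non-adapted or masked
#' cells, optionally accompanied by a winner-ecotype label layer (0 upland,
#' 1 lowland).
#'
#' @param values Numeric matrix (row 1 = northern edge).
#' @param ecotype Optional label matrix of the same dimension.
#' @param lat0,lon0 Latitude/longitude of the north-west cell centre.
#' @param res Cell size (degrees).
#' @param crs CRS identifier string, default `"EPSG:4326"`.
#' @return A `yield_raster` object.
#' @export
yield_raster <- function(values, ecotype = NULL, lat0 = 36, lon0 = 108,
                         res = 0.5, crs = "EPSG:4326") {
  stopifnot(is.matrix(values))
  if (!is.null(ecotype)) {
    stopifnot(identical(dim(ecotype), dim(values)))
    if (any(!is.na(ecotype) & is.na(values))) {
      stop("ecotype labels present where yield is NoData")
    }
  }
  if (any(values < 0, na.rm = TRUE)) stop("yields must be >= 0 or NA")
  structure(list(values = values, ecotype = ecotype,
                 lat0 = lat0, lon0 = lon0, res = res, crs = crs),
            class = "yield_raster")
}

#' @export
print.yield_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<yield_raster> %d x %d cells, %.2f deg, %s\n",
              nrow(v), ncol(v), x$res, x$crs))
  cat(sprintf("  %d valid cells, mean %.2f Mg/ha%s\n",
              sum(!is.na(v)),
              if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA,
              if (is.null(x$ecotype)) "" else ", with ecotype labels"))
  invisible(x)
}

#' Run the simulator over a climate grid
#'
#' Executes [run_site()] in every cell of a [generate_grid()] cube and
#' returns the per-cell mean annual yield. Cells where the ecotype suffers
#' more plant-death events (winter kill or drought necrosis, i.e. replant
#' years) than `max_kill_years` are outside the adaptation zone and become
#' `NA`.
#'
#' @param cube A `climate_cube`.
#' @param params A [genotype_defaults()] parameter set.
#' @param period Optional year range passed to [mean_annual_yield()].
#' @param max_kill_years Tolerated plant-death count per cell, default 0
#'   (any death excludes the cell).
#' @return A [yield_raster()].
#' @export
run_grid <- function(cube, params, period = NULL, max_kill_years = 0) {
  stopifnot(inherits(cube, "climate_cube"),
            inherits(params, "genotype_params"))
  vals <- matrix(NA_real_, cube$ny, cube$nx)
  for (r in seq_len(cube$ny)) {
    for (c in seq_len(cube$nx)) {
      cell <- cube$cells[[(r - 1) * cube$nx + c]]
      sim <- run_site(cell$weather, cell$site, cell$soil, params)
      deaths <- sum(sim$annual$kill %in% c("winter_kill",
                                           "drought_plant_death"))
      if (deaths > max_kill_years) next
      vals[r, c] <- mean_annual_yield(sim, period)
    }
  }
  yield_raster(vals, lat0 = cube$lat0, lon0 = cube$lon0, res = cube$res)
}

#' Optimal-ecotype yield map
#'
#' Cellwise maximum of the upland and lowland yield rasters with the winning
#' ecotype labelled (0 upland, 1 lowland). Ties go to upland (the wider
#' adaptation zone); a cell is NoData only where both inputs are.
#'
#' @param upland,lowland Co-registered [yield_raster()] objects.
#' @return A [yield_raster()] with an `ecotype` label layer.
#' @export
optimal_map <- function(upland, lowland) {
  stopifnot(inherits(upland, "yield_raster"), inherits(lowland, "yield_raster"))
  u <- upland$values; l <- lowland$values
  if (!identical(dim(u), dim(l))) stop("raster grids do not match")
  if (upland$res != lowland$res) stop("raster resolutions do not match")
  lowland_wins <- !is.na(l) & (is.na(u) | l > u)
  vals <- ifelse(lowland_wins, l, u)
  label <- matrix(NA_real_, nrow(u), ncol(u))
  label[lowland_wins] <- 1
  label[!lowland_wins & !is.na(u)] <- 0
  yield_raster(vals, ecotype = label, lat0 = upland$lat0, lon0 = upland$lon0,
               res = upland$res, crs = upland$crs)
}

#' Apply availability and slope masks
#'
#' Cells outside the binary availability mask, or steeper than the slope
#' limit (strictly greater than 15 degrees by default), become NoData.
#'
#' @param yields A [yield_raster()].
#' @param mask Logical matrix of available cells.
#' @param slope Optional slope raster (degrees).
#' @param slope_limit Exclusion threshold (degrees), exceeded strictly.
#' @return The masked [yield_raster()].
#' @export
apply_mask <- function(yields, mask, slope = NULL, slope_limit = 15) {
  stopifnot(inherits(yields, "yield_raster"))
  v <- yields$values
  if (!identical(dim(mask), dim(v))) stop("mask grid does not match")
  v[!mask] <- NA
  if (!is.null(slope)) {
    if (!identical(dim(slope), dim(v))) stop("slope grid does not match")
    v[slope > slope_limit] <- NA
  }
  out <- yields
  out$values <- v
  if (!is.null(out$ecotype)) out$ecotype[is.na(v)] <- NA
  out
}

#' Area-weighted yield totals
#'
#' Aggregates a yield raster to total biomass (Tg), area-weighted mean yield
#' (Mg ha-1) and total adapted area (M ha), over non-NoData cells.
#'
#' @param yields A [yield_raster()].
#' @param cell_area_ha Cell areas in hectares: a scalar (equal-area grid) or
#'   a matrix (e.g. from [geographic_cell_area()]).
#' @return List with `total_Tg`, `weighted_mean`, `area_Mha`, `n_cells`.
#' @export
aggregate_totals <- function(yields, cell_area_ha) {
  stopifnot(inherits(yields, "yield_raster"))
  v <- yields$values
  a <- if (length(cell_area_ha) == 1L) {
    matrix(cell_area_ha, nrow(v), ncol(v))
  } else cell_area_ha
  if (!identical(dim(a), dim(v))) stop("area grid does not match")
  ok <- !is.na(v)
  total_Mg <- sum(v[ok] * a[ok])
  area <- sum(a[ok])
  list(total_Tg = total_Mg * 1e-6,
       weighted_mean = if (area > 0) total_Mg / area else NA_real_,
       area_Mha = area / 1e6,
       n_cells = sum(ok))
}

#' Geographic cell area by the cosine rule
#'
#' Area of a `res x res` degree cell centred at a given latitude,
#' `(111320 res)^2 cos(lat)` square metres, in hectares.
#'
#' @param latitude Cell-centre latitude (degrees), vectorised.
#' @param res Cell size (degrees).
#' @return Area (ha).
#' @export
geographic_cell_area <- function(latitude, res) {
  (111320 * res)^2 * cos(latitude * pi / 180) / 1e4
}

#' Write a yield raster as an ESRI ASCII grid
#'
#' Plain-text north-up grid with a `-9999` NoData value, readable by common
#' GIS tools.
#'
#' @param x A [yield_raster()].
#' @param path Output file path.
#' @param nodata NoData sentinel, default -9999.
#' @return `path`, invisibly.
#' @export
write_yield_raster <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "yield_raster"))
  v <- x$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", x$lon0 - x$res / 2),
           sprintf("yllcorner %.10g", x$lat0 - (nr - 1) * x$res - x$res / 2),
           sprintf("cellsize %.10g", x$res),
           sprintf("NODATA_value %g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(row) paste(format(row, trim = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a yield raster
#'
#' @param path Path to an ASCII grid written by [write_yield_raster()].
#' @return A [yield_raster()].
#' @export
read_yield_raster <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  nc <- val(1); nr <- val(2)
  xll <- val(3); yll <- val(4); res <- val(5); nodata <- val(6)
  body <- lines[-(1:6)]
  v <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  stopifnot(nrow(v) == nr, ncol(v) == nc)
  v[v == nodata] <- NA
  yield_raster(v, lat0 = yll + (nr - 1) * res + res / 2,
               lon0 = xll + res / 2, res = res)
}
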