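#' Goodness-of-fit statistics for modelled vs measured yields
#'
#' Modval-style summary of a set of (measured, modelled) pairs:
#' * `r2` - squared Pearson correlation of modelled against measured (the
#'   regression-based coefficient of determination);
#' * `rmse` - root-mean-squared error, `sqrt(mean((modelled - measured)^2))`,
#'   in the units of the yields;
#' * `bias` - `mean(modelled - measured)`;
#' * `efficiency` - the alternative 1 - SSE/SST statistic about the measured
#'   mean (model efficiency; can be negative).
#'
#' @param measured Measured yields (Mg ha-1), or a data frame with
#'   `measured` and `modelled` columns (e.g. from [table3_fixture()]).
#' @param modelled Modelled yields, when `measured` is a vector.
#' @return A `fit_stats` list with `n`, `r2`, `rmse`, `bias`, `efficiency`.
#' @export
#' @examples
#' fit_stats(table3_fixture("lowland"))
fit_stats <- function(measured, modelled = NULL) {
  if (is.data.frame(measured)) {
    modelled <- measured$modelled
    measured <- measured$measured
  }
  if (length(measured) != length(modelled)) stop("pair lengths differ")
  n <- length(measured)
  if (n < 3L) stop("at least 3 pairs required")
  if (any(measured < 0) || any(modelled < 0)) stop("yields must be non-negative")
  degenerate <- stats::sd(measured) == 0 || stats::sd(modelled) == 0
  if (degenerate) warning("zero-variance input; r2 undefined")
  r2 <- if (degenerate) NA_real_ else stats::cor(measured, modelled)^2
  sse <- sum((modelled - measured)^2)
  sst <- sum((measured - mean(measured))^2)
  structure(list(n = n, r2 = r2,
                 rmse = sqrt(mean((modelled - measured)^2)),
                 bias = mean(modelled - measured),
                 efficiency = if (sst > 0) 1 - sse / sst else NA_real_),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("<fit_stats> n = %d  r2 = %.3f  RMSE = %.3f  bias = %+.3f  EF = %.3f\n",
              x$n, x$r2, x$rmse, x$bias, x$efficiency))
  invisible(x)
}

#' Packaged multi-site validation yield pairs
#'
#' Field-trial measured yields and the corresponding reference modelled
#' yields for upland and lowland switchgrass across China, the US, Canada
#' and Europe (14 sites, harvest years 1990-2016), shipped as a plain
#' delimited fixture so the validation statistics are reproducible without
#' downloads.
#'
#' @param subset `"all"`, `"upland"` or `"lowland"`.
#' @return Data frame with `site, country, latitude, longitude, cultivar,
#'   ecotype, harvest_year, measured, modelled`.
#' @export
table3_fixture <- function(subset = c("all", "upland", "lowland")) {
  subset <- match.arg(subset)
  path <- system.file("extdata", "validation_yield_pairs.csv",
                      package = "switchgrow", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (subset != "all") df <- df[df$ecotype == subset, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Packaged canopy extinction coefficient census
#'
#' The literature census of Beer's-law extinction coefficients (`k`) for
#' switchgrass cultivars used to fix the canopy parameter; 34 entries across
#' cultivars and sites, with the differing sign conventions of the source
#' studies preserved.
#'
#' @return Data frame with `cultivar` and `k`.
#' @export
extinction_coefficient_census <- function() {
  path <- system.file("extdata", "extinction_coefficients.csv",
                      package = "switchgrow", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Median canopy extinction coefficient
#'
#' Median of the absolute values (source tables mix sign conventions for the
#' Beer's-law exponent; magnitudes are compared).
#'
#' @param k_values Numeric vector of extinction coefficients.
#' @return The median absolute value.
#' @export
#' @examples
#' median_extinction_coefficient(extinction_coefficient_census()$k)
median_extinction_coefficient <- function(k_values) {
  if (!length(k_values)) stop("empty k vector")
  stats::median(abs(k_values))
}
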