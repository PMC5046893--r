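#' Seasonality parameters for the synthetic environment
#'
#' Returns the parameter list consumed by \code{\link{generateEnvironment}}.
#' The default preset emulates a tropical savanna: warm with weak thermal
#' seasonality and a pronounced wet/dry productivity cycle.
#'
#' @param meanTemperature annual mean air temperature, degrees C.
#' @param temperatureAmplitude semi-amplitude of the annual temperature
#'   cycle, degrees C.
#' @param meanNpp annual mean net primary productivity, kg biomass per km^2
#'   per month. The default 5e4 corresponds to roughly 0.6 kg dry mass per
#'   m^2 per year, typical of savanna systems.
#' @param nppSeasonalAmplitude relative semi-amplitude of the wet/dry NPP
#'   cycle, in [0, 1).
#' @param phaseMonth calendar month (1-12) of the seasonal peak.
#' @param spatialNoise relative scale of smooth cell-to-cell variation in
#'   both surfaces (standard deviation as a fraction of the mean).
#' @return named list of seasonality parameters.
#' @export
savannaParams <- function(meanTemperature = 25, temperatureAmplitude = 3,
                          meanNpp = 5e4, nppSeasonalAmplitude = 0.6,
                          phaseMonth = 4, spatialNoise = 0.1) {
  stopifnot2(meanNpp >= 0, "meanNpp must be non-negative")
  stopifnot2(nppSeasonalAmplitude >= 0 && nppSeasonalAmplitude < 1,
             "nppSeasonalAmplitude must lie in [0, 1)")
  list(meanTemperature = meanTemperature,
       temperatureAmplitude = temperatureAmplitude,
       meanNpp = meanNpp, nppSeasonalAmplitude = nppSeasonalAmplitude,
       phaseMonth = phaseMonth, spatialNoise = spatialNoise)
}

#' Generate a synthetic monthly environment
#'
#' Produces twelve calendar months of per-cell temperature and net primary
#' productivity, recycled annually by the simulator. Both surfaces are a
#' seasonal sinusoid modulated by a smooth multiplicative spatial field
#' (white noise smoothed with a 3 x 3 neighbour mean), so neighbouring cells
#' differ by less than the configured noise scale. Generation is pure: the
#' same landscape, parameters, and seed give the same grids, and the
#' caller's RNG stream is left untouched.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param params parameter list from \code{\link{savannaParams}}.
#' @param seed integer seed for the spatial noise field.
#' @return an \linkS4class{EnvironmentGrid}.
#' @export
generateEnvironment <- function(landscape, params = savannaParams(),
                                seed = 1L) {
  stopifnot2(params$meanNpp >= 0, "meanNpp must be non-negative")
  nc <- nCells(landscape)
  months <- 1:12
  seasonal <- cos(2 * pi * (months - params$phaseMonth) / 12)

  field <- withSeed(seed, smoothField(landscape))  # zero-mean, unit-ish sd

  tempSpace <- 1 + params$spatialNoise * field * 0.5
  nppSpace <- pmax(0, 1 + params$spatialNoise * field)

  temperature <- outer(params$meanTemperature +
                         params$temperatureAmplitude * seasonal,
                       rep(1, nc)) *
    matrix(tempSpace, nrow = 12, ncol = nc, byrow = TRUE)
  npp <- outer(params$meanNpp * (1 + params$nppSeasonalAmplitude * seasonal),
               rep(1, nc)) *
    matrix(nppSpace, nrow = 12, ncol = nc, byrow = TRUE)
  npp <- pmax(npp, 0)

  new("EnvironmentGrid", temperature = temperature, npp = npp,
      params = params, seed = as.integer(seed))
}

## Smooth zero-mean spatial field: iid normals averaged over the 3 x 3
## neighbourhood (edge-truncated), then standardized. Guarantees bounded
## neighbour differences relative to the field's sd.
smoothField <- function(landscape) {
  nr <- landscape@nRows; nc <- landscape@nCols
  z <- matrix(rnorm(nr * nc), nr, nc)
  sm <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    r1 <- max(1, 1 + dr); r2 <- min(nr, nr + dr)
    c1 <- max(1, 1 + dc); c2 <- min(nc, nc + dc)
    if (r1 > r2 || c1 > c2) next
    rs <- r1:r2; cs <- c1:c2
    sm[rs - dr, cs - dc] <- sm[rs - dr, cs - dc] + z[rs, cs]
    cnt[rs - dr, cs - dc] <- cnt[rs - dr, cs - dc] + 1
  }
  sm <- sm / cnt
  sm <- sm - mean(sm)
  s <- stats::sd(as.vector(sm))
  if (!is.na(s) && s > 0) sm <- sm / s
  ## row-major flatten to match linear cell indexing
  as.vector(t(sm))
}

#' Export an environment to a tidy table
#'
#' @param env an \linkS4class{EnvironmentGrid}.
#' @param landscape the matching \linkS4class{Landscape}.
#' @return data.frame with columns cell, row, col, month, temperature, npp
#'   (0-based row/col).
#' @export
environmentTable <- function(env, landscape) {
  nc <- ncol(env@npp)
  cell <- rep(seq_len(nc), each = 12)
  df <- data.frame(cell = cell, month = rep(1:12, times = nc),
                   temperature = as.vector(env@temperature),
                   npp = as.vector(env@npp))
  cbind(df[1], cellRowCol(landscape, df$cell), df[-1])
}
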