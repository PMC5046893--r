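#' Construct a bounded landscape grid
#'
#' Builds a rectangular grid of square (in degrees) habitat cells centred on
#' a geographic coordinate, with per-cell areas from spherical-Earth
#' geometry (mean radius 6371 km). The boundary is closed: no dispersal into
#' or out of the grid.
#'
#' Each cell spanning latitudes \eqn{[\phi_1, \phi_2]} and a longitude width
#' \eqn{\Delta\lambda} has area \eqn{R^2 \Delta\lambda (\sin\phi_2 -
#' \sin\phi_1)}. Near the equator this is within 0.5\% of the planar
#' approximation (111.32 km/deg with cos-latitude scaling of the east-west
#' edge).
#'
#' @param nRows,nCols grid dimensions (default 10 x 10).
#' @param cellSize cell edge length in degrees (e.g. 0.1 or 0.01).
#' @param centre numeric length-2, (latitude, longitude) of the grid centre
#'   in degrees. Default centres the grid just north of the equator at
#'   38 degrees east, a tropical-savanna setting.
#' @return a \linkS4class{Landscape}.
#' @examples
#' land <- makeLandscape(10, 10, 0.1)
#' sum(land@cellArea)  # ~12,300 km^2
#' @export
makeLandscape <- function(nRows = 10L, nCols = 10L, cellSize = 0.1,
                          centre = c(0.05, 38.00)) {
  stopifnot2(nRows >= 1 && nCols >= 1, "grid dimensions must be >= 1")
  stopifnot2(cellSize > 0, "cellSize must be positive")
  stopifnot2(abs(centre[1]) < 90, "|centre latitude| must be < 90")
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)

  R <- 6371  # mean Earth radius, km
  deg2rad <- pi / 180

  ## row i (1 = northernmost) spans [latTop - i*cellSize, latTop - (i-1)*cellSize]
  latTop <- centre[1] + nRows * cellSize / 2
  rowTop <- latTop - (seq_len(nRows) - 1) * cellSize
  rowBot <- rowTop - cellSize
  rowArea <- R^2 * (cellSize * deg2rad) *
    (sin(rowTop * deg2rad) - sin(rowBot * deg2rad))

  ## planar tangent coordinates (km) of cell centres, for dispersal distances
  kmPerDegLat <- R * deg2rad
  kmPerDegLon <- R * deg2rad * cos(centre[1] * deg2rad)
  rowLat <- (rowTop + rowBot) / 2
  colLon <- centre[2] - nCols * cellSize / 2 + (seq_len(nCols) - 0.5) * cellSize

  cellArea <- rep(rowArea, each = nCols)
  cellY <- rep(rowLat * kmPerDegLat, each = nCols)
  cellX <- rep(colLon * kmPerDegLon, times = nRows)

  new("Landscape", nRows = nRows, nCols = nCols, cellSize = cellSize,
      centre = as.numeric(centre), cellArea = cellArea,
      cellX = cellX, cellY = cellY)
}
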