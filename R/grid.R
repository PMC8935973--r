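#' Build a rectangular sampling grid in WGS84 coordinates
#'
#' Constructs an `n_rows` by `n_cols` grid of square cells of side
#' `cell_size_m`, anchored at a south-west origin given in decimal degrees.
#' Cell edges are spaced by converting the metric cell size to degrees at the
#' origin latitude (meridional for latitude, scaled by `cos(lat)` for
#' longitude), which is accurate to well under a metre per cell at city
#' scale. Cells are numbered row-major from the south-west corner.
#'
#' @param n_rows,n_cols Cell counts along latitude and longitude.
#' @param cell_size_m Cell side length in meters (default 2000, i.e. the
#'   2 x 2 km cells used for urban bumblebee surveys).
#' @param origin_lonlat Length-2 numeric, `c(lon, lat)` of the grid's
#'   south-west corner in WGS84 decimal degrees.
#' @return A data frame of class `bee_grid` with one row per cell:
#'   `cell_id`, `row`, `col`, and the cell bounds `west`, `east`, `south`,
#'   `north` in decimal degrees.
#' @examples
#' g <- make_grid(27, 10, 2000, c(-79.6, 43.58))
#' nrow(g)  # 270
#' @export
make_grid <- function(n_rows, n_cols, cell_size_m = 2000,
                      origin_lonlat = c(-79.6, 43.58)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_m > 0,
            length(origin_lonlat) == 2)
  lat0 <- origin_lonlat[2]
  dlat <- cell_size_m / EARTH_RADIUS_M * 180 / pi
  dlon <- dlat / cos(lat0 * pi / 180)
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  g <- data.frame(
    cell_id = seq_len(n_rows * n_cols),
    row = row, col = col,
    west  = origin_lonlat[1] + (col - 1) * dlon,
    east  = origin_lonlat[1] + col * dlon,
    south = lat0 + (row - 1) * dlat,
    north = lat0 + row * dlat
  )
  attr(g, "cell_size_m") <- cell_size_m
  attr(g, "origin_lonlat") <- origin_lonlat
  class(g) <- c("bee_grid", "data.frame")
  g
}

#' Assign points to grid cells
#'
#' Cell membership uses half-open intervals `[west, east) x [south, north)`
#' so a point lying exactly on an interior grid line belongs to exactly one
#' cell (the one to its north-east).
#'
#' @param grid A `bee_grid` from [make_grid()].
#' @param lon,lat Numeric vectors of WGS84 coordinates.
#' @return Integer vector of `cell_id`s; `NA` for points outside the grid.
#' @export
cell_of <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "bee_grid"), length(lon) == length(lat))
  origin <- attr(grid, "origin_lonlat")
  n_cols <- max(grid$col); n_rows <- max(grid$row)
  dlon <- (grid$east[1] - grid$west[1])
  dlat <- (grid$north[1] - grid$south[1])
  col <- floor((lon - origin[1]) / dlon) + 1
  row <- floor((lat - origin[2]) / dlat) + 1
  ok <- col >= 1 & col <= n_cols & row >= 1 & row <= n_rows &
    !is.na(col) & !is.na(row)
  out <- rep(NA_integer_, length(lon))
  out[ok] <- as.integer((row[ok] - 1) * n_cols + col[ok])
  out
}

#' Write grid cells as a GeoJSON FeatureCollection
#'
#' @param grid A `bee_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
grid_to_geojson <- function(grid, path) {
  stopifnot(inherits(grid, "bee_grid"))
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    w <- grid$west[i]; e <- grid$east[i]; s <- grid$south[i]; n <- grid$north[i]
    list(
      type = "Feature",
      properties = list(cell_id = grid$cell_id[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(list(c(w, s), c(e, s), c(e, n), c(w, n), c(w, s)))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = 10
  )
  invisible(path)
}

#' Fraction of each grid cell overlapped by an axis-aligned rectangle
#'
#' A rectangle-intersection helper for synthetic landscapes: returns, per
#' grid cell, the fraction of the cell's area covered by the rectangle
#' `c(west, east, south, north)` (degrees). Used to build the cell-by-polygon
#' overlap tables consumed by [extract_covariates()].
#'
#' @param grid A `bee_grid`.
#' @param rect Numeric length 4: west, east, south, north.
#' @return Numeric vector of overlap fractions in `[0, 1]`, one per cell.
#' @export
rect_overlap_fractions <- function(grid, rect) {
  stopifnot(inherits(grid, "bee_grid"), length(rect) == 4)
  ow <- pmax(pmin(grid$east, rect[2]) - pmax(grid$west, rect[1]), 0)
  oh <- pmax(pmin(grid$north, rect[4]) - pmax(grid$south, rect[3]), 0)
  (ow * oh) / ((grid$east - grid$west) * (grid$north - grid$south))
}
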