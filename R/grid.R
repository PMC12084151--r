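#' Build a regular analysis grid
#'
#' Constructs the coarse analysis grid used by every pipeline stage: a
#' regular lattice of square cells with cell-center coordinates in km,
#' row 1 at the southern edge, column 1 at the western edge. Cells are
#' numbered row-major from the south-west corner.
#'
#' @param nx,ny Number of columns (west-east) and rows (south-north).
#' @param res_km Cell size in km.
#' @param center_lat_deg Latitude of the domain center (degrees N), used to
#'   assign an approximate latitude to each row (1 degree ~= 111.32 km).
#' @return A tibble with columns `cell`, `col`, `row`, `x`, `y` (km, cell
#'   centers) and `lat` (degrees), carrying `nx`, `ny`, `res_km` attributes.
#' @export
go_grid <- function(nx, ny, res_km, center_lat_deg = 31) {
  stopifnot(nx >= 1, ny >= 1, res_km > 0)
  g <- crossing(row = seq_len(ny), col = seq_len(nx)) |>
    mutate(
      cell = (.data$row - 1L) * nx + .data$col,
      x = (.data$col - 0.5) * res_km,
      y = (.data$row - 0.5) * res_km,
      lat = center_lat_deg + (.data$y - ny * res_km / 2) / 111.32
    ) |>
    select("cell", "col", "row", "x", "y", "lat") |>
    arrange(.data$cell)
  attr(g, "nx") <- as.integer(nx)
  attr(g, "ny") <- as.integer(ny)
  attr(g, "res_km") <- res_km
  attr(g, "center_lat_deg") <- center_lat_deg
  g
}

grid_nx <- function(grid) attr(grid, "nx") %||% max(grid$col)
grid_ny <- function(grid) attr(grid, "ny") %||% max(grid$row)
grid_res_km <- function(grid) attr(grid, "res_km")

#' Mass-conserving aggregation of a fine raster to a coarse grid
#'
#' Sums a fine-resolution quantity (e.g. population counts) into the coarse
#' cell containing each fine cell. The fine resolution must divide the
#' coarse resolution evenly; totals are conserved exactly.
#'
#' @param fine Tibble with integer fine-cell indices `fx`, `fy` (1-based,
#'   row 1 southernmost) and a `value` column.
#' @param grid Coarse grid from [go_grid()].
#' @param factor Number of fine cells per coarse cell edge.
#' @param value Name of the value column in `fine`.
#' @return Tibble `cell`, `value` covering every coarse cell (zeros filled).
#' @export
regrid_sum <- function(fine, grid, factor, value = "value") {
  stopifnot(factor == as.integer(factor), factor >= 1)
  nx <- grid_nx(grid)
  cc <- ((fine$fy - 1L) %/% factor) * nx + ((fine$fx - 1L) %/% factor) + 1L
  agg <- tibble(cell = cc, v = fine[[value]]) |>
    summarise(value = sum(.data$v), .by = "cell")
  grid |>
    select("cell") |>
    left_join(agg, by = "cell") |>
    mutate(value = ifelse(is.na(.data$value), 0, .data$value))
}

# distance (km) of each grid cell center from a point
grid_dist_km <- function(grid, center) {
  sqrt((grid$x - center[1])^2 + (grid$y - center[2])^2)
}
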