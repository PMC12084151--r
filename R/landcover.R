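#' Shipped parameter tables
#'
#' The package ships its vegetation parameter tables as editable CSVs under
#' `inst/extdata/`: the 16-entry plant-functional-type (PFT) scheme, the
#' fine 4-class urban vegetation mapping, a coarse 8-class mapping, per-PFT
#' reference leaf area index, and per-PFT standard isoprene emission
#' factors. Each loader returns the shipped default unless a path to a
#' replacement CSV with the same columns is given.
#'
#' @param path Optional path to a replacement CSV.
#' @return A tibble.
#' @name param_tables
NULL

read_extdata <- function(fname, path = NULL) {
  f <- path %||% system.file("extdata", fname, package = "greenozone")
  if (!nzchar(f) || !file.exists(f)) abort(paste("missing table:", fname))
  readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
}

#' @rdname param_tables
#' @export
pft_definitions <- function(path = NULL) read_extdata("pft_definitions.csv", path)

#' @rdname param_tables
#' @export
fine_class_pft_map <- function(path = NULL) read_extdata("fine_class_to_pft.csv", path)

#' @rdname param_tables
#' @export
coarse_class_pft_map <- function(path = NULL) read_extdata("coarse_class_to_pft.csv", path)

#' @rdname param_tables
#' @export
lai_reference <- function(path = NULL) read_extdata("lai_reference.csv", path)

#' @rdname param_tables
#' @export
isoprene_emission_factors <- function(path = NULL)
  read_extdata("isoprene_emission_factors.csv", path)

#' Classify an urban vegetation class into a PFT
#'
#' Urban tree cover is assumed to be broadleaf; whether it is evergreen or
#' deciduous depends on latitude: below `phenology_lat_cutoff` (absolute
#' value) trees are broadleaf evergreen, at or above it broadleaf
#' deciduous. Shrub, grass and crop map to their single PFT regardless of
#' latitude. The mapping lives in [fine_class_pft_map()].
#'
#' @param veg_class Character vector over `tree`, `shrub`, `grass`, `crop`.
#' @param latitude Latitude in degrees, in \[-90, 90\]; recycled.
#' @param phenology_lat_cutoff Evergreen/deciduous divide (degrees,
#'   default 30).
#' @param map Mapping table with columns `veg_class`, `pft_low_lat`,
#'   `pft_high_lat`.
#' @return Integer PFT indices (1-16).
#' @export
classify_urban_pft <- function(veg_class, latitude,
                               phenology_lat_cutoff = 30,
                               map = fine_class_pft_map()) {
  if (any(abs(latitude) > 90)) abort("latitude must be within [-90, 90]")
  i <- match(veg_class, map$veg_class)
  if (anyNA(i)) {
    abort(paste("unknown vegetation class:",
                paste(unique(veg_class[is.na(i)]), collapse = ", ")))
  }
  n <- max(length(veg_class), length(latitude))
  i <- rep_len(i, n)
  lat <- rep_len(latitude, n)
  as.integer(ifelse(abs(lat) < phenology_lat_cutoff,
                    map$pft_low_lat[i], map$pft_high_lat[i]))
}

#' Map coarse land-cover classes to PFT fractions
#'
#' Expands per-cell coarse class fractions into PFT fractions using the
#' shipped 8-class mapping (a class may split across several PFTs).
#'
#' @param classes Tibble `cell`, `class`, `frac` (class areal fraction).
#' @param map Table from [coarse_class_pft_map()] with `class`, `pft`,
#'   `weight` (weights sum to 1 within a class).
#' @return Tibble `cell`, `pft`, `chi`.
#' @export
map_coarse_classes <- function(classes, map = coarse_class_pft_map()) {
  bad <- setdiff(unique(classes$class), map$class)
  if (length(bad)) abort(paste("unknown coarse class:", paste(bad, collapse = ", ")))
  classes |>
    inner_join(map, by = "class", relationship = "many-to-many") |>
    mutate(chi = .data$frac * .data$weight) |>
    summarise(chi = sum(.data$chi), .by = c("cell", "pft")) |>
    arrange(.data$cell, .data$pft)
}

#' Fuse fine urban land cover with coarse PFT fractions
#'
#' Builds the analysis-grid PFT map: outside the urban mask, PFT fractions
#' are copied from the coarse raster; inside it they are computed as the
#' areal fraction of fine cells of each vegetation class within each
#' coarse cell, reclassified to PFTs with [classify_urban_pft()] at the
#' cell's latitude. Area bookkeeping is exact: the total vegetated
#' fraction inside the urban mask equals the fine-raster vegetated areal
#' fraction.
#'
#' @param fine Fine raster tibble `fx`, `fy`, `veg_class` (vegetated cells
#'   only; absent fine cells are non-vegetated). Indices are 1-based with
#'   row 1 southernmost; fine cells outside the urban mask are ignored.
#' @param coarse Coarse PFT tibble `cell`, `pft`, `chi` for non-urban cells.
#' @param mask Grid tibble with `urban` column (see [urban_mask()]).
#' @param fine_factor Fine cells per coarse-cell edge (integer).
#' @param phenology_lat_cutoff Passed to [classify_urban_pft()].
#' @param map Fine-class mapping table.
#' @return Tibble of class `go_pft` with columns `cell`, `pft`, `chi`,
#'   `source` (rows with `chi > 0` only), carrying the grid and a per-cell
#'   provenance tibble as attributes.
#' @export
fuse_landcover <- function(fine, coarse, mask, fine_factor,
                           phenology_lat_cutoff = 30,
                           map = fine_class_pft_map()) {
  if (fine_factor != as.integer(fine_factor) || fine_factor < 1)
    abort("fine_factor must be a positive integer", class = "go_grid_error")
  nx <- grid_nx(mask)
  if (!all(coarse$cell %in% mask$cell))
    abort("coarse raster holds cells outside the analysis grid",
          class = "go_grid_error")
  chk <- summarise(coarse, s = sum(.data$chi), .by = "cell")
  if (any(chk$s > 1 + 1e-9) || any(coarse$chi < 0))
    abort("coarse PFT fractions must be nonnegative and sum to <= 1 per cell")

  f <- as.integer(fine_factor)
  urban_cells <- mask$cell[mask$urban]

  urban_chi <- tibble(cell = integer(), pft = integer(), chi = numeric())
  if (nrow(fine)) {
    cc <- ((fine$fy - 1L) %/% f) * nx + ((fine$fx - 1L) %/% f) + 1L
    inside <- cc %in% urban_cells
    counts <- tibble(cell = cc[inside], veg_class = fine$veg_class[inside]) |>
      count(.data$cell, .data$veg_class)
    lat <- mask$lat[match(counts$cell, mask$cell)]
    counts$pft <- classify_urban_pft(counts$veg_class, lat,
                                     phenology_lat_cutoff, map)
    urban_chi <- counts |>
      summarise(chi = sum(.data$n) / f^2, .by = c("cell", "pft"))
  }

  out <- bind_rows(
    urban_chi |> mutate(source = "fine-urban"),
    coarse |>
      filter(!.data$cell %in% urban_cells, .data$chi > 0) |>
      mutate(source = "coarse-nonurban")
  ) |>
    arrange(.data$cell, .data$pft)

  src <- tibble(cell = mask$cell,
                source = ifelse(mask$urban, "fine-urban", "coarse-nonurban"))
  structure(out,
            class = c("go_pft", class(out)),
            grid = mask, fine_factor = f, source_mask = src)
}

#' Leaf area index from PFT fractions
#'
#' Cell LAI is the fraction-weighted sum of per-PFT reference LAI values,
#' `sum_j chi_j * LAI_ref(j)`; cells with no vegetation get LAI 0. The
#' shipped reference table encodes an empirical PFT-to-LAI relationship
#' and is editable.
#'
#' @param pft_map A `go_pft` from [fuse_landcover()].
#' @param lai_table Table with columns `pft`, `lai_ref` covering every PFT
#'   present in `pft_map`.
#' @param epoch 8-day composite index carried as metadata.
#' @return Tibble of class `go_lai` with `cell`, `x`, `y`, `lai`
#'   (m2 m-2), one row per grid cell.
#' @export
lai_from_pft <- function(pft_map, lai_table = lai_reference(), epoch = 1L) {
  grid <- attr(pft_map, "grid")
  missing <- setdiff(unique(pft_map$pft), lai_table$pft)
  if (length(missing))
    abort(paste("no reference LAI for PFT:", paste(missing, collapse = ", ")))
  per_cell <- pft_map |>
    inner_join(lai_table, by = "pft") |>
    summarise(lai = sum(.data$chi * .data$lai_ref), .by = "cell")
  out <- grid |>
    select("cell", "x", "y") |>
    left_join(per_cell, by = "cell") |>
    mutate(lai = ifelse(is.na(.data$lai), 0, .data$lai))
  structure(out, class = c("go_lai", class(out)), grid = grid, epoch = epoch)
}
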