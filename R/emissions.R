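#' MEGAN-style activity-factor configuration
#'
#' The biogenic emission flux of species i is
#' `F_i = gamma_i * sum_j epsilon_ij * chi_j`, with the emission activity
#' factor `gamma_i = C_CE * LAI * gamma_L * gamma_T * gamma_LA * gamma_SM
#' * gamma_CI`. This constructor bundles the parameter sets of the light
#' and temperature responses with the remaining multipliers. Leaf-age,
#' soil-moisture and CO2-inhibition activities default to 1 (no driving
#' data in the synthetic pipeline) and are overridable. The canopy
#' environment coefficient `C_CE` defaults to the value that makes
#' `gamma = 1` at standard conditions (LAI 5, 30 degC leaf temperature,
#' PAR 1000 umol m-2 s-1), computed at call time.
#'
#' @param temperature Parameters for [gamma_temperature()].
#' @param light Parameters for [gamma_light()].
#' @param gamma_la,gamma_sm,gamma_ci Scalar activities in \[0, 1\]
#'   (leaf age may exceed 1 for young canopies; values must be >= 0).
#' @param c_ce Canopy environment coefficient; `NULL` = standardized.
#' @return List of class `go_activity`.
#' @export
activity_config <- function(temperature = megan_temperature_params(),
                            light = megan_light_params(),
                            gamma_la = 1, gamma_sm = 1, gamma_ci = 1,
                            c_ce = NULL) {
  stopifnot(gamma_la >= 0, gamma_sm >= 0, gamma_sm <= 1,
            gamma_ci >= 0, gamma_ci <= 1)
  if (is.null(c_ce)) {
    c_ce <- 1 / (5 * gamma_temperature(303.15, temperature) *
                   gamma_light(1000, light))
  }
  stopifnot(c_ce > 0)
  structure(list(temperature = temperature, light = light,
                 gamma_la = gamma_la, gamma_sm = gamma_sm,
                 gamma_ci = gamma_ci, c_ce = c_ce),
            class = "go_activity")
}

#' @rdname activity_config
#' @export
megan_temperature_params <- function() {
  list(c_t1 = 95, c_t2 = 230, t_opt_k = 313, e_opt = 2.037)
}

#' @rdname activity_config
#' @export
megan_light_params <- function() {
  list(alpha = 0.004, c_p = 1.21)
}

#' Temperature activity factor
#'
#' Closed-form isoprene temperature response:
#' `gamma_T = E_opt * C_T2 * exp(C_T1 * x) /
#'   (C_T2 - C_T1 * (1 - exp(C_T2 * x)))` with
#' `x = (1/T_opt - 1/T) / 0.00831` (T in kelvin). The response is smooth
#' and single-peaked, equals `E_opt` at `T_opt`, and is strictly
#' increasing below the optimum.
#'
#' @param t_leaf_k Leaf temperature (K), within \[240, 330\]; the 2 m air
#'   temperature is used as a proxy throughout the pipeline.
#' @param params List with `c_t1`, `c_t2`, `t_opt_k`, `e_opt`.
#' @return Dimensionless activity, >= 0.
#' @export
gamma_temperature <- function(t_leaf_k, params = megan_temperature_params()) {
  if (any(t_leaf_k < 240 | t_leaf_k > 330))
    abort("leaf temperature outside the physical range [240, 330] K")
  x <- (1 / params$t_opt_k - 1 / t_leaf_k) / 0.00831
  params$e_opt * params$c_t2 * exp(params$c_t1 * x) /
    (params$c_t2 - params$c_t1 * (1 - exp(params$c_t2 * x)))
}

#' Light activity factor
#'
#' Saturating photosynthetic-photon-flux response
#' `gamma_L = c_p * alpha * P / sqrt(1 + alpha^2 * P^2)`: zero in the
#' dark, linear at low PAR, saturating at `c_p` for large PAR.
#'
#' @param par PAR (umol m-2 s-1), >= 0.
#' @param params List with `alpha`, `c_p`.
#' @return Dimensionless activity, >= 0.
#' @export
gamma_light <- function(par, params = megan_light_params()) {
  if (any(par < 0)) abort("PAR must be nonnegative")
  params$c_p * params$alpha * par / sqrt(1 + params$alpha^2 * par^2)
}

#' Hourly biogenic isoprene emission flux
#'
#' Per cell and hour, `F = C_CE * LAI * gamma_L(PAR) * gamma_T(T) *
#' gamma_LA * gamma_SM * gamma_CI * sum_j epsilon_j chi_j`. Temperature is
#' taken from the meteorology in degC and converted to kelvin internally;
#' leaf temperature is approximated by 2 m air temperature. The flux is
#' bilinear in the activity factor and the emission-factor-weighted PFT
#' fraction sum, and is zero wherever LAI or the vegetated fraction is
#' zero.
#'
#' @param pft_map `go_pft` from [fuse_landcover()].
#' @param lai `go_lai` from [lai_from_pft()] on the same grid.
#' @param met `go_met` from [generate_meteorology()].
#' @param act_cfg [activity_config()].
#' @param ef_table Per-PFT standard emission factors: columns `pft`,
#'   `epsilon_ug_m2_h`; must cover every PFT present.
#' @param species Species label carried in the output.
#' @return Tibble of class `go_emission` with `cell`, `time`, `flux`
#'   (ug m-2 h-1), rows for vegetated cells only (absent cells emit 0);
#'   grid, hour axis and species as attributes.
#' @export
emission_flux <- function(pft_map, lai, met,
                          act_cfg = activity_config(),
                          ef_table = isoprene_emission_factors(),
                          species = "isoprene") {
  grid <- attr(pft_map, "grid")
  if (!identical(grid$cell, attr(lai, "grid")$cell))
    abort("PFT and LAI grids are misaligned", class = "go_grid_error")
  missing <- setdiff(unique(pft_map$pft), ef_table$pft)
  if (length(missing))
    abort(paste("no emission factor for PFT:", paste(missing, collapse = ", ")))

  epsum <- pft_map |>
    inner_join(ef_table, by = "pft") |>
    summarise(epsum = sum(.data$chi * .data$epsilon_ug_m2_h), .by = "cell")
  cellw <- epsum |>
    left_join(select(as_tibble(lai), "cell", "lai"), by = "cell") |>
    left_join(select(attr(met, "spatial"), "cell", "t2m_offset"), by = "cell") |>
    filter(.data$epsum > 0, .data$lai > 0)
  if (anyNA(cellw$t2m_offset))
    abort("meteorology grid does not cover the PFT grid", class = "go_grid_error")

  gl <- gamma_light(met$par, act_cfg$light)
  scale_cell <- act_cfg$c_ce * cellw$lai * cellw$epsum *
    act_cfg$gamma_la * act_cfg$gamma_sm * act_cfg$gamma_ci
  # cells x hours leaf temperature (K); gamma_T is not separable in space/time
  t_k <- outer(cellw$t2m_offset, met$t2m, "+") + 273.15
  gt <- gamma_temperature(t_k, act_cfg$temperature)
  flux <- (scale_cell * gt) * rep(gl, each = nrow(cellw))

  out <- tibble(
    cell = rep(cellw$cell, length(met$time)),
    time = rep(met$time, each = nrow(cellw)),
    flux = as.vector(flux)
  )
  structure(out,
            class = c("go_emission", class(out)),
            grid = grid, species = species,
            hours = select(as_tibble(met), "day", "hour", "time"))
}

#' Seasonal emission budget and urban share
#'
#' Integrates the hourly flux over cells and hours
#' (`sum F * area * 1 h`), converts to Gg, and splits the total into the
#' urban-mask and non-urban parts; the split is exact by construction
#' (`total = urban + nonurban`).
#'
#' @param em `go_emission` from [emission_flux()].
#' @param mask Grid tibble with logical `urban` column.
#' @param cell_area_m2 Area of one analysis cell (m2); must be positive.
#' @return One-row tibble `species`, `total_gg`, `urban_gg`,
#'   `nonurban_gg`, `urban_fraction`.
#' @export
seasonal_budget <- function(em, mask, cell_area_m2) {
  if (cell_area_m2 <= 0) abort("cell area must be positive")
  if (!all(em$cell %in% mask$cell))
    abort("emission cells missing from mask grid", class = "go_grid_error")
  urb <- mask$urban[match(em$cell, mask$cell)]
  ug_per_ug <- cell_area_m2 * 1e-15 # ug m-2 h-1 over one cell-hour -> Gg
  urban_gg <- sum(em$flux[urb]) * ug_per_ug
  nonurban_gg <- sum(em$flux[!urb]) * ug_per_ug
  total_gg <- urban_gg + nonurban_gg
  tibble(species = attr(em, "species") %||% "isoprene",
         total_gg = total_gg, urban_gg = urban_gg,
         nonurban_gg = nonurban_gg,
         urban_fraction = if (total_gg > 0) urban_gg / total_gg else NA_real_)
}
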