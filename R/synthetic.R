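#' Configuration for the synthetic study domain
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object. The defaults describe a single megacity domain: a 50 km square
#' at 1 km analysis resolution with a 10 m urban land-cover layer, a summer
#' (JJA) simulation of 92 days of which the first 4 are spin-up, an urban
#' core of 15 km radius holding most of the population, and an injected
#' urban-greening ozone enhancement whose urban-mean MDA8 difference is
#' `delta_o3_urban_ppb` and which scales with daily-mean temperature at
#' relative slope `temp_coupling` per degree C.
#'
#' @param seed Integer seed; every stochastic recipe below derives its own
#'   stream from it, so a fixed seed gives bit-identical outputs.
#' @param domain_size_km Side length of the square domain (km).
#' @param fine_res_m Fine land-cover resolution (m); must divide
#'   `coarse_res_km * 1000` evenly.
#' @param coarse_res_km Analysis-grid resolution (km).
#' @param n_days Simulated days, including `spinup_days` later dropped by
#'   the ozone analysis.
#' @param spinup_days Leading days treated as model spin-up.
#' @param urban_center Domain coordinates (km) of the urban core center.
#' @param urban_radius_km Radius of the urban mask (km).
#' @param urban_green_fraction Target vegetated areal fraction inside the
#'   urban mask, in \[0, 1\].
#' @param delta_o3_urban_ppb Injected mean urban MDA8 O3 difference between
#'   the UG (with urban biogenic emissions) and Base scenarios (ppb).
#' @param temp_coupling Relative change of the injected enhancement per
#'   degree C of daily-mean temperature anomaly (1/degC).
#' @param pop_total Total domain population (persons).
#' @param incidence_annual Baseline cause-specific annual mortality
#'   incidence (deaths per person per year).
#' @param center_lat_deg Latitude of the domain center (degrees N).
#' @param temp_mean_c,temp_diurnal_amp_c,temp_daily_sd_c Daily-mean
#'   temperature level, diurnal half-amplitude, and day-to-day standard
#'   deviation (degC).
#' @param uhi_amp_c Urban heat island amplitude added at the core (degC).
#' @param hot_day_threshold_c Daily-mean threshold used to count hot days.
#' @param par_max Clear-sky noon photosynthetically active radiation
#'   (umol m-2 s-1).
#' @param wind_u,wind_v Constant advection wind vector (m s-1) stretching
#'   the enhancement kernel downwind.
#' @param base_o3_mean_ppb,base_o3_diurnal_amp_ppb Base-scenario ozone
#'   level and diurnal half-amplitude (ppb).
#' @param base_o3_temp_slope Base ozone response to daily-mean temperature
#'   anomaly (ppb per degC).
#' @param base_noise_sd Additive Gaussian noise on hourly Base ozone (ppb).
#' @param delta_noise_sd Log-scale standard deviation of the multiplicative
#'   lognormal noise on the daily enhancement (dimensionless; mean 1).
#' @param patch_radius_m Radius of the circular vegetation patches planted
#'   inside the urban mask (m).
#' @param veg_class_mix Named numeric vector of patch-class probabilities
#'   over `tree`, `shrub`, `grass`, `crop`; must sum to 1.
#' @return A validated list of class `go_config`.
#' @export
synth_config <- function(seed = 1L,
                         domain_size_km = 50,
                         fine_res_m = 10,
                         coarse_res_km = 1,
                         n_days = 92L,
                         spinup_days = 4L,
                         urban_center = c(domain_size_km / 2, domain_size_km / 2),
                         urban_radius_km = 15,
                         urban_green_fraction = 0.25,
                         delta_o3_urban_ppb = 3.6,
                         temp_coupling = 0.08,
                         pop_total = 5e6,
                         incidence_annual = 6.4e-4,
                         center_lat_deg = 31,
                         temp_mean_c = 27,
                         temp_diurnal_amp_c = 5,
                         temp_daily_sd_c = 2.5,
                         uhi_amp_c = 1,
                         hot_day_threshold_c = 30,
                         par_max = 2000,
                         wind_u = 2,
                         wind_v = 1,
                         base_o3_mean_ppb = 60,
                         base_o3_diurnal_amp_ppb = 20,
                         base_o3_temp_slope = 1.5,
                         base_noise_sd = 2,
                         delta_noise_sd = 0.3,
                         patch_radius_m = 200,
                         veg_class_mix = c(tree = 0.7, shrub = 0.05,
                                           grass = 0.15, crop = 0.1)) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed) %% .Machine$integer.max
  cfg$n_days <- as.integer(n_days)
  cfg$spinup_days <- as.integer(spinup_days)
  validate_config(cfg)
  structure(cfg, class = "go_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "go_config_error")
  chk(cfg$fine_res_m > 0 && cfg$coarse_res_km > 0, "resolutions must be positive")
  chk((cfg$coarse_res_km * 1000) %% cfg$fine_res_m == 0,
      "fine resolution must divide the coarse resolution evenly")
  chk(cfg$domain_size_km %% cfg$coarse_res_km == 0,
      "domain size must be a whole number of coarse cells")
  chk(cfg$urban_green_fraction >= 0 && cfg$urban_green_fraction <= 1,
      "urban_green_fraction must be in [0, 1]")
  chk(cfg$n_days > cfg$spinup_days, "n_days must exceed spinup_days")
  chk(cfg$delta_o3_urban_ppb >= 0, "delta_o3_urban_ppb must be >= 0")
  chk(cfg$pop_total > 0, "pop_total must be positive")
  chk(all(cfg$veg_class_mix >= 0) && abs(sum(cfg$veg_class_mix) - 1) < 1e-8,
      "veg_class_mix must be nonnegative and sum to 1")
  chk(all(names(cfg$veg_class_mix) %in% c("tree", "shrub", "grass", "crop")),
      "veg_class_mix names must be tree/shrub/grass/crop")
  invisible(cfg)
}

# deterministic per-recipe seed streams derived from the master seed
sub_seed <- function(cfg, offset) (cfg$seed %% 2000000000L) + offset

config_grid <- function(cfg) {
  n <- as.integer(cfg$domain_size_km / cfg$coarse_res_km)
  go_grid(n, n, cfg$coarse_res_km, cfg$center_lat_deg)
}

#' Urban mask on the analysis grid
#'
#' Cells whose center lies within `urban_radius_km` of the urban core are
#' flagged urban; everything else is suburban/rural.
#'
#' @param cfg A [synth_config()].
#' @return The analysis grid tibble with a logical `urban` column.
#' @export
urban_mask <- function(cfg) {
  g <- config_grid(cfg)
  g$urban <- grid_dist_km(g, cfg$urban_center) <= cfg$urban_radius_km
  g
}

#' Generate synthetic land cover
#'
#' Produces the three land-cover inputs of the fusion stage: a fine urban
#' vegetation-class raster, a coarse per-cell PFT-fraction raster for the
#' non-urban domain, and the urban mask. Urban vegetation is planted as
#' spatially clustered circular patches (Poisson-placed centers, one
#' vegetation class per patch) whose number is chosen so the expected
#' covered fraction of the urban area equals `urban_green_fraction`;
#' coverage 0 and 1 are handled exactly.
#'
#' Outside the urban mask the coarse raster carries plant-functional-type
#' fractions directly: a broadleaf-deciduous tree fraction that increases
#' away from the urban core plus grass and crop fractions, summing to at
#' most 1 per cell.
#'
#' @param cfg A [synth_config()].
#' @return List with `fine` (tibble `fx`, `fy`, `veg_class`; urban coarse
#'   cells only, `non-vegetated` rows omitted and implied), `coarse`
#'   (tibble `cell`, `pft`, `chi` for non-urban cells), `mask` (grid with
#'   `urban`), and `fine_factor` (fine cells per coarse edge).
#' @export
generate_landcover <- function(cfg) {
  mask <- urban_mask(cfg)
  nx <- grid_nx(mask)
  f <- as.integer(cfg$coarse_res_km * 1000 / cfg$fine_res_m)
  urb <- mask[mask$urban, ]

  fine <- generate_urban_fine(cfg, urb, nx, f)

  # non-urban coarse PFT fractions: a crop/grass-dominated periphery with
  # forest thickening toward the rural fringe
  nonurb <- mask[!mask$urban, ]
  d <- grid_dist_km(nonurb, cfg$urban_center)
  rel <- if (nrow(nonurb)) pmin(1, d / max(cfg$domain_size_km / 2, 1e-9)) else numeric(0)
  chi_tree <- 0.10 + 0.20 * rel
  chi_grass <- rep(0.15, nrow(nonurb))
  chi_crop <- rep(0.10, nrow(nonurb))
  coarse <- bind_rows(
    tibble(cell = nonurb$cell, pft = 7L, chi = chi_tree),
    tibble(cell = nonurb$cell, pft = 13L, chi = chi_grass),
    tibble(cell = nonurb$cell, pft = 15L, chi = chi_crop)
  ) |> arrange(.data$cell, .data$pft)

  list(fine = fine, coarse = coarse, mask = mask, fine_factor = f)
}

# clustered vegetation patches on the fine grid, urban coarse cells only
generate_urban_fine <- function(cfg, urb, nx, f) {
  p <- cfg$urban_green_fraction
  # enumerate fine cells of urban coarse cells
  off <- crossing(dy = seq_len(f), dx = seq_len(f))
  fx <- rep((urb$col - 1L) * f, each = f * f) + rep(off$dx, nrow(urb))
  fy <- rep((urb$row - 1L) * f, each = f * f) + rep(off$dy, nrow(urb))
  n_fine <- length(fx)
  if (p <= 0 || n_fine == 0) {
    return(tibble(fx = integer(), fy = integer(),
                  veg_class = character()))
  }
  cls_levels <- c("tree", "shrub", "grass", "crop")
  if (p >= 1) {
    cls <- with_seed(sub_seed(cfg, 202L),
                     sample(cls_levels, n_fine, TRUE, cfg$veg_class_mix[cls_levels]))
    return(tibble(fx = fx, fy = fy, veg_class = cls))
  }
  res_km <- cfg$fine_res_m / 1000
  r_cells <- max(1, round(cfg$patch_radius_m / cfg$fine_res_m))
  patch_area_km2 <- pi * (r_cells * res_km)^2
  # Poisson coverage: centers sampled over the urban disk dilated by one
  # patch radius so interior coverage probability is uniform
  r_dil <- cfg$urban_radius_km + r_cells * res_km
  area_dil <- pi * r_dil^2
  n_patch <- max(1L, as.integer(ceiling(-area_dil / patch_area_km2 * log(1 - p))))
  nfx <- nx * f
  patch_cls <- with_seed(sub_seed(cfg, 202L),
                         sample(cls_levels, n_patch, TRUE, cfg$veg_class_mix[cls_levels]))
  centers <- with_seed(sub_seed(cfg, 201L), {
    th <- runif(n_patch, 0, 2 * pi)
    rr <- r_dil * sqrt(runif(n_patch))
    cbind(cfg$urban_center[1] + rr * cos(th), cfg$urban_center[2] + rr * sin(th))
  })
  # rasterize patches; later patches overwrite earlier where they overlap
  class_of <- integer(nfx * nfx) # 0 = non-vegetated, global fine raster
  dr <- seq(-r_cells, r_cells)
  disk <- crossing(dy = dr, dx = dr) |> filter(.data$dx^2 + .data$dy^2 <= r_cells^2)
  for (k in seq_len(n_patch)) {
    cx <- as.integer(ceiling(centers[k, 1] / res_km))
    cy <- as.integer(ceiling(centers[k, 2] / res_km))
    px <- cx + disk$dx
    py <- cy + disk$dy
    ok <- px >= 1L & px <= nfx & py >= 1L & py <= nfx
    class_of[(py[ok] - 1L) * nfx + px[ok]] <- match(patch_cls[k], cls_levels)
  }
  idx <- (fy - 1L) * nfx + fx
  hit <- class_of[idx] > 0L
  tibble(fx = fx[hit], fy = fy[hit],
         veg_class = cls_levels[class_of[idx[hit]]])
}

#' Generate synthetic hourly meteorology
#'
#' Hourly 2 m temperature and photosynthetically active radiation (PAR).
#' The recipe is deliberately simple and fully documented so it can be
#' re-simulated independently: daily-mean temperature is
#' `temp_mean_c + rnorm(n_days, 0, temp_daily_sd_c)` drawn under seed
#' `seed + 101`; the hourly series adds a cosine diurnal cycle of
#' half-amplitude `temp_diurnal_amp_c` peaking at 14:00 (zero daily mean,
#' so the daily mean equals the drawn value exactly). PAR is
#' `par_max * max(0, sin(pi * (hour - 6) / 12))` scaled by a daily cloud
#' factor `runif(n_days, 0.7, 1)` drawn under seed `seed + 102`; it is zero
#' at night. Space enters through a separable urban-heat-island offset,
#' `uhi_amp_c * exp(-d^2 / (2 * (0.8 * urban_radius_km)^2))` with `d` the
#' distance from the urban center, stored per cell.
#'
#' @param cfg A [synth_config()].
#' @return A tibble of class `go_met` with columns `day`, `hour` (0-23),
#'   `time` (1-based hour index), `t2m` (degC, domain reference) and `par`
#'   (umol m-2 s-1), carrying the per-cell `spatial` offset tibble
#'   (`cell`, `t2m_offset`) and the daily means as attributes. The full
#'   temperature field is `t2m + t2m_offset`.
#' @export
generate_meteorology <- function(cfg) {
  nd <- cfg$n_days
  t_daily <- cfg$temp_mean_c +
    with_seed(sub_seed(cfg, 101L), rnorm(nd, 0, cfg$temp_daily_sd_c))
  cloud <- with_seed(sub_seed(cfg, 102L), runif(nd, 0.7, 1))
  ser <- crossing(day = seq_len(nd), hour = 0:23) |>
    mutate(
      time = (.data$day - 1L) * 24L + .data$hour + 1L,
      t2m = t_daily[.data$day] +
        cfg$temp_diurnal_amp_c * cos(2 * pi * (.data$hour - 14) / 24),
      par = cfg$par_max * pmax(0, sin(pi * (.data$hour - 6) / 12)) *
        cloud[.data$day]
    ) |>
    select("day", "hour", "time", "t2m", "par")
  g <- config_grid(cfg)
  d <- grid_dist_km(g, cfg$urban_center)
  spatial <- tibble(
    cell = g$cell,
    t2m_offset = cfg$uhi_amp_c * exp(-d^2 / (2 * (0.8 * cfg$urban_radius_km)^2))
  )
  structure(ser,
            class = c("go_met", class(ser)),
            spatial = spatial, t_daily = t_daily, cloud = cloud,
            n_days = nd)
}

#' Daily-mean 2 m temperature series
#'
#' @param met A `go_met` object from [generate_meteorology()].
#' @return Tibble `day`, `t2m` (daily-mean domain-reference temperature, degC).
#' @export
daily_mean_temperature <- function(met) {
  tibble(day = seq_along(attr(met, "t_daily")), t2m = attr(met, "t_daily"))
}

# spatial enhancement kernel: urban Gaussian bump stretched downwind
delta_kernel <- function(cfg, grid) {
  dx <- grid$x - cfg$urban_center[1]
  dy <- grid$y - cfg$urban_center[2]
  spd <- sqrt(cfg$wind_u^2 + cfg$wind_v^2)
  sig <- 0.7 * cfg$urban_radius_km
  if (spd < 1e-12) return(exp(-(dx^2 + dy^2) / (2 * sig^2)))
  wu <- cfg$wind_u / spd
  wv <- cfg$wind_v / spd
  a <- dx * wu + dy * wv    # along-wind (positive downwind)
  cc <- -dx * wv + dy * wu  # cross-wind
  sig_down <- sig * (1 + 0.3 * spd)
  sig_along <- ifelse(a >= 0, sig_down, sig)
  exp(-(a^2 / (2 * sig_along^2) + cc^2 / (2 * sig^2)))
}

#' Generate a paired Base/UG ozone scenario
#'
#' Builds two aligned hourly surface-ozone fields: `Base` (no urban
#' biogenic emissions) and `UG` (with them). Base ozone is a diurnal cycle
#' peaking mid-afternoon plus a temperature-driven day effect and additive
#' Gaussian noise, clipped at zero. The UG field adds a nonnegative
#' enhancement that is constant within each day for each cell:
#' `amp * kernel(cell) * (1 + temp_coupling * (Td - mean(Td))) * eps`, with
#' `kernel` an urban Gaussian stretched downwind of the constant wind,
#' `Td` the daily-mean temperature, and `eps` lognormal multiplicative
#' noise with mean 1 (`delta_noise_sd` on the log scale). The amplitude is
#' calibrated analytically so that, over the post-spin-up days, the mean
#' urban-cell MDA8 difference equals `delta_o3_urban_ppb` exactly in the
#' noise-free case; a day-constant increment shifts a day's MDA8 by itself,
#' which is what makes the calibration closed-form.
#'
#' @param cfg A [synth_config()].
#' @param met Meteorology from [generate_meteorology()] on the same config.
#' @return A tibble of class `go_scenario` with columns `cell`, `time`,
#'   `o3_base`, `o3_ug` (ppb), carrying the grid, mask, hour axis and the
#'   noise-free daily enhancement as attributes.
#' @export
generate_scenario_pair <- function(cfg, met) {
  if (!inherits(met, "go_met")) abort("met must come from generate_meteorology()")
  if (attr(met, "n_days") != cfg$n_days)
    abort("meteorology and config day counts differ", class = "go_grid_error")
  mask <- urban_mask(cfg)
  n_cell <- nrow(mask)
  nd <- cfg$n_days
  nt <- nd * 24L
  t_daily <- attr(met, "t_daily")

  # Base field, cells x hours
  diurnal <- cfg$base_o3_diurnal_amp_ppb * cos(2 * pi * (met$hour - 15) / 24)
  day_eff <- cfg$base_o3_temp_slope * (t_daily - mean(t_daily))
  base_t <- cfg$base_o3_mean_ppb + diurnal + day_eff[met$day]
  spat <- -2 * (grid_dist_km(mask, cfg$urban_center) / cfg$domain_size_km)
  base <- matrix(rep(base_t, each = n_cell), n_cell, nt) + spat
  if (cfg$base_noise_sd > 0) {
    base <- base + with_seed(sub_seed(cfg, 301L),
                             matrix(rnorm(n_cell * nt, 0, cfg$base_noise_sd),
                                    n_cell, nt))
  }
  base[base < 0] <- 0

  # daily enhancement, cells x days, calibrated to the urban-mean target
  kern <- delta_kernel(cfg, mask)
  keep <- seq(cfg$spinup_days + 1L, nd)
  mod <- pmax(0, 1 + cfg$temp_coupling * (t_daily - mean(t_daily)))
  amp <- if (cfg$delta_o3_urban_ppb > 0) {
    cfg$delta_o3_urban_ppb / (mean(kern[mask$urban]) * mean(mod[keep]))
  } else 0
  delta_day <- amp * outer(kern, mod)
  delta_free <- delta_day
  if (cfg$delta_noise_sd > 0 && amp > 0) {
    s <- cfg$delta_noise_sd
    eps <- with_seed(sub_seed(cfg, 302L),
                     matrix(rlnorm(n_cell * nd, -s^2 / 2, s), n_cell, nd))
    delta_day <- delta_day * eps
  }
  ug <- base + delta_day[, rep(seq_len(nd), each = 24L)]

  out <- tibble(
    cell = rep(mask$cell, nt),
    time = rep(seq_len(nt), each = n_cell),
    o3_base = as.vector(base),
    o3_ug = as.vector(ug)
  )
  structure(out,
            class = c("go_scenario", class(out)),
            grid = mask, n_days = nd, spinup_days = cfg$spinup_days,
            delta_daily_noisefree = delta_free,
            labels = c("Base", "UG"))
}

#' Generate a synthetic population raster
#'
#' Population density decays as a Gaussian from the urban center
#' (sd = 0.6 * urban_radius_km) over a uniform rural floor carrying 10% of
#' the unnormalized mass, then is normalized so the raster sums exactly to
#' `pop_total`. With `uniform = TRUE` every cell holds the same population.
#'
#' @param cfg A [synth_config()].
#' @param uniform Spread the population evenly instead.
#' @return Tibble `cell`, `x`, `y`, `pop` (persons), one row per grid cell.
#' @export
generate_population <- function(cfg, uniform = FALSE) {
  g <- config_grid(cfg)
  if (uniform) {
    w <- rep(1, nrow(g))
  } else {
    d <- grid_dist_km(g, cfg$urban_center)
    core <- exp(-d^2 / (2 * (0.6 * cfg$urban_radius_km)^2))
    w <- core + 0.1 * sum(core) / nrow(g)
  }
  tibble(cell = g$cell, x = g$x, y = g$y,
         pop = cfg$pop_total * w / sum(w))
}

#' Generate a baseline incidence table
#'
#' One aggregate age group by default, with the configured annual
#' cause-specific mortality incidence. Additional age groups can be passed
#' straight to the health functions as extra rows with their own
#' `annual_rate` and `pop_share`.
#'
#' @param cfg A [synth_config()].
#' @return Tibble `age_group`, `cause`, `annual_rate` (per person per
#'   year), `pop_share` (fractions summing to 1).
#' @export
generate_incidence <- function(cfg) {
  tibble(age_group = "all_ages", cause = "copd",
         annual_rate = cfg$incidence_annual, pop_share = 1)
}
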