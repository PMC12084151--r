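# independent transcription of the closed-form responses, for the oracle
# checks: gamma_T = Eopt*CT2*exp(CT1*x)/(CT2 - CT1*(1 - exp(CT2*x))),
# x = (1/Topt - 1/T)/0.00831; gamma_L = Cp*alpha*P/sqrt(1 + alpha^2 P^2)
oracle_gamma_t <- function(t_k, ct1 = 95, ct2 = 230, topt = 313, eopt = 2.037) {
  x <- (1 / topt - 1 / t_k) / 0.00831
  eopt * ct2 * exp(ct1 * x) / (ct2 - ct1 * (1 - exp(ct2 * x)))
}
oracle_gamma_l <- function(p, alpha = 0.004, cp = 1.21) {
  cp * alpha * p / sqrt(1 + alpha^2 * p^2)
}

# hand-built go_met: one day, constant temperature/PAR, given cell offsets
make_met <- function(t2m_c, par, cells, offsets = 0, n_hours = 24) {
  ser <- tibble::tibble(day = 1L, hour = seq_len(n_hours) - 1L,
                        time = seq_len(n_hours),
                        t2m = t2m_c, par = par)
  structure(ser, class = c("go_met", class(ser)),
            spatial = tibble::tibble(cell = cells,
                                     t2m_offset = rep_len(offsets, length(cells))),
            t_daily = t2m_c, n_days = 1L)
}

# single-cell PFT map + LAI on a 1x1 grid
one_cell_pft <- function(chi, pft = 7L, lai = 5) {
  g <- go_grid(1, 1, 1)
  g$urban <- FALSE
  pm <- structure(tibble::tibble(cell = 1L, pft = pft, chi = chi,
                                 source = "coarse-nonurban"),
                  class = c("go_pft", "tbl_df", "tbl", "data.frame"),
                  grid = g, fine_factor = 1L)
  lm <- structure(tibble::tibble(cell = 1L, x = 0.5, y = 0.5, lai = lai),
                  class = c("go_lai", "tbl_df", "tbl", "data.frame"), grid = g)
  list(pft = pm, lai = lm)
}

test_that("temperature activity peaks at T_opt with value E_opt", {
  p <- megan_temperature_params()
  expect_equal(gamma_temperature(p$t_opt_k), p$e_opt, tolerance = 1e-12)
  # strictly increasing below the optimum
  ts <- seq(265, p$t_opt_k, by = 0.5)
  g <- gamma_temperature(ts)
  expect_true(all(diff(g) > 0))
  # single-peaked: decreasing above
  expect_true(all(diff(gamma_temperature(seq(p$t_opt_k, 329, by = 0.5))) < 0))
  expect_true(all(g >= 0))
  expect_error(gamma_temperature(200), "physical range")
})

test_that("activity factors match an independent closed-form transcription", {
  expect_equal(gamma_temperature(303.15), oracle_gamma_t(303.15), tolerance = 1e-12)
  for (tk in c(285.5, 295, 303.15, 313, 325)) {
    expect_equal(gamma_temperature(tk), oracle_gamma_t(tk), tolerance = 1e-12)
  }
  expect_equal(gamma_light(1000), oracle_gamma_l(1000), tolerance = 1e-12)
  expect_equal(gamma_light(c(0, 50, 500, 2000)),
               oracle_gamma_l(c(0, 50, 500, 2000)), tolerance = 1e-12)
})

test_that("light activity is zero in the dark, near-linear at low PAR, saturating", {
  expect_identical(gamma_light(0), 0)
  expect_equal(gamma_light(20) / gamma_light(10), 2, tolerance = 0.1)
  expect_lt(gamma_light(4000) / gamma_light(2000), 1.01)
  expect_error(gamma_light(-1), "nonnegative")
})

test_that("standardized canopy coefficient gives gamma = 1 at standard conditions", {
  act <- activity_config()
  g_std <- act$c_ce * 5 * gamma_temperature(303.15) * gamma_light(1000)
  expect_equal(g_std, 1, tolerance = 1e-12)
})

test_that("flux is the product of activity and the emission-weighted fractions", {
  # gamma forced to 0.5: F = 0.5 * chi * epsilon = 0.5 * 1 * 10 = 5
  met <- make_met(30, 1000, cells = 1L)
  oc <- one_cell_pft(chi = 1, lai = 5)
  halfg <- activity_config(c_ce = 0.5 / (5 * gamma_temperature(303.15) *
                                           gamma_light(1000)))
  ef <- tibble::tibble(pft = 7L, epsilon_ug_m2_h = 10)
  em <- emission_flux(oc$pft, oc$lai, met, halfg, ef)
  expect_equal(unique(em$flux), 5, tolerance = 1e-12)

  # gamma = 1, two PFTs: F = 0.3*10 + 0.2*4 = 3.8
  oc2 <- one_cell_pft(chi = c(0.3, 0.2), pft = c(7L, 13L), lai = 5)
  unitg <- activity_config(c_ce = 1 / (5 * gamma_temperature(303.15) *
                                         gamma_light(1000)))
  ef2 <- tibble::tibble(pft = c(7L, 13L), epsilon_ug_m2_h = c(10, 4))
  em2 <- emission_flux(oc2$pft, oc2$lai, met, unitg, ef2)
  expect_equal(unique(em2$flux), 3.8, tolerance = 1e-12)
})

test_that("flux is exactly linear in chi and in epsilon", {
  met <- make_met(28, 800, cells = 1L)
  oc <- one_cell_pft(chi = c(0.2, 0.15), pft = c(5L, 13L), lai = 4)
  ef <- tibble::tibble(pft = c(5L, 13L), epsilon_ug_m2_h = c(10000, 800))
  f1 <- emission_flux(oc$pft, oc$lai, met, ef_table = ef)$flux
  oc2 <- one_cell_pft(chi = 2 * c(0.2, 0.15), pft = c(5L, 13L), lai = 4)
  f2 <- emission_flux(oc2$pft, oc2$lai, met, ef_table = ef)$flux
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  ef3 <- dplyr::mutate(ef, epsilon_ug_m2_h = epsilon_ug_m2_h * 3)
  f3 <- emission_flux(oc$pft, oc$lai, met, ef_table = ef3)$flux
  expect_equal(f3, 3 * f1, tolerance = 1e-12)
})

test_that("zero LAI or zero vegetated fraction emits nothing", {
  met <- make_met(30, 1000, cells = 1L)
  oc <- one_cell_pft(chi = 1, lai = 0)
  em <- emission_flux(oc$pft, oc$lai, met)
  expect_identical(nrow(em), 0L) # absent rows encode zero flux
  bud <- seasonal_budget(em, attr(oc$pft, "grid"), 1e6)
  expect_identical(bud$total_gg, 0)
})

test_that("flux is nonnegative on full synthetic meteorology", {
  cfg <- tiny_config(seed = 6)
  lc <- generate_landcover(cfg)
  met <- generate_meteorology(cfg)
  pm <- fuse_landcover(lc$fine, lc$coarse, lc$mask, lc$fine_factor)
  em <- emission_flux(pm, lai_from_pft(pm), met)
  expect_true(all(em$flux >= 0))
  # dark hours still emit zero (gamma_L = 0)
  hours <- attr(em, "hours")
  night <- hours$time[hours$hour == 2]
  expect_true(all(em$flux[em$time %in% night] == 0))
})

test_that("missing emission factors are reported", {
  met <- make_met(30, 1000, cells = 1L)
  oc <- one_cell_pft(chi = 1, pft = 9L)
  expect_error(emission_flux(oc$pft, oc$lai, met,
                             ef_table = tibble::tibble(pft = 7L,
                                                       epsilon_ug_m2_h = 10)),
               "no emission factor")
})

test_that("budget unit conversion and exact urban/non-urban decomposition", {
  # constant 1 ug m-2 h-1 over one 1 km2 cell for one hour = 1 g = 1e-9 Gg
  g <- go_grid(1, 1, 1)
  g$urban <- TRUE
  em <- structure(tibble::tibble(cell = 1L, time = 1L, flux = 1),
                  class = c("go_emission", "tbl_df", "tbl", "data.frame"),
                  grid = g, species = "isoprene")
  bud <- seasonal_budget(em, g, 1e6)
  expect_equal(bud$total_gg, 1e-9, tolerance = 1e-15)
  expect_identical(bud$urban_fraction, 1) # mask covers the whole domain

  cfg <- tiny_config(seed = 8)
  lc <- generate_landcover(cfg)
  pm <- fuse_landcover(lc$fine, lc$coarse, lc$mask, lc$fine_factor)
  em2 <- emission_flux(pm, lai_from_pft(pm), generate_meteorology(cfg))
  bud2 <- seasonal_budget(em2, lc$mask, (cfg$coarse_res_km * 1000)^2)
  expect_equal(bud2$total_gg, bud2$urban_gg + bud2$nonurban_gg, tolerance = 1e-15)
  expect_gt(bud2$total_gg, 0)
  expect_error(seasonal_budget(em2, lc$mask, -1), "positive")
})
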