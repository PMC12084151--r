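test_that("relative risk is clamped at the minimum-risk concentration", {
  m <- rr_model(rr_per_10ppb = 1.06, c0 = 32.4)
  expect_identical(relative_risk(32.4, m), 1)
  expect_identical(relative_risk(c(0, 10, 32.4), m), c(1, 1, 1))
  expect_equal(relative_risk(42.4, m), 1.06, tolerance = 1e-12)
  expect_equal(relative_risk(52.4, m), 1.06^2, tolerance = 1e-12) # 1.1236
  expect_error(relative_risk(-1, m), "nonnegative")
  expect_error(rr_model(rr_per_10ppb = 0))
})

test_that("population-weighted RR matches the hand computation", {
  m <- rr_model(1.06, 32.4)
  df <- tibble::tibble(conc = c(42.4, 52.4), pop = c(100, 300))
  # (100*1.06 + 300*1.1236)/400 = 1.1077
  expect_equal(population_weighted_rr(df, m), 1.1077, tolerance = 1e-12)
  expect_identical(population_weighted_rr(
    tibble::tibble(conc = c(10, 30), pop = c(5, 5)), m), 1)
  one <- tibble::tibble(conc = 52.4, pop = 7)
  expect_equal(population_weighted_rr(one, m), relative_risk(52.4, m))
  expect_error(population_weighted_rr(tibble::tibble(conc = 40, pop = 0), m),
               class = "go_zero_pop")
})

test_that("single-cell attributable mortality matches the hand oracle", {
  m <- rr_model(1.06, 32.4)
  df <- tibble::tibble(cell = 1L, conc = 52.4, pop = 1000)
  inc <- tibble::tibble(age_group = "all", annual_rate = 0.001, pop_share = 1)
  b <- attributable_mortality(df, inc, m, season_days = 365)
  rr <- 1.06^2
  expect_equal(b$rr_bar, rr, tolerance = 1e-12)
  expect_equal(unname(b$i_hat), 0.001 / rr, tolerance = 1e-12)
  expect_equal(b$total, 1000 * 0.001 / rr * (rr - 1), tolerance = 1e-10) # 0.1100
  b92 <- attributable_mortality(df, inc, m, season_days = 92)
  expect_equal(b92$total, b$total * 92 / 365, tolerance = 1e-12)
})

test_that("no burden accrues below the minimum-risk concentration", {
  m <- rr_model(1.08, 32.4)
  df <- tibble::tibble(cell = 1:5, conc = c(0, 5, 20, 30, 32.4),
                       pop = runif(5, 10, 1e4))
  inc <- tibble::tibble(age_group = "all", annual_rate = 0.002)
  b <- attributable_mortality(df, inc, m)
  expect_identical(b$total, 0)
  expect_identical(b$rr_bar, 1)
  expect_true(all(b$grid$deaths == 0))
})

test_that("uniform concentration collapses to the closed form", {
  m <- rr_model(1.07, 32.4)
  withr::with_seed(16, {
    pop <- runif(50, 0, 1e4)
    df <- tibble::tibble(cell = 1:50, conc = 61.7, pop = pop)
    inc <- tibble::tibble(age_group = "all", annual_rate = 0.0015)
    b <- attributable_mortality(df, inc, m)
    rr <- relative_risk(61.7, m)
    expect_equal(b$total, sum(pop) * 0.0015 * (rr - 1) / rr, tolerance = 1e-12)
  })
})

test_that("age groups partition the burden consistently", {
  m <- rr_model(1.06)
  df <- tibble::tibble(cell = 1:3, conc = c(40, 55, 70), pop = c(1e3, 2e3, 3e3))
  inc <- tibble::tibble(age_group = c("25-60", "60+"),
                        annual_rate = c(5e-4, 3e-3),
                        pop_share = c(0.7, 0.3))
  b <- attributable_mortality(df, inc, m, season_days = 92)
  expect_equal(sum(b$by_group$deaths), b$total, tolerance = 1e-12)
  expect_equal(sum(b$grid$deaths), b$total, tolerance = 1e-12)
  expect_error(attributable_mortality(df, dplyr::mutate(inc, pop_share = c(0.5, 0.3)), m),
               "sum to 1")
  expect_error(attributable_mortality(df, dplyr::mutate(inc, annual_rate = -1), m),
               ">= 0")
})

test_that("raising any concentration never decreases the total burden", {
  m <- rr_model(1.06)
  withr::with_seed(17, {
    df <- tibble::tibble(cell = 1:20, conc = runif(20, 10, 80),
                         pop = runif(20, 1, 1e4))
    inc <- tibble::tibble(age_group = "all", annual_rate = 0.001)
    b0 <- attributable_mortality(df, inc, m)$total
    for (g in c(1, 7, 15)) {
      df2 <- df
      df2$conc[g] <- df2$conc[g] + 10
      expect_gte(attributable_mortality(df2, inc, m)$total, b0)
    }
  })
})

test_that("urban-greening attribution has the right limits", {
  m <- rr_model(1.06)
  inc <- tibble::tibble(age_group = "all", annual_rate = 0.001)
  # identical scenarios: no attributed burden
  df <- tibble::tibble(cell = 1:4, conc_base = c(40, 50, 60, 30),
                       conc_ug = c(40, 50, 60, 30), pop = rep(1e3, 4))
  at <- attribute_to_urban_greening(df, inc, m)
  expect_identical(at$deaths_attributed, 0)
  expect_identical(at$fraction, 0)

  # base at the threshold, UG above: the whole burden is attributed
  df1 <- tibble::tibble(cell = 1L, conc_base = 32.4, conc_ug = 45, pop = 1e3)
  at1 <- attribute_to_urban_greening(df1, inc, m)
  expect_identical(at1$fraction, 1)

  # both below threshold: fraction undefined
  df0 <- tibble::tibble(cell = 1L, conc_base = 20, conc_ug = 25, pop = 1e3)
  expect_true(is.na(attribute_to_urban_greening(df0, inc, m)$fraction))
})

test_that("attribution fraction stays in [0, 1] for cellwise UG >= Base", {
  m <- rr_model(1.06)
  inc <- tibble::tibble(age_group = "all", annual_rate = 0.001)
  withr::with_seed(18, {
    for (k in 1:20) {
      n <- sample(2:50, 1)
      df <- tibble::tibble(cell = seq_len(n),
                           conc_base = runif(n, 20, 80),
                           pop = runif(n, 1, 1e4))
      df$conc_ug <- df$conc_base + runif(n, 0, 10)
      fr <- attribute_to_urban_greening(df, inc, m)$fraction
      expect_true(fr >= 0 && fr <= 1)
    }
  })
})

test_that("pipeline health chain equals the loop oracle on small instances", {
  withr::with_seed(19, {
    for (k in 1:25) {
      n <- sample(100, 1)
      rr <- runif(1, 1.01, 1.15)
      c0 <- runif(1, 20, 45)
      sdays <- sample(c(92, 180, 365), 1)
      conc <- runif(n, 0, 100)
      pop <- runif(n, 0, 1e5)
      if (sum(pop) == 0) pop[1] <- 1
      ng <- sample(3, 1)
      shares <- runif(ng); shares <- shares / sum(shares)
      rates <- runif(ng, 1e-5, 5e-3)
      m <- rr_model(rr, c0)
      inc <- tibble::tibble(age_group = paste0("g", seq_len(ng)),
                            annual_rate = rates, pop_share = shares)
      b <- attributable_mortality(tibble::tibble(cell = seq_len(n), conc = conc,
                                                 pop = pop),
                                  inc, m, season_days = sdays)
      o <- oracle_health(conc, pop, rates, shares, rr, c0, sdays)
      expect_equal(b$total, o$total, tolerance = 1e-10)
      expect_equal(b$rr_bar, o$rr_bar, tolerance = 1e-10)
      expect_equal(unname(b$i_hat), o$i_hat, tolerance = 1e-10)
      expect_equal(b$grid$deaths, o$m_cell, tolerance = 1e-10)
    }
  })
})
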