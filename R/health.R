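#' Log-linear relative-risk model for ozone exposure
#'
#' Exposure-response model used throughout the health module:
#' `RR(C) = rr ^ ((C - c0) / 10)` for concentrations above the theoretical
#' minimum risk concentration `c0`, and exactly 1 at or below it. `rr` is
#' the relative risk associated with a 10 ppb increase in the exposure
#' metric (seasonal-mean MDA8 O3 by default).
#'
#' @param rr_per_10ppb Relative risk per 10 ppb (> 0); default 1.06 for
#'   COPD mortality, editable.
#' @param c0 Theoretical minimum risk concentration (ppb, default 32.4).
#' @param cause Disease label carried into results.
#' @return List of class `go_rr_model`.
#' @export
rr_model <- function(rr_per_10ppb = 1.06, c0 = 32.4, cause = "copd") {
  stopifnot(rr_per_10ppb > 0, c0 >= 0)
  structure(list(rr_per_10ppb = rr_per_10ppb, c0 = c0, cause = cause),
            class = "go_rr_model")
}

#' Relative risk at a concentration
#'
#' @param c Concentration(s), ppb, >= 0.
#' @param model A [rr_model()].
#' @return Dimensionless RR, >= 1 (exactly 1 at or below `c0`).
#' @export
relative_risk <- function(c, model = rr_model()) {
  if (any(c < 0)) abort("concentrations must be nonnegative")
  ifelse(c > model$c0, model$rr_per_10ppb^((c - model$c0) / 10), 1)
}

#' Population-weighted mean relative risk
#'
#' `rr_bar = sum_g P_g * RR(C_g) / sum_g P_g`; equals 1 when every cell is
#' at or below the minimum-risk concentration.
#'
#' @param df Tibble with columns `conc` (ppb) and `pop` (persons).
#' @param model A [rr_model()].
#' @return A single number >= 1.
#' @export
population_weighted_rr <- function(df, model = rr_model()) {
  if (any(df$pop < 0)) abort("population must be nonnegative")
  tot <- sum(df$pop)
  if (tot <= 0) abort("total population is zero", class = "go_zero_pop")
  sum(df$pop * relative_risk(df$conc, model)) / tot
}

#' Ozone-attributable mortality on a grid
#'
#' Attributable-fraction calculation: the underlying incidence is the
#' reported incidence deflated by the population-weighted mean relative
#' risk, `I_hat = I / rr_bar`, and per cell g and age group j the
#' attributable deaths are `M_gj = P_g * share_j * I_hat_j *
#' (RR(C_g) - 1)`, summed over cells and groups. A seasonal burden scales
#' the annual incidence by `season_days / 365`.
#'
#' @param df Tibble `cell`, `conc` (exposure metric, ppb), `pop`
#'   (persons); optional `x`, `y` carried through.
#' @param incidence Tibble `age_group`, `annual_rate` (per person-year,
#'   >= 0) and `pop_share` (group shares of every cell's population,
#'   summing to 1; defaults to a single aggregate group when the column is
#'   absent).
#' @param model A [rr_model()].
#' @param season_days Days of the exposure season; 365 gives an annual
#'   burden.
#' @return Object of class `go_burden`: list with `grid` (per-cell tibble
#'   incl. `rr` and `deaths`), `by_group`, `total` deaths, `rr_bar`,
#'   `i_hat` per group, the model and `season_days`. See [tidy()] /
#'   [glance()].
#' @export
attributable_mortality <- function(df, incidence, model = rr_model(),
                                   season_days = 365) {
  if (any(incidence$annual_rate < 0)) abort("incidence rates must be >= 0")
  if (!"pop_share" %in% names(incidence)) incidence$pop_share <- 1
  if (abs(sum(incidence$pop_share) - 1) > 1e-8)
    abort("age-group population shares must sum to 1")
  stopifnot(season_days > 0, season_days <= 366)
  rr <- relative_risk(df$conc, model)
  tot <- sum(df$pop)
  if (tot <= 0) abort("total population is zero", class = "go_zero_pop")
  rr_bar <- sum(df$pop * rr) / tot
  scale <- season_days / 365
  i_hat <- incidence$annual_rate / rr_bar
  # deaths per cell summed over groups: P_g * (RR-1) * sum_j share_j i_hat_j
  per_pop <- sum(incidence$pop_share * i_hat) * scale
  grid <- df |>
    mutate(rr = rr, deaths = .data$pop * (rr - 1) * per_pop)
  by_group <- incidence |>
    mutate(i_hat = i_hat,
           deaths = .data$pop_share * i_hat * scale *
             sum(df$pop * (rr - 1)))
  structure(list(grid = as_tibble(grid), by_group = as_tibble(by_group),
                 total = sum(grid$deaths), rr_bar = rr_bar,
                 i_hat = setNames(i_hat, incidence$age_group),
                 model = model, season_days = season_days),
            class = "go_burden")
}

#' Attribute the ozone burden to urban greening
#'
#' Computes the attributable mortality independently for the Base and UG
#' exposure surfaces and reports the difference as the urban-greening
#' burden, with `fraction = (M_ug - M_base) / M_ug` (in \[0, 1\] whenever
#' the UG exposure is at least the Base exposure everywhere; `NA` when
#' `M_ug` is zero).
#'
#' @param df Tibble `cell`, `conc_base`, `conc_ug` (ppb), `pop`.
#' @inheritParams attributable_mortality
#' @return Object of class `go_attribution`: list with the two
#'   `go_burden`s, `deaths_base`, `deaths_ug`, `deaths_attributed`,
#'   `fraction`, and a per-cell `grid` tibble.
#' @export
attribute_to_urban_greening <- function(df, incidence, model = rr_model(),
                                        season_days = 365) {
  base <- attributable_mortality(
    select(df, any_of(c("cell", "x", "y", "pop")), conc = "conc_base"),
    incidence, model, season_days)
  ug <- attributable_mortality(
    select(df, any_of(c("cell", "x", "y", "pop")), conc = "conc_ug"),
    incidence, model, season_days)
  grid <- df |>
    mutate(deaths_base = base$grid$deaths,
           deaths_ug = ug$grid$deaths,
           deaths_attributed = .data$deaths_ug - .data$deaths_base)
  structure(list(base = base, ug = ug,
                 deaths_base = base$total, deaths_ug = ug$total,
                 deaths_attributed = ug$total - base$total,
                 fraction = if (ug$total > 0)
                   (ug$total - base$total) / ug$total else NA_real_,
                 grid = as_tibble(grid),
                 model = model, season_days = season_days),
            class = "go_attribution")
}

#' @export
print.go_burden <- function(x, ...) {
  cat("<go_burden>", format(x$total, digits = 4), "attributable deaths",
      sprintf("(rr_bar = %.4f, season = %g days)\n", x$rr_bar, x$season_days))
  invisible(x)
}

#' @export
print.go_attribution <- function(x, ...) {
  cat("<go_attribution>\n",
      sprintf("  Base: %.4g  UG: %.4g  attributed: %.4g (%.1f%%)\n",
              x$deaths_base, x$deaths_ug, x$deaths_attributed,
              100 * x$fraction))
  invisible(x)
}
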