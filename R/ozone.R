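#' Daily maximum 8-hour mean ozone (MDA8)
#'
#' For each day, MDA8 is the maximum over the 24 running 8-hour means
#' whose window starts in that day (00:00-23:00 local); windows crossing
#' midnight draw their remaining hours from the next day, and hours past
#' the end of the series count as missing. A window is valid when at least
#' `min_valid_hours` of its 8 hours are present (the mean is over the
#' valid hours); a day's MDA8 is `NA` unless at least `min_valid_windows`
#' of its 24 windows are valid. This is the common regulatory convention.
#'
#' @param df Tibble with columns `cell`, `time` (1-based hour index over
#'   consecutive days) and the hourly ozone column named by `value`;
#'   missing hours may be `NA` or absent rows.
#' @param value Name of the ozone column.
#' @param min_valid_hours,min_valid_windows Validity thresholds.
#' @return Tibble `cell`, `day`, `mda8` (ppb).
#' @export
mda8 <- function(df, value = "o3", min_valid_hours = 6L,
                 min_valid_windows = 18L) {
  cells <- sort(unique(df$cell))
  nt <- max(df$time)
  if (any(df$time < 1)) abort("time indices must be >= 1")
  m <- matrix(NA_real_, length(cells), nt)
  m[cbind(match(df$cell, cells), df$time)] <- df[[value]]
  md <- mda8_matrix(m, min_valid_hours, min_valid_windows)
  tibble(cell = rep(cells, ncol(md)),
         day = rep(seq_len(ncol(md)), each = length(cells)),
         mda8 = as.vector(md))
}

#' MDA8 on a single hourly series
#'
#' @param x Hourly values covering whole days (length a multiple of 24, or
#'   it is right-padded with `NA`).
#' @inheritParams mda8
#' @return Numeric vector of per-day MDA8 values.
#' @export
mda8_series <- function(x, min_valid_hours = 6L, min_valid_windows = 18L) {
  as.vector(mda8_matrix(matrix(x, 1), min_valid_hours, min_valid_windows))
}

# cells x hours matrix -> cells x days MDA8
mda8_matrix <- function(m, min_valid_hours = 6L, min_valid_windows = 18L) {
  nt <- ncol(m)
  n_days <- ceiling(nt / 24)
  if (nt < n_days * 24) m <- cbind(m, matrix(NA_real_, nrow(m), n_days * 24 - nt))
  v <- !is.na(m)
  m0 <- ifelse(v, m, 0)
  pad <- matrix(0, nrow(m), 7)
  cs <- t(apply(cbind(m0, pad), 1, cumsum))
  cv <- t(apply(cbind(v, pad), 1, cumsum))
  idx <- seq_len(n_days * 24)
  # rolling 8-h sums/counts for windows starting at each hour
  roll_sum <- cs[, idx + 7, drop = FALSE] - cbind(0, cs[, idx[-length(idx)], drop = FALSE])
  roll_n <- cv[, idx + 7, drop = FALSE] - cbind(0, cv[, idx[-length(idx)], drop = FALSE])
  wmean <- roll_sum / roll_n
  wmean[roll_n < min_valid_hours] <- NA_real_
  out <- matrix(NA_real_, nrow(m), n_days)
  for (d in seq_len(n_days)) {
    w <- wmean[, (d - 1L) * 24L + 1:24, drop = FALSE]
    nvalid <- rowSums(!is.na(w))
    mx <- suppressWarnings(apply(w, 1, max, na.rm = TRUE))
    mx[nvalid < min_valid_windows] <- NA_real_
    mx[!is.finite(mx)] <- NA_real_
    out[, d] <- mx
  }
  out
}

#' Scenario MDA8 difference surface
#'
#' Computes per-cell daily MDA8 for both scenarios, drops the leading
#' spin-up days, and summarizes each cell over the retained days: mean
#' Base and UG MDA8, their difference `delta = UG - Base` (ppb), and the
#' relative change `rel_pct = delta / base seasonal mean * 100` (`NA`
#' where the Base mean is zero).
#'
#' @param pair `go_scenario` tibble (`cell`, `time`, `o3_base`, `o3_ug`)
#'   from [generate_scenario_pair()] or assembled to the same contract.
#' @param spinup_days Leading days to drop (default from the pair's
#'   metadata, else 4).
#' @return Tibble of class `go_exposure` with the per-cell seasonal
#'   summary (`cell`, `x`, `y`, `urban` when known, `mda8_base`,
#'   `mda8_ug`, `delta`, `rel_pct`); the per-day table (`cell`, `day`,
#'   `mda8_base`, `mda8_ug`, `delta`) is in `attr(, "daily")`.
#' @export
delta_mda8 <- function(pair, spinup_days = NULL) {
  spinup_days <- spinup_days %||% attr(pair, "spinup_days") %||% 4L
  db <- mda8(pair, "o3_base")
  du <- mda8(pair, "o3_ug")
  daily <- db |>
    rename(mda8_base = "mda8") |>
    mutate(mda8_ug = du$mda8, delta = .data$mda8_ug - .data$mda8_base) |>
    filter(.data$day > spinup_days)
  if (!nrow(daily)) abort("no days remain after spin-up removal")
  seasonal <- daily |>
    summarise(mda8_base = mean(.data$mda8_base, na.rm = TRUE),
              mda8_ug = mean(.data$mda8_ug, na.rm = TRUE),
              .by = "cell") |>
    mutate(delta = .data$mda8_ug - .data$mda8_base,
           rel_pct = ifelse(.data$mda8_base > 0,
                            .data$delta / .data$mda8_base * 100, NA_real_))
  grid <- attr(pair, "grid")
  if (!is.null(grid)) {
    keep <- intersect(c("cell", "x", "y", "urban"), names(grid))
    seasonal <- left_join(select(as_tibble(grid), all_of(keep)),
                          seasonal, by = "cell")
  }
  structure(seasonal,
            class = c("go_exposure", class(seasonal)),
            daily = daily, spinup_days = spinup_days, grid = grid)
}

#' Urban versus suburban summary of the MDA8 difference
#'
#' Boxplot-style statistics (min, 25th/50th/75th percentiles, max, mean)
#' of the seasonal per-cell MDA8 difference in the urban and
#' suburban/rural strata.
#'
#' @param surface `go_exposure` from [delta_mda8()].
#' @param mask Grid tibble with logical `urban`; defaults to the mask
#'   carried by the surface.
#' @return Tibble with one row per stratum (`region`, `n_cells`, `min`,
#'   `p25`, `p50`, `p75`, `max`, `mean`).
#' @export
stratify <- function(surface, mask = NULL) {
  mask <- mask %||% attr(surface, "grid")
  df <- as_tibble(surface)
  if (!"urban" %in% names(df)) {
    df <- left_join(df, select(as_tibble(mask), "cell", "urban"), by = "cell")
  }
  if (!any(df$urban) || all(df$urban))
    abort("both an urban and a suburban stratum are required",
          class = "go_empty_stratum")
  df |>
    mutate(region = ifelse(.data$urban, "urban", "suburban")) |>
    summarise(n_cells = dplyr::n(),
              min = min(.data$delta, na.rm = TRUE),
              p25 = quantile(.data$delta, 0.25, na.rm = TRUE, names = FALSE),
              p50 = quantile(.data$delta, 0.50, na.rm = TRUE, names = FALSE),
              p75 = quantile(.data$delta, 0.75, na.rm = TRUE, names = FALSE),
              max = max(.data$delta, na.rm = TRUE),
              mean = mean(.data$delta, na.rm = TRUE),
              .by = "region") |>
    arrange(desc(.data$region))
}

#' MDA8 enhancement versus daily-mean temperature
#'
#' Relates the daily urban-mean (or all-cell-mean) MDA8 difference to the
#' daily-mean 2 m temperature: equal-width temperature bins with
#' boxplot-style statistics, plus the Pearson correlation of the daily
#' series with a two-sided t-distribution p-value (via [stats::cor.test]).
#'
#' @param surface `go_exposure` from [delta_mda8()].
#' @param t_daily Tibble `day`, `t2m` of daily-mean temperature (degC),
#'   e.g. [daily_mean_temperature()]; spin-up days are dropped to match.
#' @param mask Grid tibble with `urban`; defaults to the surface's.
#' @param n_bins Number of temperature bins.
#' @param all_cells Use all grid cells instead of the urban mask for the
#'   daily means.
#' @return Tibble of class `go_temprel` of per-bin statistics (`bin_mid`,
#'   `n_days`, `min`, `p25`, `p50`, `p75`, `max`, `mean`); the daily
#'   pairs, `r` and `p_value` are attributes (see [glance()]).
#' @export
temperature_relationship <- function(surface, t_daily, mask = NULL,
                                     n_bins = 5L, all_cells = FALSE) {
  mask <- mask %||% attr(surface, "grid")
  daily <- attr(surface, "daily")
  if (is.null(daily)) abort("surface carries no daily table")
  if (!all_cells) {
    ucells <- mask$cell[mask$urban]
    daily <- filter(daily, .data$cell %in% ucells)
  }
  series <- daily |>
    summarise(delta = mean(.data$delta, na.rm = TRUE), .by = "day") |>
    inner_join(t_daily, by = "day")
  if (nrow(series) < 3) abort("at least 3 days are required for a correlation")
  if (stats::sd(series$delta) == 0 || stats::sd(series$t2m) == 0) {
    # degenerate: constant series carry no correlation information
    ct <- list(estimate = c(cor = NA_real_), p.value = NA_real_)
  } else {
    ct <- cor.test(series$t2m, series$delta, method = "pearson",
                   alternative = "two.sided")
  }
  breaks <- seq(min(series$t2m), max(series$t2m), length.out = n_bins + 1)
  series$bin <- cut(series$t2m, breaks, include.lowest = TRUE)
  bins <- series |>
    summarise(n_days = dplyr::n(),
              min = min(.data$delta), p25 = quantile(.data$delta, 0.25, names = FALSE),
              p50 = quantile(.data$delta, 0.5, names = FALSE),
              p75 = quantile(.data$delta, 0.75, names = FALSE),
              max = max(.data$delta), mean = mean(.data$delta),
              .by = "bin") |>
    mutate(bin_mid = (breaks[as.integer(.data$bin)] +
                        breaks[as.integer(.data$bin) + 1]) / 2,
           .before = 1) |>
    arrange(.data$bin_mid)
  structure(bins,
            class = c("go_temprel", class(bins)),
            daily = series, r = unname(ct$estimate), p_value = ct$p.value,
            n_days = nrow(series))
}

#' Population-weighted mean of an exposure column
#'
#' `sum(P * z) / sum(P)` over grid cells; equals the arithmetic mean for
#' uniform population and is invariant to rescaling P.
#'
#' @param surface `go_exposure` (or any tibble with `cell` and the value
#'   column).
#' @param population Tibble `cell`, `pop` (nonnegative, positive total).
#' @param value Column to weight (default `delta`).
#' @return A single number (ppb for the default column).
#' @export
population_weighted_mean <- function(surface, population, value = "delta") {
  df <- inner_join(as_tibble(surface), select(population, "cell", "pop"),
                   by = "cell")
  if (any(df$pop < 0)) abort("population must be nonnegative")
  ok <- !is.na(df[[value]])
  tot <- sum(df$pop[ok])
  if (tot <= 0) abort("total population is zero", class = "go_zero_pop")
  sum(df$pop[ok] * df[[value]][ok]) / tot
}
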