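# Independent brute-force oracles and tiny fixtures shared across tests.
# The oracles deliberately use plain loops and no package internals.

# exhaustive MDA8: for each day, scan all 24 windows starting that day
oracle_mda8 <- function(x, min_valid_hours = 6, min_valid_windows = 18) {
  n_days <- ceiling(length(x) / 24)
  out <- rep(NA_real_, n_days)
  for (d in seq_len(n_days)) {
    means <- rep(NA_real_, 24)
    for (s in 1:24) {
      i0 <- (d - 1) * 24 + s
      hrs <- x[i0:(i0 + 7)] # indexing past the end yields NA
      if (sum(!is.na(hrs)) >= min_valid_hours) means[s] <- mean(hrs, na.rm = TRUE)
    }
    if (sum(!is.na(means)) >= min_valid_windows) out[d] <- max(means, na.rm = TRUE)
  }
  out
}

# loop transcription of the attributable-mortality chain:
# RR(C) = rr^((C - c0)/10) above c0 else 1; rr_bar population-weighted;
# I_hat = I / rr_bar; M = sum_g sum_j P_g share_j I_hat_j (RR_g - 1) * s/365
oracle_health <- function(conc, pop, rates, shares, rr, c0, season_days) {
  n <- length(conc)
  rr_g <- numeric(n)
  for (g in seq_len(n)) {
    rr_g[g] <- if (conc[g] > c0) rr^((conc[g] - c0) / 10) else 1
  }
  rr_bar <- sum(pop * rr_g) / sum(pop)
  i_hat <- rates / rr_bar
  m_cell <- numeric(n)
  total <- 0
  for (g in seq_len(n)) {
    for (j in seq_along(rates)) {
      m <- pop[g] * shares[j] * i_hat[j] * (rr_g[g] - 1) * season_days / 365
      m_cell[g] <- m_cell[g] + m
      total <- total + m
    }
  }
  list(total = total, rr_bar = rr_bar, i_hat = i_hat, m_cell = m_cell)
}

# small, fast synthetic configuration for structural tests
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, domain_size_km = 12, coarse_res_km = 1,
         fine_res_m = 100, urban_radius_km = 4, n_days = 7,
         spinup_days = 2),
    list(...))
  do.call(synth_config, args)
}

# hand-built scenario tibble from a cells x hours matrix pair
scenario_from_matrices <- function(base, ug, grid = NULL, spinup_days = 0L) {
  n_cell <- nrow(base)
  nt <- ncol(base)
  out <- tibble::tibble(
    cell = rep(seq_len(n_cell), nt),
    time = rep(seq_len(nt), each = n_cell),
    o3_base = as.vector(base),
    o3_ug = as.vector(ug)
  )
  structure(out, class = c("go_scenario", class(out)),
            grid = grid, spinup_days = spinup_days)
}
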