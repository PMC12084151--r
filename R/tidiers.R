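#' Tidy and glance methods
#'
#' broom-style accessors for the pipeline's result objects: `tidy()`
#' returns the per-cell (or per-bin) table, `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name go_tidiers
NULL

#' @rdname go_tidiers
#' @method tidy go_exposure
#' @export
tidy.go_exposure <- function(x, ...) as_tibble(x)

#' @rdname go_tidiers
#' @method glance go_exposure
#' @export
glance.go_exposure <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_days = max(attr(x, "daily")$day) - attr(x, "spinup_days"),
         mean_base = mean(x$mda8_base, na.rm = TRUE),
         mean_delta = mean(x$delta, na.rm = TRUE),
         max_delta = max(x$delta, na.rm = TRUE))
}

#' @rdname go_tidiers
#' @method tidy go_burden
#' @export
tidy.go_burden <- function(x, ...) x$grid

#' @rdname go_tidiers
#' @method glance go_burden
#' @export
glance.go_burden <- function(x, ...) {
  tibble(total_deaths = x$total, rr_bar = x$rr_bar,
         season_days = x$season_days,
         rr_per_10ppb = x$model$rr_per_10ppb, c0 = x$model$c0,
         cause = x$model$cause)
}

#' @rdname go_tidiers
#' @method tidy go_attribution
#' @export
tidy.go_attribution <- function(x, ...) x$grid

#' @rdname go_tidiers
#' @method glance go_attribution
#' @export
glance.go_attribution <- function(x, ...) {
  tibble(deaths_base = x$deaths_base, deaths_ug = x$deaths_ug,
         deaths_attributed = x$deaths_attributed, fraction = x$fraction,
         season_days = x$season_days)
}

#' @rdname go_tidiers
#' @method tidy go_temprel
#' @export
tidy.go_temprel <- function(x, ...) as_tibble(x)

#' @rdname go_tidiers
#' @method glance go_temprel
#' @export
glance.go_temprel <- function(x, ...) {
  tibble(r = attr(x, "r"), p_value = attr(x, "p_value"),
         n_days = attr(x, "n_days"))
}

#' @rdname go_tidiers
#' @method glance go_run
#' @export
glance.go_run <- function(x, ...) x$summary
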