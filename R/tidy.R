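# broom-style accessors for run results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a run's metrics series
#'
#' One row per sampled time point and epithelial type, in long format.
#'
#' @param x A `cornea_run`.
#' @param ... Unused.
#' @return A tibble: mcs, day, type, count, thickness_um, wound_open.
#' @export
tidy.cornea_run <- function(x, ...) {
  m <- dplyr::select(x$metrics, "mcs", "day", dplyr::starts_with("n_"),
                     "thickness_um", "wound_open")
  tidyr::pivot_longer(m, dplyr::starts_with("n_"), names_to = "type",
                      names_prefix = "n_", values_to = "count") |>
    dplyr::mutate(type = toupper(.data$type)) |>
    dplyr::relocate("type", "count", .after = "day")
}

#' One-row run summary
#'
#' @param x A `cornea_run`.
#' @param ... Unused.
#' @return A one-row tibble: stratification day, homeostasis day, final
#'   counts, mean thickness over the last third of the run, wound-open
#'   fraction at the end.
#' @export
glance.cornea_run <- function(x, ...) {
  m <- x$metrics
  last3 <- m[m$day >= max(m$day) * 2 / 3, ]
  tibble::tibble(
    days = max(m$day),
    seed = x$seed,
    stratified_day = stratification_day(m),
    homeostasis_day = homeostasis_day(m),
    mean_thickness_um = mean(last3$thickness_um, na.rm = TRUE),
    final_cells = sum(m[nrow(m), c("n_stem", "n_basal", "n_wing", "n_super")]),
    final_wound_open = m$wound_open[nrow(m)]
  )
}
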