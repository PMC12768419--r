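# High-level drivers: sampled simulation, full scenarios, replicates.

#' Advance a simulation while sampling metrics
#'
#' Runs `days * day_to_mcs` MCS, collecting a metrics record (and a regional
#' census of live cell ids, for turnover analysis) every `sample_every` MCS.
#'
#' @param sim A `cornea_sim` (advanced in place).
#' @param days Simulated days (may be fractional).
#' @param sample_every Sampling interval in MCS.
#' @param sample_start Record a sample of the starting state too.
#' @return A metrics tibble; the per-sample censuses are attached as
#'   `attr(, "censuses")`.
#' @export
simulate_days <- function(sim, days, sample_every = NULL, sample_start = TRUE) {
  sample_every <- sample_every %||% sim$config$run$sample_every
  total <- as.integer(round(days * sim$config$slough$day_to_mcs))
  rows <- list(); cens <- list()
  take <- function() {
    rows[[length(rows) + 1L]] <<- collect_metrics(sim)
    cs <- region_census(sim)
    cs$day <- sim$mcs / sim$config$slough$day_to_mcs
    cens[[length(cens) + 1L]] <<- cs
  }
  if (sample_start) take()
  done <- 0L
  while (done < total) {
    chunk <- min(sample_every, total - done)
    run_mcs(sim, chunk)
    done <- done + chunk
    take()
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "censuses") <- cens
  out
}

#' Run a full scenario
#'
#' Builds the initial state from the config, seeds the RNG, simulates the
#' configured number of days with sampling, and returns a `cornea_run`
#' bundling the metrics series, event log, turnover censuses, the final
#' state snapshot and the config.  With `output_dir` set, also writes
#' `metrics.csv`, `events.csv`, `summary.json` and a final-state PNG.
#'
#' @param cfg A `cornea_config`.
#' @param output_dir Optional directory for file outputs.
#' @return A `cornea_run` object.
#' @export
#' @examples
#' \donttest{
#' cfg <- default_config(days = 1, seed = 7)
#' run <- run_scenario(cfg)
#' tidy(run)
#' }
run_scenario <- function(cfg, output_dir = NULL) {
  validate_config(cfg)
  set.seed(cfg$run$seed)
  sim <- build_initial_state(cfg)
  metrics <- simulate_days(sim, cfg$run$days, cfg$run$sample_every)
  run <- new_cornea_run(sim, metrics, cfg)
  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

new_cornea_run <- function(sim, metrics, cfg) {
  structure(list(
    metrics = metrics,
    events = event_table(sim),
    censuses = attr(metrics, "censuses"),
    final = snapshot_state(sim),
    config = cfg,
    seed = cfg$run$seed
  ), class = "cornea_run")
}

#' Continue a run from a snapshot
#'
#' Restores the state (including the RNG), optionally schedules an injury at
#' an offset from the current MCS, and simulates further.  Used to branch
#' injury scenarios from a common homeostatic state.
#'
#' @param snap A snapshot from [snapshot_state()] or a `cornea_run`'s
#'   `$final`.
#' @param days Additional days to simulate.
#' @param injury Optional [injury_spec()]; its `trigger_mcs` is interpreted
#'   as an offset from the snapshot's MCS.
#' @param seed Optional reseed for the continuation.
#' @param sample_every Sampling interval in MCS.
#' @return A `cornea_run` covering the continuation (metrics include the
#'   restart sample).
#' @export
continue_run <- function(snap, days, injury = NULL, seed = NULL,
                         sample_every = NULL) {
  sim <- restore_state(snap)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(injury)) {
    injury$trigger_mcs <- sim$mcs + injury$trigger_mcs
    sim$config$injury <- injury
    sim$injury_applied <- FALSE
  }
  metrics <- simulate_days(sim, days, sample_every)
  cfg <- sim$config
  cfg$run$seed <- seed %||% cfg$run$seed
  new_cornea_run(sim, metrics, cfg)
}

write_run_outputs <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- run$metrics[, !vapply(run$metrics, is.list, logical(1))]
  bt <- do.call(rbind, run$metrics$bin_thickness)
  colnames(bt) <- paste0("bin_thickness_", 0:(ncol(bt) - 1))
  write.csv(cbind(flat, bt), file.path(output_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(run$events, file.path(output_dir, "events.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(glance(run)), file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sim <- restore_state(run$final)
  snapshot(sim, file.path(output_dir, "final_state.png"), kind = "png")
  invisible(output_dir)
}

#' Run replicate scenarios
#'
#' Runs the scenario under `n` deterministically derived seeds
#' (`base_seed * 1000 + replicate`) and row-binds the tidied metrics with a
#' `replicate` column.
#'
#' @param cfg A `cornea_config`.
#' @param n Number of replicates.
#' @return A tibble of per-replicate metrics.
#' @export
run_replicates <- function(cfg, n = 3) {
  purrr::map_dfr(seq_len(n), function(r) {
    cfg$run$seed <- as.integer((cfg$run$seed * 1000 + r) %% .Machine$integer.max)
    run <- run_scenario(cfg)
    dplyr::mutate(tidy(run), replicate = r)
  })
}

#' @export
print.cornea_run <- function(x, ...) {
  cat("<cornea_run> ", x$config$run$days, " days, seed ", x$seed, ", ",
      nrow(x$metrics), " samples\n", sep = "")
  print(glance(x))
  invisible(x)
}
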