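# Tissue-level quantification: counts, thickness, binned apical positions,
# turnover, transit, healing and stability.

occupancy_types <- function(sim) {
  occ <- sim$spin
  ifelse(occ == 0L, 0L, sim$cells$ctype[pmax(occ, 1L)])
}

#' Cell counts by type
#'
#' @param sim A `cornea_sim`.
#' @return A tibble with one row per epithelial type and its live-cell count.
#' @export
count_cells <- function(sim) {
  cl <- sim$cells
  ids <- live_ids(sim, EPI_TYPES)
  tp <- factor(type_name(cl$ctype[ids]), levels = names(EPI_TYPES))
  tibble::tibble(type = names(EPI_TYPES),
                 count = as.integer(table(tp)))
}

#' Center-of-mass epithelial thickness
#'
#' The distance between the superficial layer and the deepest layer (basal
#' and stem cells): `(mean y of SUPER voxels - mean y of BASAL/STEM voxels) *
#' voxel_um`, restricted to an x-window (default: the central bins,
#' excluding the limbus).  Returns `NA` when either layer is missing (as
#' happens mid-injury).
#'
#' @param sim A `cornea_sim`.
#' @param x_range Inclusive 0-based voxel x-window `c(lo, hi)`; `NULL` for
#'   the default central window (bins 4-9 of 10).
#' @return Thickness in micrometers, or `NA_real_`.
#' @export
thickness_com <- function(sim, x_range = NULL) {
  W <- sim$W
  if (is.null(x_range)) x_range <- c(4 * (W %/% 10), W - 1)
  types <- occupancy_types(sim)
  idx0 <- seq_along(types) - 1L
  x <- idx0 %% W; y <- idx0 %/% W
  inwin <- x >= x_range[1] & x <= x_range[2]
  top <- y[inwin & types == CELL_TYPES[["SUPER"]]]
  bot <- y[inwin & types %in% CELL_TYPES[c("BASAL", "STEM")]]
  if (!length(top) || !length(bot)) return(NA_real_)
  (mean(top) - mean(bot)) * sim$config$geometry$voxel_um
}

#' Binned apical surface positions
#'
#' Divides the x-axis into `n_bins` equal segments (bin k covers columns
#' `[k*W/n, (k+1)*W/n)`); for each bin reports the mean over columns of the
#' highest epithelial (stem/basal/wing/super) voxel, in micrometers, plus the
#' epithelial thickness above the membrane row.
#'
#' @param sim A `cornea_sim`.
#' @param n_bins Number of segments (must divide the lattice width).
#' @return A tibble: bin (0-based), top_um, thickness_um.
#' @export
segment_top_positions <- function(sim, n_bins = 10) {
  W <- sim$W; H <- sim$H
  if (W %% n_bins != 0) stop("n_bins must divide the lattice width")
  types <- occupancy_types(sim)
  tm <- matrix(types %in% EPI_TYPES, nrow = W)   # W x H, row = x
  # highest epithelial voxel per column
  top <- apply(tm, 1, function(col) {
    w <- which(col)
    if (length(w)) max(w) - 1L else NA_integer_
  })
  mem_row <- sim$config$geometry$stroma_depth
  vox_um <- sim$config$geometry$voxel_um
  col_bin <- (seq_len(W) - 1L) %/% (W %/% n_bins)
  # mean superficial-cell voxel depth per segment: the smoother per-segment
  # apical-position tracker (the top_um column is the max-voxel estimate)
  supm <- matrix(types == CELL_TYPES[["SUPER"]], nrow = W)
  sup_y <- vapply(0:(n_bins - 1), function(b) {
    sel <- supm[col_bin == b, , drop = FALSE]
    if (!any(sel)) return(NA_real_)
    sum(t(sel) * (0:(H - 1))) / sum(sel)
  }, numeric(1))
  tibble::tibble(
    bin = 0:(n_bins - 1),
    top_um = vapply(0:(n_bins - 1), function(b)
      mean(top[col_bin == b], na.rm = TRUE) * vox_um, numeric(1)),
    thickness_um = vapply(0:(n_bins - 1), function(b)
      mean(top[col_bin == b] - mem_row, na.rm = TRUE) * vox_um, numeric(1)),
    super_pos_um = (sup_y - mem_row) * vox_um
  )
}

#' Fraction of the surface lacking superficial coverage
#'
#' The wound-open fraction: the share of interior x-columns lacking
#' superficial coverage -- either containing no superficial-cell voxel, or
#' having tear film penetrating below the apical surface (a crater or
#' erosion).  Zero defines structural closure.
#'
#' @param sim A `cornea_sim`.
#' @param tol Tear may dip this many voxels below the local apical surface
#'   before a column counts as open (surface roughness allowance).
#' @return A fraction in `[0, 1]`.
#' @export
wound_open_fraction <- function(sim, tol = 12L) {
  W <- sim$W; H <- sim$H
  types <- matrix(occupancy_types(sim), nrow = W)
  ys <- matrix(rep(0:(H - 1), each = W), nrow = W)
  epi <- matrix(types %in% EPI_TYPES, nrow = W)
  sup <- types == CELL_TYPES[["SUPER"]]
  tear <- types == CELL_TYPES[["TEAR"]]
  top_epi <- apply(ifelse(epi, ys, -1L), 1, max)
  has_super <- rowSums(sup) > 0
  # tear reaching more than `tol` voxels below the apical surface marks the
  # column as an open defect even when superficial cells flank it
  tear_depth <- apply(ifelse(tear, ys, H), 1, min)
  open <- !has_super | (tear_depth < top_epi - tol)
  interior <- 2:(W - 1)
  mean(open[interior])
}

#' One metrics record for the current state
#'
#' @param sim A `cornea_sim`.
#' @return A one-row tibble: mcs, day, per-type counts, COM thickness,
#'   wound-open fraction, and the 10 binned top positions/thicknesses as
#'   list-columns.
#' @export
collect_metrics <- function(sim) {
  cnt <- count_cells(sim)
  segs <- segment_top_positions(sim)
  wide <- setNames(as.list(cnt$count), paste0("n_", tolower(cnt$type)))
  types <- occupancy_types(sim)
  y <- (seq_along(types) - 1L) %/% sim$W
  mean_y <- function(tps) {
    sel <- types %in% tps
    if (any(sel)) mean(y[sel]) else NA_real_
  }
  tibble::tibble(
    mcs = sim$mcs,
    day = sim$mcs / sim$config$slough$day_to_mcs,
    !!!wide,
    thickness_um = thickness_com(sim),
    wound_open = wound_open_fraction(sim),
    y_basal = mean_y(CELL_TYPES[c("STEM", "BASAL")]),
    y_wing = mean_y(CELL_TYPES[["WING"]]),
    y_super = mean_y(CELL_TYPES[["SUPER"]]),
    bin_top = list(segs$top_um),
    bin_thickness = list(segs$thickness_um),
    bin_super_pos = list(segs$super_pos_um)
  )
}

# live epithelial cell ids by region (limbal: centroid x below the limbal
# boundary; peripheral: the rest)
region_census <- function(sim) {
  cl <- sim$cells
  ids <- live_ids(sim, EPI_TYPES)
  cx <- cl$sumx[ids] / pmax(cl$volume[ids], 1)
  lim <- sim$config$geometry$limbal_voxels
  list(limbal = ids[cx < lim], peripheral = ids[cx >= lim])
}

#' Regional turnover time
#'
#' From per-sample regional censuses of live cell ids, finds the first day at
#' which at least `threshold` (default 95%) of the region's reference-time
#' ids are no longer present — "nearly complete" cellular substitution.
#'
#' @param censuses A list of per-sample censuses as recorded by
#'   [simulate_days()] (`attr(metrics, "censuses")`), each with elements
#'   `day`, `limbal`, `peripheral`.
#' @param region `"limbal"` or `"peripheral"`.
#' @param reference_day Day whose census is the reference population.
#' @param threshold Substitution fraction defining turnover.
#' @return Days from the reference until turnover, or `NA_real_` if never
#'   reached within the series.
#' @export
turnover_time <- function(censuses, region = c("peripheral", "limbal"),
                          reference_day, threshold = 0.95) {
  region <- match.arg(region)
  days <- vapply(censuses, `[[`, numeric(1), "day")
  ref_i <- which.min(abs(days - reference_day))
  ref <- censuses[[ref_i]][[region]]
  if (!length(ref)) return(NA_real_)
  for (i in seq(ref_i, length(censuses))) {
    frac <- 1 - length(intersect(ref, censuses[[i]][[region]])) / length(ref)
    if (frac >= threshold) return(days[i] - days[ref_i])
  }
  NA_real_
}

#' Substitution-fraction series
#'
#' @inheritParams turnover_time
#' @return A tibble: day, substituted fraction (monotone non-decreasing).
#' @export
substitution_series <- function(censuses, region = c("peripheral", "limbal"),
                                reference_day) {
  region <- match.arg(region)
  days <- vapply(censuses, `[[`, numeric(1), "day")
  ref_i <- which.min(abs(days - reference_day))
  ref <- censuses[[ref_i]][[region]]
  keep <- seq(ref_i, length(censuses))
  tibble::tibble(
    day = days[keep] - days[ref_i],
    substituted = vapply(keep, function(i)
      1 - length(intersect(ref, censuses[[i]][[region]])) / max(length(ref), 1),
      numeric(1))
  )
}

#' Mean per-layer transit time
#'
#' For every cell with both a birth (division) and a slough event in the
#' log, divides its lifetime by the number of layers it occupied (one plus
#' its differentiation transitions) and averages, in days per layer.
#'
#' @param events An event tibble ([event_table()]).
#' @param day_to_mcs MCS per day.
#' @return A list: `mean_days_per_layer`, `n_trajectories` (NA mean when no
#'   completed trajectory exists).
#' @export
layer_transit_time <- function(events, day_to_mcs = 240) {
  births <- events[events$event == "divide", c("id", "mcs")]
  sloughs <- events[events$event == "slough", c("id", "mcs")]
  if (!nrow(births) || !nrow(sloughs))
    return(list(mean_days_per_layer = NA_real_, n_trajectories = 0L))
  # robust to an id with several birth records: the trajectory starts at the
  # last birth before sloughing
  births <- stats::aggregate(mcs ~ id, births, max)
  done <- merge(births, sloughs, by = "id", suffixes = c("_birth", "_slough"))
  if (!nrow(done)) return(list(mean_days_per_layer = NA_real_, n_trajectories = 0L))
  diffs <- events[events$event == "differentiate", c("id", "mcs")]
  layers <- vapply(seq_len(nrow(done)), function(i) {
    1L + sum(diffs$id == done$id[i] & diffs$mcs > done$mcs_birth[i])
  }, integer(1))
  per <- (done$mcs_slough - done$mcs_birth) / day_to_mcs / layers
  list(mean_days_per_layer = mean(per), n_trajectories = nrow(done))
}

#' First day with a complete stratified structure
#'
#' A sample qualifies when all four epithelial types are present and their
#' mean depths are correctly ordered (stem/basal below wing below
#' superficial).  Returns the first qualifying day.
#'
#' @param metrics A metrics tibble with the per-sample layer depth columns
#'   recorded by [simulate_days()].
#' @return Day (fractional), or `NA_real_`.
#' @export
stratification_day <- function(metrics) {
  ok <- metrics$n_stem > 0 & metrics$n_basal > 0 & metrics$n_wing > 0 &
    metrics$n_super > 0 &
    !is.na(metrics$y_basal) & !is.na(metrics$y_wing) & !is.na(metrics$y_super) &
    metrics$y_basal < metrics$y_wing & metrics$y_wing < metrics$y_super
  if (!any(ok)) return(NA_real_)
  metrics$day[which(ok)[1]]
}

#' First day of stable homeostasis
#'
#' A day qualifies when each per-type daily mean count and the daily mean
#' thickness lie within `band` (default 10%) of their trailing
#' `window`-day mean; homeostasis is declared on the first day ending a run
#' of `window` consecutive qualifying days with all four types present.
#'
#' @param metrics A metrics tibble from [simulate_days()].
#' @param band Relative tolerance.
#' @param window Consecutive qualifying days required.
#' @return Day (integer-valued), or `NA_real_`.
#' @export
homeostasis_day <- function(metrics, band = 0.10, window = 3) {
  m <- metrics[!is.na(metrics$thickness_um), ]
  m$dday <- ceiling(m$day)
  agg <- dplyr::summarise(
    dplyr::group_by(m, .data$dday),
    dplyr::across(c("n_stem", "n_basal", "n_wing", "n_super", "thickness_um"),
                  mean),
    .groups = "drop"
  )
  if (nrow(agg) < window + 1) return(NA_real_)
  series <- c("n_stem", "n_basal", "n_wing", "n_super", "thickness_um")
  okday <- rep(FALSE, nrow(agg))
  for (i in seq_len(nrow(agg))) {
    lo <- which(agg$dday > agg$dday[i] - window & agg$dday <= agg$dday[i])
    if (length(lo) < window) next
    ok <- TRUE
    for (s in series) {
      ref <- mean(agg[[s]][lo])
      if (ref == 0) { ok <- ok && agg[[s]][i] == 0; next }
      if (abs(agg[[s]][i] - ref) / ref > band) { ok <- FALSE; break }
    }
    okday[i] <- ok && all(agg[i, c("n_stem", "n_basal", "n_wing", "n_super")] > 0)
  }
  run <- 0L
  for (i in seq_along(okday)) {
    run <- if (okday[i]) run + 1L else 0L
    if (run >= window) return(agg$dday[i])
  }
  NA_real_
}

#' Healing time after injury
#'
#' The first post-injury day at which the wound-open fraction is zero and
#' the COM thickness lies within `band` of the pre-injury baseline (the mean
#' over the `baseline_days` before injury).  Also counts recurrence events:
#' re-openings (wound-open fraction rising above `reopen_frac`) after a
#' closure.
#'
#' @param metrics A metrics tibble covering the injury.
#' @param injury_mcs MCS of the injury.
#' @param band Relative thickness tolerance.
#' @param baseline_days Days before injury averaged into the baseline.
#' @param reopen_frac Wound-open fraction counting as a re-opening.
#' @return A list: `healing_days` (NA if never healed within the series),
#'   `closure_days` (first surface closure regardless of thickness),
#'   `recurrences`, `baseline_thickness`.
#' @export
healing_time <- function(metrics, injury_mcs, band = 0.10, baseline_days = 3,
                         reopen_frac = 0.05) {
  if (max(metrics$mcs) < injury_mcs)
    stop("metrics series ends before the injury")
  day_to_mcs <- 240
  pre <- metrics[metrics$mcs <= injury_mcs &
                   metrics$mcs > injury_mcs - baseline_days * day_to_mcs, ]
  base <- mean(pre$thickness_um, na.rm = TRUE)
  post <- metrics[metrics$mcs > injury_mcs, ]
  if (!nrow(post))
    return(list(healing_days = NA_real_, closure_days = NA_real_,
                recurrences = 0L, baseline_thickness = base))
  closed <- post$wound_open == 0
  healed <- closed & !is.na(post$thickness_um) &
    abs(post$thickness_um - base) / base <= band
  t_post <- (post$mcs - injury_mcs) / day_to_mcs
  healing_days <- if (any(healed)) t_post[which(healed)[1]] else NA_real_
  closure_days <- if (any(closed)) t_post[which(closed)[1]] else NA_real_
  rec <- 0L
  seen_closed <- FALSE
  for (i in seq_along(closed)) {
    if (closed[i]) seen_closed <- TRUE
    else if (seen_closed && post$wound_open[i] >= reopen_frac) {
      rec <- rec + 1L
      seen_closed <- FALSE
    }
  }
  list(healing_days = healing_days, closure_days = closure_days,
       recurrences = rec, baseline_thickness = base)
}

#' Population stability statistics
#'
#' Per-type mean and standard deviation of counts over a window, plus a
#' Shapiro-Wilk normality p-value when enough samples exist.
#'
#' @param metrics A metrics tibble.
#' @param from_day,to_day Window bounds (days, inclusive).
#' @return A tibble: type, mean, sd, n, shapiro_p.
#' @export
population_stability_stats <- function(metrics, from_day, to_day = Inf) {
  m <- metrics[metrics$day >= from_day & metrics$day <= to_day, ]
  cols <- c(STEM = "n_stem", BASAL = "n_basal", WING = "n_wing", SUPER = "n_super")
  purrr::map_dfr(names(cols), function(tp) {
    v <- m[[cols[[tp]]]]
    sw <- if (length(unique(v)) > 3 && length(v) >= 10 && length(v) <= 5000)
      stats::shapiro.test(v)$p.value else NA_real_
    tibble::tibble(type = tp, mean = mean(v), sd = stats::sd(v),
                   n = length(v), shapiro_p = sw)
  })
}

#' Pooled standard deviation of binned apical position
#'
#' For each x-segment, the per-bin apical-position SD over the window; pooled
#' as the root of the mean per-bin variance.  Quantifies architectural
#' uniformity over time.  The default measure tracks the mean superficial-cell
#' position per segment; `measure = "top"` uses the max-voxel top-position
#' thickness instead.
#'
#' @param metrics A metrics tibble with the binned list-columns.
#' @param from_day,to_day Window bounds.
#' @param bins Which bins to pool (0-based; default: the central bins 4-9).
#' @param measure Per-bin series to pool.
#' @return Pooled SD in micrometers.
#' @export
binned_thickness_sd <- function(metrics, from_day, to_day = Inf, bins = 4:9,
                                measure = c("super_pos", "top")) {
  measure <- match.arg(measure)
  m <- metrics[metrics$day >= from_day & metrics$day <= to_day, ]
  col <- if (measure == "super_pos" && "bin_super_pos" %in% names(m))
    "bin_super_pos" else "bin_thickness"
  bt <- do.call(rbind, m[[col]])   # samples x 10
  v <- apply(bt[, bins + 1, drop = FALSE], 2, stats::var, na.rm = TRUE)
  sqrt(mean(v))
}
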