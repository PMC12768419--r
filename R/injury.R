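# Injury application: circular ablation and chemical exposure.

maybe_apply_injury <- function(sim) {
  spec <- sim$config$injury
  if (is.null(spec) || isTRUE(sim$injury_applied)) return(invisible(sim))
  if (sim$mcs < spec$trigger_mcs) return(invisible(sim))
  if (spec$mode == "ablation") ablate(sim, spec) else apply_chemical(sim, spec)
  sim$injury_applied <- TRUE
  log_event(sim, 0L, paste0("injury_", spec$mode), NA_integer_, NA_integer_)
  invisible(sim)
}

#' Circular ablation
#'
#' Removes every epithelial voxel within `radius` of the center and replaces
#' it with tear film (reflecting increased tear production after trauma).
#' Stroma and walls are untouched; membrane voxels are removed only when the
#' spec requests membrane-depth ablation.  Cells left with no voxels are
#' deregistered.  Idempotent for a fixed circle.
#'
#' @param sim A `cornea_sim`.
#' @param spec An [injury_spec()] with `mode = "ablation"`.
#' @return The sim, invisibly.
#' @export
ablate <- function(sim, spec) {
  W <- sim$W; H <- sim$H
  cx <- spec$center[1]; cy <- spec$center[2]
  if (cx + spec$radius < 0 || cx - spec$radius >= W ||
      cy + spec$radius < 0 || cy - spec$radius >= H)
    stop("ablation circle lies entirely outside the lattice")
  if (spec$radius <= 0) return(invisible(sim))
  idx0 <- seq_len(W * H) - 1L
  x <- idx0 %% W; y <- idx0 %/% W
  inside <- (x - cx)^2 + (y - cy)^2 <= spec$radius^2
  occ <- sim$spin
  types <- ifelse(occ == 0L, 0L, sim$cells$ctype[pmax(occ, 1L)])
  target_types <- EPI_TYPES
  if (isTRUE(spec$ablate_membrane))
    target_types <- c(target_types, CELL_TYPES[c("LIMB", "MEMB")])
  hit <- inside & types %in% target_types
  if (any(hit)) {
    affected <- unique(occ[hit])
    sim$spin[hit] <- sim$tear_id
    refresh_stats(sim)
    cl <- sim$cells
    gone <- affected[cl$volume[affected] == 0 & cl$alive[affected]]
    for (id in gone) {
      cl$alive[id] <- FALSE
      log_event(sim, id, "ablated", cl$ctype[id], NA_integer_)
    }
  }
  invisible(sim)
}

#' Chemical exposure
#'
#' Activates the toxicant field and deposits the dose into the tear film,
#' either as a Gaussian droplet in x (amplitude scaled so the integrated
#' deposit equals `dose`) or uniformly over the tear.  Subsequent spread is
#' handled by the reaction-diffusion solver; cell death and membrane
#' destruction are evaluated against the field each MCS.
#'
#' @param sim A `cornea_sim`.
#' @param spec An [injury_spec()] with `mode = "chemical"`.
#' @return The sim, invisibly.
#' @export
apply_chemical <- function(sim, spec) {
  W <- sim$W
  if (is.null(sim$fields$chem)) sim$fields$chem <- numeric(W * sim$H)
  occ <- sim$spin
  types <- ifelse(occ == 0L, 0L, sim$cells$ctype[pmax(occ, 1L)])
  tear <- which(types == CELL_TYPES[["TEAR"]])
  if (!length(tear)) stop("no tear film to deposit into")
  x <- (tear - 1L) %% W
  w <- switch(spec$profile,
    gaussian = exp(-(x - spec$center[1])^2 / (2 * spec$sigma^2)),
    uniform = rep(1, length(tear)),
    stop("unknown chemical profile: ", spec$profile)
  )
  if (sum(w) == 0) stop("chemical deposit has zero weight inside the tear film")
  sim$fields$chem[tear] <- sim$fields$chem[tear] + spec$dose * w / sum(w)
  invisible(sim)
}

#' Basement-membrane destruction
#'
#' Membrane voxels (central or limbal) whose toxicant concentration exceeds
#' the membrane threshold are permanently converted to stroma: the epithelium
#' above the gap loses its differentiation-maintaining substrate (the
#' membrane does not regenerate).
#'
#' @param sim A `cornea_sim`.
#' @param threshold Concentration threshold (defaults to the injury spec's).
#' @return Number of membrane voxels destroyed.
#' @export
destroy_membrane <- function(sim, threshold = NULL) {
  if (is.null(sim$fields$chem)) return(0L)
  threshold <- threshold %||% sim$config$injury$membrane_threshold
  if (is.null(threshold)) return(0L)
  occ <- sim$spin
  types <- ifelse(occ == 0L, 0L, sim$cells$ctype[pmax(occ, 1L)])
  hit <- which(types %in% CELL_TYPES[c("LIMB", "MEMB")] &
                 sim$fields$chem > threshold)
  if (!length(hit)) return(0L)
  sim$spin[hit] <- sim$stroma_id
  refresh_stats(sim)
  cl <- sim$cells
  for (id in c(sim$limb_id, sim$memb_id)) {
    if (!is.na(id) && cl$alive[id] && cl$volume[id] == 0) cl$alive[id] <- FALSE
  }
  length(hit)
}

# Deactivate the toxicant field once it has decayed to irrelevance.
maybe_retire_chem <- function(sim) {
  spec <- sim$config$injury
  if (is.null(sim$fields$chem) || is.null(spec)) return(invisible(sim))
  if (isTRUE(sim$injury_applied) &&
      max(sim$fields$chem) < 1e-3 * spec$cell_threshold) {
    sim$fields$chem <- NULL
    cl <- sim$cells
    cl$dying[seq_len(cl$n)] <- FALSE
  }
  invisible(sim)
}
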