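# Potts engine: energy evaluation, copy attempts, and the MCS loop.

potts_args <- function(sim) {
  cfg <- sim$config
  cl <- sim$cells
  n <- max(cl$n, 1L)
  J <- contact_energy_table(cfg$potts$contact, cfg$potts$contact_default)
  chemo_cfg <- cfg$chemotaxis
  fnames <- intersect(names(chemo_cfg), names(sim$fields))
  chemo <- matrix(0, nrow = max(length(fnames), 1L), ncol = N_TYPES)
  flds <- list()
  if (length(fnames)) {
    for (k in seq_along(fnames)) {
      lam <- chemo_cfg[[fnames[k]]]
      for (tn in names(lam)) chemo[k, CELL_TYPES[[tn]] + 1L] <- lam[[tn]]
      flds[[k]] <- sim$fields[[fnames[k]]]
    }
  } else flds <- list(numeric(sim$W * sim$H))
  list(
    spin = sim$spin, W = sim$W, H = sim$H,
    ctype = sim$cells$ctype, vol = cl$volume, tvol = cl$tvol,
    surf = cl$surf, tsurf = cl$tsurf, sumx = cl$sumx, sumy = cl$sumy,
    J = J, temperature = cfg$potts$temperature,
    lam_vol = unname(cfg$potts$lambda_volume[names(CELL_TYPES)]),
    lam_surf = unname(cfg$potts$lambda_surface[names(CELL_TYPES)]),
    frozen = as.integer(names(CELL_TYPES) %in% names(FROZEN_TYPES)),
    fields = flds, chemo = chemo,
    links = build_links(sim)
  )
}

# Hookean center-to-center links between adjacent superficial cells: the
# apical sheet's tension term.  Rebuilt every MCS; links to dead cells are
# thereby pruned.  Consecutive SUPER cells (ordered by centroid x) closer
# than max_gap are linked.
build_links <- function(sim) {
  lk <- sim$config$potts$links
  cl <- sim$cells
  ids <- live_ids(sim, CELL_TYPES[["SUPER"]])
  ids <- ids[cl$volume[ids] > 0]
  if (length(ids) < 2)
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("id1", "id2", "k", "L0"))))
  cx <- cl$sumx[ids] / cl$volume[ids]
  cy <- cl$sumy[ids] / cl$volume[ids]
  ord <- order(cx)
  ids <- ids[ord]; cx <- cx[ord]; cy <- cy[ord]
  n <- length(ids)
  d <- sqrt(diff(cx)^2 + diff(cy)^2)
  keep <- d <= lk$max_gap
  cbind(id1 = ids[-n][keep], id2 = ids[-1][keep],
        k = rep(lk$k, sum(keep)), L0 = rep(lk$L0, sum(keep)))
}

#' Energy change of a proposed voxel copy
#'
#' Evaluates `dH = dH_contact + dH_links + dH_volume + dH_surface +
#' dH_chemotaxis` for copying the spin at the source voxel onto the target
#' voxel, without mutating the state.  A frozen target returns `Inf` (the
#' copy is rejected by construction).
#'
#' @param sim A `cornea_sim`.
#' @param source,target Voxel coordinates as `c(x, y)` (0-based) or single
#'   0-based voxel indices.
#' @return The energy change (possibly `Inf`).
#' @export
delta_hamiltonian <- function(sim, source, target) {
  to_idx <- function(v) {
    if (length(v) == 2) {
      if (any(v < 0) || v[1] >= sim$W || v[2] >= sim$H)
        stop("voxel out of bounds")
      v[1] + sim$W * v[2]
    } else as.integer(v)
  }
  a <- to_idx(source); b <- to_idx(target)
  pa <- potts_args(sim)
  cpm_delta_h(pa$spin, pa$W, pa$H, pa$ctype, pa$vol, pa$tvol, pa$surf,
              pa$tsurf, pa$sumx, pa$sumy, pa$J, pa$temperature, pa$lam_vol,
              pa$lam_surf, pa$frozen, pa$fields, pa$chemo, pa$links, a, b)
}

#' Run Monte Carlo steps
#'
#' Advances the simulation by `n` MCS.  Each MCS performs, in order:
#' a full sweep of `W*H` random copy attempts (Metropolis acceptance at the
#' configured temperature); scheduled injury application; field substeps
#' (EGF, movement bias, and the toxicant while active); growth; mitosis;
#' differentiation; sloughing; chemical death; fragment culling.  Identical
#' seeds yield identical trajectories.
#'
#' @param sim A `cornea_sim`.
#' @param n Number of MCS (>= 0).
#' @return The sim, invisibly.
#' @export
run_mcs <- function(sim, n = 1) {
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  cfg <- sim$config
  for (step in seq_len(n)) {
    maybe_apply_injury(sim)

    pa <- potts_args(sim)
    cpm_sweep(pa$spin, pa$W, pa$H, pa$ctype, pa$vol, pa$tvol, pa$surf,
              pa$tsurf, pa$sumx, pa$sumy, pa$J, pa$temperature, pa$lam_vol,
              pa$lam_surf, pa$frozen, pa$fields, pa$chemo, pa$links,
              pa$W * pa$H)

    step_field(sim, "egf", dt = 1)
    if (!is.null(sim$fields$bias)) step_field(sim, "bias", dt = 1)
    if (!is.null(sim$fields$chem)) {
      step_field(sim, "chem", dt = 1)
      destroy_membrane(sim)
      maybe_retire_chem(sim)
    }

    sim$mcs <- sim$mcs + 1L

    apply_growth(sim)
    apply_mitosis(sim)
    cl <- sim$cells
    contacts <- cpm_contacts(sim$spin, sim$W, sim$H, cl$ctype[seq_len(cl$n)],
                             cl$n, N_TYPES, unname(CELL_TYPES[c("LIMB", "MEMB")]))
    apply_differentiation(sim, contacts)
    n_slough <- length(apply_sloughing(sim, contacts))
    n_death <- length(apply_injury_death(sim, contacts))
    # contact census is stale after removals; culling recomputes as needed
    n_cull <- length(cull_fragments(sim, if (n_slough + n_death == 0) contacts else NULL))
  }
  invisible(sim)
}
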