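# Per-cell behavior rules: growth, mitosis, differentiation, sloughing,
# and injury-induced death.

#' Hill factors for growth regulation
#'
#' `egf_growth_factor()` is the activating Hill function of the local EGF
#' concentration, `egf^n / (km^n + egf^n)`; `density_growth_factor()` is the
#' inhibitory Hill function of intracellular pressure,
#' `km^n / (km^n + p^n)`.  Both lie in `[0, 1]`; the exponent (default 4)
#' encodes an ultrasensitive proliferate/quiesce switch.
#'
#' @param egf Mean EGF concentration in the cell (arb. units, >= 0).
#' @param km Half-maximum constant (> 0).
#' @param n Hill exponent.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' egf_growth_factor(3.5, 3.5)     # 0.5 at the midpoint
#' egf_growth_factor(7, 3.5)       # 2401/2551.0625
egf_growth_factor <- function(egf, km, n = 4) {
  if (any(egf < 0)) stop("egf must be >= 0")
  if (any(km <= 0)) stop("km must be > 0")
  egf^n / (km^n + egf^n)
}

#' @rdname egf_growth_factor
#' @param pressure Effective intracellular pressure (arb. units; clamped at 0
#'   upstream).
#' @export
#' @examples
#' density_growth_factor(250, 125) # 1/17
density_growth_factor <- function(pressure, km, n = 4) {
  if (any(km <= 0)) stop("km must be > 0")
  km^n / (km^n + pressure^n)
}

#' Effective pressure from volume deviation
#'
#' The crowding proxy: a cell prevented by its neighbors from reaching its
#' target volume accumulates a positive deviation `V_target - V`; pressure is
#' `max(0, lambda * (V_target - V))`.  Overfilled cells report zero.
#'
#' @param volume Current cell volume (voxels).
#' @param target_volume Target volume (voxels).
#' @param lambda Scale constant linking volume deficit to pressure.
#' @return Pressure, arb. units (>= 0).
#' @export
cell_pressure <- function(volume, target_volume, lambda) {
  pmax(0, lambda * (target_volume - volume))
}

#' Grow proliferative cells for one MCS
#'
#' Adds `delta_i * G_density * G_EGF` to the target volume of every live,
#' non-dying STEM and BASAL cell (growth acts on the target; actual volume
#' follows through the Potts volume constraint).  `delta_i` is calibrated so
#' a fully stimulated, uncrowded cell doubles its target volume (25 to 50
#' voxels) in 80 MCS (8 h).
#'
#' @param sim A `cornea_sim`.
#' @return The sim, invisibly.
#' @export
apply_growth <- function(sim) {
  gp <- sim$config$growth
  cl <- sim$cells
  ids <- live_ids(sim, EPI_TYPES[c("STEM", "BASAL")])
  ids <- ids[!cl$dying[ids]]
  if (!length(ids)) return(invisible(sim))
  egf <- all_cell_means(sim, "egf")[ids]
  km <- ifelse(cl$ctype[ids] == CELL_TYPES[["STEM"]],
               gp$km_egf[["STEM"]], gp$km_egf[["BASAL"]])
  dl <- ifelse(cl$ctype[ids] == CELL_TYPES[["STEM"]],
               gp$delta[["STEM"]], gp$delta[["BASAL"]])
  p <- cell_pressure(cl$volume[ids], cl$tvol[ids], gp$lambda_pressure)
  g <- dl * density_growth_factor(p, gp$km_density, gp$hill_n) *
    egf_growth_factor(pmax(egf, 0), km, gp$hill_n)
  cl$tvol[ids] <- pmin(cl$tvol[ids] + g, gp$tvol_cap)
  maturation_sizes(sim)
  invisible(sim)
}

# Post-mitotic size dynamics: wing cells swell toward their mature size;
# superficial cells condense toward the squame size before sloughing.
maturation_sizes <- function(sim) {
  gp <- sim$config$growth
  cl <- sim$cells
  w <- live_ids(sim, CELL_TYPES[["WING"]])
  w <- w[!cl$dying[w]]
  if (length(w)) {
    # the limbal epithelium is thicker in vivo; its transitional cells are
    # given a larger mature size (calibrated zone factor)
    lim <- sim$config$geometry$limbal_voxels
    cx <- cl$sumx[w] / pmax(cl$volume[w], 1)
    cap <- gp$wing_tvol_max *
      ifelse(cx < 1.2 * lim, gp$limbal_wing_factor, 1)
    cl$tvol[w] <- pmin(cl$tvol[w] + gp$wing_swell_rate, cap)
  }
  s <- live_ids(sim, CELL_TYPES[["SUPER"]])
  s <- s[!cl$dying[s] & cl$tvol[s] > gp$super_tvol]
  if (length(s))
    cl$tvol[s] <- pmax(cl$tvol[s] - gp$super_shrink_rate, gp$super_tvol)
  invisible(sim)
}

# Partition a voxel set by signed distance to a cleavage plane through the
# centroid; ties and parity balanced so daughter volumes differ by <= 1.
split_voxels <- function(vox, angle) {
  cx <- mean(vox[, "x"]); cy <- mean(vox[, "y"])
  d <- cos(angle) * (vox[, "x"] - cx) + sin(angle) * (vox[, "y"] - cy)
  ord <- order(d, vox[, "x"], vox[, "y"])
  n <- nrow(vox)
  half <- n %/% 2
  list(a = ord[seq_len(half)], b = ord[(half + 1):n])
}

#' Volume-triggered mitosis
#'
#' Cells at or above the division volume (50 voxels) split through a plane
#' through their centroid: STEM cells along a vertical plane (the high-x
#' daughter lies centripetally and, once off the limbal membrane, commits via
#' the stem-to-basal rule); BASAL cells at a uniformly random plane angle.
#' The parent's voxels are distributed equally (within one voxel) between two
#' daughter cells with fresh ids and birth stamps (division consumes the
#' parent), both with target volume reset to the initial 25 voxels.
#'
#' @param sim A `cornea_sim`.
#' @return Integer vector of daughter ids created this call.
#' @export
apply_mitosis <- function(sim) {
  gp <- sim$config$growth
  cl <- sim$cells
  ids <- live_ids(sim, EPI_TYPES[c("STEM", "BASAL")])
  ids <- ids[!cl$dying[ids] & cl$volume[ids] >= gp$divide_volume]
  out <- integer(0)
  for (id in ids) {
    vox <- voxels_of(sim, id)
    if (nrow(vox) < 2) next
    # STEM: vertical cleavage plane, daughters side by side, the high-x one
    # placed centripetally; BASAL: uniformly random plane angle
    angle <- if (cl$ctype[id] == CELL_TYPES[["STEM"]]) 0 else runif(1, 0, pi)
    parts <- split_voxels(vox, angle)
    d1 <- register_cell(sim, cl$ctype[id], tvol = gp$init_volume)
    d2 <- register_cell(sim, cl$ctype[id], tvol = gp$init_volume)
    paint_voxels(sim, d1, vox[parts$a, "x"], vox[parts$a, "y"])
    paint_voxels(sim, d2, vox[parts$b, "x"], vox[parts$b, "y"])
    cl$alive[id] <- FALSE
    cl$volume[id] <- 0; cl$sumx[id] <- 0; cl$sumy[id] <- 0; cl$surf[id] <- 0
    log_event(sim, d1, "divide", cl$ctype[id], cl$ctype[id])
    log_event(sim, d2, "divide", cl$ctype[id], cl$ctype[id])
    out <- c(out, d1, d2)
  }
  if (length(out)) refresh_stats(sim)
  out
}

#' Contact-triggered differentiation
#'
#' Applies the three deterministic transition rules, at most one per cell per
#' MCS, to cells born before this MCS:
#' * STEM -> BASAL when the limbal membrane (`LIMB`) is absent from the
#'   cell's neighbor set;
#' * BASAL -> WING when the cell's face-contact area with the basement
#'   membrane falls to 5 voxels or fewer;
#' * WING -> SUPER when the cell touches both the tear film and another wing
#'   cell while touching none of BASAL, MEMB, STEM.
#'
#' Transitions are logged and increment the cell's layer-transit counter.
#'
#' @param sim A `cornea_sim`.
#' @param contacts Optional precomputed result of the internal contact
#'   census (engine use).
#' @return Integer vector of ids that changed type.
#' @export
apply_differentiation <- function(sim, contacts = NULL) {
  cl <- sim$cells
  if (cl$n == 0L) return(integer(0))
  if (is.null(contacts))
    contacts <- cpm_contacts(sim$spin, sim$W, sim$H,
                             cl$ctype[seq_len(cl$n)], cl$n, N_TYPES,
                             unname(CELL_TYPES[c("LIMB", "MEMB")]))
  nb <- contacts$neighbor_counts
  epbm <- contacts$epbm_area
  changed <- integer(0)
  ids <- live_ids(sim, EPI_TYPES)
  ids <- ids[cl$birth[ids] < sim$mcs & !cl$dying[ids]]
  has <- function(i, tn) nb[i, CELL_TYPES[[tn]] + 1L] > 0L
  for (id in ids) {
    tp <- cl$ctype[id]
    new <- NA_integer_
    if (tp == CELL_TYPES[["STEM"]]) {
      if (!has(id, "LIMB")) new <- CELL_TYPES[["BASAL"]]
    } else if (tp == CELL_TYPES[["BASAL"]]) {
      if (epbm[id] <= sim$config$differentiation$epbm_contact_max)
        new <- CELL_TYPES[["WING"]]
    } else if (tp == CELL_TYPES[["WING"]]) {
      if (has(id, "TEAR") && has(id, "WING") &&
          !has(id, "BASAL") && !has(id, "MEMB") && !has(id, "STEM"))
        new <- CELL_TYPES[["SUPER"]]
    }
    if (!is.na(new)) {
      log_event(sim, id, "differentiate", tp, new)
      cl$ctype[id] <- new
      cl$ndiff[id] <- cl$ndiff[id] + 1L
      if (new %in% CELL_TYPES[c("WING", "SUPER")]) {
        # non-proliferative from here on; size follows maturation dynamics
        cl$tvol[id] <- cl$volume[id]
      }
      changed <- c(changed, id)
    }
  }
  changed
}

#' Probabilistic sloughing of superficial cells
#'
#' Each superficial cell in contact with the tear film is removed with
#' per-MCS probability `1 / (lifetime_days * day_to_mcs)` (1/720 at the
#' defaults: a 3-day mean exposed lifetime).  Removed voxels join the tear
#' film.  Superficial cells not touching tear never slough.
#'
#' @inheritParams apply_differentiation
#' @return Integer vector of sloughed ids.
#' @export
apply_sloughing <- function(sim, contacts = NULL) {
  cl <- sim$cells
  ids <- live_ids(sim, CELL_TYPES[["SUPER"]])
  ids <- ids[cl$birth[ids] < sim$mcs]
  if (!length(ids)) return(integer(0))
  if (is.null(contacts))
    contacts <- cpm_contacts(sim$spin, sim$W, sim$H,
                             cl$ctype[seq_len(cl$n)], cl$n, N_TYPES,
                             unname(CELL_TYPES[c("LIMB", "MEMB")]))
  touching <- contacts$neighbor_counts[ids, CELL_TYPES[["TEAR"]] + 1L] > 0L
  ids <- ids[touching]
  if (!length(ids)) return(integer(0))
  p <- slough_probability(sim$config$slough)
  gone <- ids[runif(length(ids)) < p]
  for (id in gone) remove_cell(sim, id, "slough", to = sim$tear_id)
  if (length(gone)) refresh_stats(sim)
  gone
}

#' @rdname apply_sloughing
#' @param slough The `slough` section of a config.
#' @export
slough_probability <- function(slough) {
  1 / (slough$lifetime_days * slough$day_to_mcs)
}

# Convert a cell's voxels to another agent (tear or medium) and drop it.
remove_cell <- function(sim, id, event, to = 0L) {
  cl <- sim$cells
  idx <- which(sim$spin == id)
  sim$spin[idx] <- as.integer(to)
  cl$alive[id] <- FALSE; cl$dying[id] <- FALSE
  cl$volume[id] <- 0; cl$sumx[id] <- 0; cl$sumy[id] <- 0; cl$surf[id] <- 0
  log_event(sim, id, event, cl$ctype[id], NA_integer_)
  invisible(sim)
}

#' Chemical-injury cell death
#'
#' Marks epithelial cells dying when their mean toxicant concentration
#' exceeds the cell threshold; each subsequent MCS a dying cell's target
#' volume drops by the configured rate, and once the Potts dynamics have
#' shrunk it below 3 voxels it is removed (its voxels join the tear film if
#' exposed to it, otherwise become medium).
#'
#' @inheritParams apply_differentiation
#' @return Integer vector of ids removed this MCS.
#' @export
apply_injury_death <- function(sim, contacts = NULL) {
  spec <- sim$config$injury
  if (is.null(spec) || is.null(sim$fields$chem)) return(integer(0))
  cl <- sim$cells
  ids <- live_ids(sim, EPI_TYPES)
  if (length(ids)) {
    chem <- all_cell_means(sim, "chem")[ids]
    newly <- ids[!cl$dying[ids] & chem > spec$cell_threshold]
    cl$dying[newly] <- TRUE
  }
  dying <- live_ids(sim, EPI_TYPES)
  dying <- dying[cl$dying[dying]]
  removed <- integer(0)
  if (length(dying)) {
    cl$tvol[dying] <- pmax(0, cl$tvol[dying] - spec$death_rate)
    done <- dying[cl$volume[dying] < 3]
    if (length(done)) {
      if (is.null(contacts))
        contacts <- cpm_contacts(sim$spin, sim$W, sim$H,
                                 cl$ctype[seq_len(cl$n)], cl$n, N_TYPES,
                                 unname(CELL_TYPES[c("LIMB", "MEMB")]))
      for (id in done) {
        to <- if (contacts$neighbor_counts[id, CELL_TYPES[["TEAR"]] + 1L] > 0L)
          sim$tear_id else 0L
        remove_cell(sim, id, "chem_death", to = to)
      }
      refresh_stats(sim)
      removed <- done
    }
  }
  removed
}

# Orphan-fragment control: connectivity is not enforced, but cells whose
# total volume falls below 3 voxels are culled (their voxels become medium,
# or tear when the cell still touches it).
cull_fragments <- function(sim, contacts = NULL) {
  cl <- sim$cells
  ids <- live_ids(sim, EPI_TYPES)
  tiny <- ids[cl$volume[ids] < 3]
  if (!length(tiny)) return(integer(0))
  if (is.null(contacts))
    contacts <- cpm_contacts(sim$spin, sim$W, sim$H,
                             cl$ctype[seq_len(cl$n)], cl$n, N_TYPES,
                             unname(CELL_TYPES[c("LIMB", "MEMB")]))
  for (id in tiny) {
    to <- if (!is.na(sim$tear_id) &&
              contacts$neighbor_counts[id, CELL_TYPES[["TEAR"]] + 1L] > 0L)
      sim$tear_id else 0L
    remove_cell(sim, id, "cull", to = to)
  }
  refresh_stats(sim)
  tiny
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change `dH` outright when `dH <= 0`, otherwise with
#' Boltzmann probability `exp(-dH / temperature)`.  Vectorized; one uniform
#' draw per element.
#'
#' @param dH Energy changes.
#' @param temperature Potts temperature (> 0).
#' @return Logical vector of acceptance decisions.
#' @export
metropolis_rule <- function(dH, temperature) {
  dH <= 0 | runif(length(dH)) < exp(-dH / temperature)
}
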