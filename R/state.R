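# Simulation state container.
#
# A `cornea_sim` is an environment holding the lattice (`spin`, integer vector
# of cell ids, voxel (x, y) at index x + W*(y-0) + 1 with 0-based x, y and
# y = 0 the bottom row), the cell registry (id-indexed vectors), the scalar
# fields, the parameter set and the event log.  Mutated in place by the
# engine; `snapshot_state()` deep-copies it into a plain list.

INIT_CAPACITY <- 512L

new_sim_env <- function(W, H, cfg) {
  sim <- new.env(parent = emptyenv())
  sim$W <- as.integer(W); sim$H <- as.integer(H)
  sim$spin <- integer(W * H)
  sim$mcs <- 0L
  sim$config <- cfg
  cl <- new.env(parent = emptyenv())
  n <- INIT_CAPACITY
  cl$ctype <- integer(n); cl$volume <- numeric(n); cl$tvol <- numeric(n)
  cl$surf <- numeric(n); cl$tsurf <- numeric(n)
  cl$sumx <- numeric(n); cl$sumy <- numeric(n)
  cl$birth <- integer(n); cl$ndiff <- integer(n)
  cl$alive <- logical(n); cl$dying <- logical(n)
  cl$n <- 0L
  sim$cells <- cl
  sim$fields <- list()
  ev <- new.env(parent = emptyenv())
  ev$mcs <- integer(0); ev$id <- integer(0); ev$event <- character(0)
  ev$old_type <- character(0); ev$new_type <- character(0)
  sim$events <- ev
  class(sim) <- c("cornea_sim", "environment")
  sim
}

grow_registry <- function(cl, need) {
  cap <- length(cl$ctype)
  if (need <= cap) return(invisible())
  newcap <- max(need, 2L * cap)
  pad_i <- function(v) c(v, integer(newcap - cap))
  pad_d <- function(v) c(v, numeric(newcap - cap))
  pad_l <- function(v) c(v, logical(newcap - cap))
  cl$ctype <- pad_i(cl$ctype); cl$birth <- pad_i(cl$birth); cl$ndiff <- pad_i(cl$ndiff)
  cl$volume <- pad_d(cl$volume); cl$tvol <- pad_d(cl$tvol)
  cl$surf <- pad_d(cl$surf); cl$tsurf <- pad_d(cl$tsurf)
  cl$sumx <- pad_d(cl$sumx); cl$sumy <- pad_d(cl$sumy)
  cl$alive <- pad_l(cl$alive); cl$dying <- pad_l(cl$dying)
  invisible()
}

register_cell <- function(sim, type, tvol = NA_real_, tsurf = 0, birth = sim$mcs) {
  cl <- sim$cells
  id <- cl$n + 1L
  grow_registry(cl, id)
  cl$n <- id
  cl$ctype[id] <- as.integer(type)
  cl$volume[id] <- 0; cl$tvol[id] <- if (is.na(tvol)) 0 else tvol
  cl$surf[id] <- 0; cl$tsurf[id] <- tsurf
  cl$sumx[id] <- 0; cl$sumy[id] <- 0
  cl$birth[id] <- as.integer(birth); cl$ndiff[id] <- 0L
  cl$alive[id] <- TRUE; cl$dying[id] <- FALSE
  id
}

# Assign a rectangular or arbitrary voxel set to a cell id (builder-time only;
# callers must refresh_stats() before running dynamics).
paint_voxels <- function(sim, id, x, y) {
  stopifnot(all(x >= 0), all(x < sim$W), all(y >= 0), all(y < sim$H))
  sim$spin[x + sim$W * y + 1L] <- as.integer(id)
  invisible(sim)
}

voxels_of <- function(sim, id) {
  idx <- which(sim$spin == id) - 1L
  cbind(x = idx %% sim$W, y = idx %/% sim$W)
}

# Recompute volume/centroid/surface bookkeeping for every cell from the grid.
refresh_stats <- function(sim) {
  cl <- sim$cells
  if (cl$n == 0L) return(invisible(sim))
  rc <- cpm_recount(sim$spin, sim$W, sim$H, cl$n)
  ix <- seq_len(cl$n)
  cl$volume[ix] <- rc$volume
  cl$sumx[ix] <- rc$sum_x; cl$sumy[ix] <- rc$sum_y
  cl$surf[ix] <- rc$surface
  invisible(sim)
}

log_event <- function(sim, id, event, old_type = NA_integer_, new_type = NA_integer_) {
  ev <- sim$events
  k <- length(ev$mcs) + 1L
  ev$mcs[k] <- sim$mcs; ev$id[k] <- as.integer(id); ev$event[k] <- event
  ev$old_type[k] <- if (is.na(old_type)) NA_character_ else type_name(old_type)
  ev$new_type[k] <- if (is.na(new_type)) NA_character_ else type_name(new_type)
  invisible(sim)
}

live_ids <- function(sim, types = NULL) {
  cl <- sim$cells
  ix <- which(cl$alive[seq_len(cl$n)])
  if (!is.null(types)) ix <- ix[cl$ctype[ix] %in% types]
  ix
}

#' Tidy view of the cell registry
#'
#' @param sim A `cornea_sim`.
#' @param alive_only Drop dead cells.
#' @return A tibble with one row per cell: id, type, volume, target volume,
#'   surface, centroid (voxels), birth MCS, differentiation count, flags.
#' @export
cell_table <- function(sim, alive_only = TRUE) {
  cl <- sim$cells
  ix <- if (alive_only) live_ids(sim) else seq_len(cl$n)
  tibble::tibble(
    id = ix,
    type = type_name(cl$ctype[ix]),
    volume = cl$volume[ix],
    target_volume = cl$tvol[ix],
    surface = cl$surf[ix],
    target_surface = cl$tsurf[ix],
    x = ifelse(cl$volume[ix] > 0, cl$sumx[ix] / cl$volume[ix], NA_real_),
    y = ifelse(cl$volume[ix] > 0, cl$sumy[ix] / cl$volume[ix], NA_real_),
    birth_mcs = cl$birth[ix],
    n_transitions = cl$ndiff[ix],
    alive = cl$alive[ix],
    dying = cl$dying[ix]
  )
}

#' Event log as a tibble
#'
#' One row per discrete cell event: `divide` (one row per daughter),
#' `differentiate`, `slough`, `chem_death`, `ablated`, `cull`.
#'
#' @param sim A `cornea_sim` (or a `cornea_run`).
#' @return A tibble with columns mcs, id, event, old_type, new_type.
#' @export
event_table <- function(sim) {
  ev <- if (inherits(sim, "cornea_run")) sim$events else {
    e <- sim$events
    tibble::tibble(mcs = e$mcs, id = e$id, event = e$event,
                   old_type = e$old_type, new_type = e$new_type)
  }
  ev
}

#' Deep-copy a simulation state
#'
#' Captures everything needed to resume a run: lattice, registry, fields,
#' counters and the RNG state.  The companion `restore_state()` rebuilds a
#' live `cornea_sim` from the list (the RNG state is restored too, so a
#' resumed trajectory continues deterministically).
#'
#' @param sim A `cornea_sim`.
#' @return A plain list (serializable with `saveRDS` or kept in memory).
#' @export
snapshot_state <- function(sim) {
  cl <- sim$cells
  n <- cl$n
  ix <- seq_len(n)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) runif(1)
  list(
    W = sim$W, H = sim$H, spin = sim$spin + 0L, mcs = sim$mcs,
    config = sim$config,
    cells = list(ctype = cl$ctype[ix], volume = cl$volume[ix], tvol = cl$tvol[ix],
                 surf = cl$surf[ix], tsurf = cl$tsurf[ix],
                 sumx = cl$sumx[ix], sumy = cl$sumy[ix],
                 birth = cl$birth[ix], ndiff = cl$ndiff[ix],
                 alive = cl$alive[ix], dying = cl$dying[ix]),
    fields = lapply(sim$fields, function(f) f + 0),
    special = list(tear = sim$tear_id, limb = sim$limb_id, memb = sim$memb_id,
                   stroma = sim$stroma_id, wall = sim$wall_id),
    events = list(mcs = sim$events$mcs, id = sim$events$id,
                  event = sim$events$event, old_type = sim$events$old_type,
                  new_type = sim$events$new_type),
    injury_applied = isTRUE(sim$injury_applied),
    rng = get(".Random.seed", globalenv())
  )
}

#' @rdname snapshot_state
#' @param snap A list produced by `snapshot_state()`.
#' @export
restore_state <- function(snap) {
  sim <- new_sim_env(snap$W, snap$H, snap$config)
  sim$spin <- snap$spin + 0L
  sim$mcs <- snap$mcs
  cl <- sim$cells
  n <- length(snap$cells$ctype)
  grow_registry(cl, n)
  ix <- seq_len(n)
  cl$ctype[ix] <- snap$cells$ctype; cl$volume[ix] <- snap$cells$volume
  cl$tvol[ix] <- snap$cells$tvol; cl$surf[ix] <- snap$cells$surf
  cl$tsurf[ix] <- snap$cells$tsurf
  cl$sumx[ix] <- snap$cells$sumx; cl$sumy[ix] <- snap$cells$sumy
  cl$birth[ix] <- snap$cells$birth; cl$ndiff[ix] <- snap$cells$ndiff
  cl$alive[ix] <- snap$cells$alive; cl$dying[ix] <- snap$cells$dying
  cl$n <- n
  sim$fields <- lapply(snap$fields, function(f) f + 0)
  sim$tear_id <- snap$special$tear; sim$limb_id <- snap$special$limb
  sim$memb_id <- snap$special$memb; sim$stroma_id <- snap$special$stroma
  sim$wall_id <- snap$special$wall
  sim$events$mcs <- snap$events$mcs; sim$events$id <- snap$events$id
  sim$events$event <- snap$events$event
  sim$events$old_type <- snap$events$old_type
  sim$events$new_type <- snap$events$new_type
  sim$injury_applied <- snap$injury_applied
  assign(".Random.seed", snap$rng, envir = globalenv())
  sim
}

#' @export
print.cornea_sim <- function(x, ...) {
  ct <- table(type_name(x$cells$ctype[live_ids(x)]))
  cat("<cornea_sim> ", x$W, "x", x$H, " voxels, MCS ", x$mcs,
      " (day ", round(x$mcs / x$config$slough$day_to_mcs, 2), ")\n", sep = "")
  cat("  live cells:", paste(names(ct), ct, sep = "=", collapse = " "), "\n")
  invisible(x)
}
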