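# Day-0 tissue construction and small fixture states.

#' Build the initial tissue state
#'
#' Constructs the day-0 configuration: frozen wall columns at both lateral
#' extremes, a frozen stromal slab at the bottom, a one-voxel basement
#' membrane on top of it (limbal zone `LIMB` at low x, central `MEMB`
#' elsewhere), limbal stem cells (25 voxels each) seeded in contact with the
#' limbal membrane, a deformable tear-film agent draped over the surface, and
#' medium (air) above.  The EGF field starts at zero with the tear source
#' active; the movement-bias field likewise.
#'
#' @param cfg A validated `cornea_config`.
#' @return A `cornea_sim` ready for [run_mcs()].
#' @export
#' @examples
#' sim <- build_initial_state(default_config(days = 0))
#' sim
build_initial_state <- function(cfg = default_config()) {
  validate_config(cfg)
  g <- cfg$geometry
  W <- g$width; H <- g$height
  sim <- new_sim_env(W, H, cfg)

  mem_row <- g$stroma_depth                   # y of the membrane strip
  if (mem_row + 10 > H) stop("geometry: lattice too shallow for the stroma depth")

  # frozen substrate agents
  sim$wall_id <- register_cell(sim, CELL_TYPES["WALL"])
  sim$stroma_id <- register_cell(sim, CELL_TYPES["STROMA"])
  sim$limb_id <- register_cell(sim, CELL_TYPES["LIMB"])
  sim$memb_id <- register_cell(sim, CELL_TYPES["MEMB"])

  ally <- 0:(H - 1)
  paint_voxels(sim, sim$wall_id, rep(0L, H), ally)
  paint_voxels(sim, sim$wall_id, rep(W - 1L, H), ally)
  sx <- rep(1:(W - 2), each = mem_row)
  sy <- rep(0:(mem_row - 1), W - 2)
  paint_voxels(sim, sim$stroma_id, sx, sy)
  limb_x <- 1:(g$limbal_voxels - 1)
  memb_x <- g$limbal_voxels:(W - 2)
  paint_voxels(sim, sim$limb_id, limb_x, rep(mem_row, length(limb_x)))
  paint_voxels(sim, sim$memb_id, memb_x, rep(mem_row, length(memb_x)))

  # stem seeds tiling the limbal membrane
  sz <- g$stem_size
  for (k in seq_len(g$stem_count)) {
    id <- register_cell(sim, CELL_TYPES["STEM"], tvol = cfg$growth$init_volume)
    x0 <- 1L + (k - 1L) * sz
    xs <- rep(x0:(x0 + sz - 1L), each = sz)
    ys <- rep((mem_row + 1L):(mem_row + sz), sz)
    paint_voxels(sim, id, xs, ys)
  }

  if (isTRUE(g$seed_basal)) {
    # optional pre-seeded basal cells on the central membrane
    n_basal <- (W - 2L - g$limbal_voxels) %/% sz
    for (k in seq_len(n_basal)) {
      id <- register_cell(sim, CELL_TYPES["BASAL"], tvol = cfg$growth$init_volume)
      x0 <- g$limbal_voxels + (k - 1L) * sz
      xs <- rep(x0:(x0 + sz - 1L), each = sz)
      ys <- rep((mem_row + 1L):(mem_row + sz), sz)
      paint_voxels(sim, id, xs, ys)
    }
  }

  # tear film: fills the first tear_rows above the membrane wherever no cell
  # sits, so it wets both the seeded cells and the bare membrane
  sim$tear_id <- register_cell(sim, CELL_TYPES["TEAR"])
  tx <- rep(1:(W - 2), each = g$tear_rows)
  ty <- rep((mem_row + 1L):(mem_row + g$tear_rows), W - 2)
  ti <- tx + W * ty + 1L
  free <- sim$spin[ti] == 0L
  sim$spin[ti[free]] <- sim$tear_id
  sim$cells$tvol[sim$tear_id] <- sum(free)

  refresh_stats(sim)
  # target volumes for frozen agents track their painted size (inert anyway)
  for (id in c(sim$wall_id, sim$stroma_id, sim$limb_id, sim$memb_id))
    sim$cells$tvol[id] <- sim$cells$volume[id]

  sim$fields <- list(egf = numeric(W * H), bias = numeric(W * H))
  sim$injury_applied <- FALSE
  sim
}

# ---- fixture builders (unit tests, CLI `fixtures` subcommand) --------------

#' Hand-buildable lattice states
#'
#' `empty_state()` makes a bare lattice with no agents (all medium) and the
#' given parameters; `add_cell()` registers a cell and paints a voxel set.
#' These are the fixture generators used throughout the unit tests to build
#' small hand-checkable configurations.
#'
#' @param W,H Lattice dimensions in voxels.
#' @param cfg Optional config (defaults to `default_config()` with geometry
#'   overridden).
#' @return A `cornea_sim`.
#' @export
empty_state <- function(W, H, cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- default_config(days = 0)
    cfg$geometry$width <- as.integer(W); cfg$geometry$height <- as.integer(H)
  }
  sim <- new_sim_env(W, H, cfg)
  sim$tear_id <- NA_integer_; sim$limb_id <- NA_integer_
  sim$memb_id <- NA_integer_; sim$stroma_id <- NA_integer_
  sim$wall_id <- NA_integer_
  sim$fields <- list(egf = numeric(W * H), bias = numeric(W * H))
  sim$injury_applied <- FALSE
  sim
}

#' @rdname empty_state
#' @param sim A `cornea_sim`.
#' @param type Cell type (name or code).
#' @param x,y 0-based voxel coordinates of the cell's voxels.
#' @param tvol Target volume (defaults to the painted volume).
#' @param tsurf Target surface.
#' @return The new cell id.
#' @export
add_cell <- function(sim, type, x, y, tvol = NULL, tsurf = 0) {
  code <- if (is.character(type)) CELL_TYPES[[type]] else as.integer(type)
  id <- register_cell(sim, code, tsurf = tsurf)
  paint_voxels(sim, id, as.integer(x), as.integer(y))
  refresh_stats(sim)
  sim$cells$tvol[id] <- if (is.null(tvol)) sim$cells$volume[id] else tvol
  if (code == CELL_TYPES[["TEAR"]] && is.na(sim$tear_id)) sim$tear_id <- id
  id
}
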