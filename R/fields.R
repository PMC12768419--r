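# Scalar-field (reaction-diffusion) interface.
#
# Each field evolves by dc/dt = D(x,y) grad^2 c - kd c + sources, with D read
# from the cell type occupying each voxel (Eq-level behavior: the superficial
# layer and the central membrane are low-D barriers, the limbal membrane
# blocks transport entirely).  Concentrations are arbitrary units on the
# scale set by the tear-film source.

field_source_voxels <- function(sim, name) {
  if (name == "egf") {
    occ <- sim$spin
    types <- ifelse(occ == 0L, 0L, sim$cells$ctype[pmax(occ, 1L)])
    return(which(occ > 0L & types == CELL_TYPES[["TEAR"]]) - 1L)
  }
  if (name == "bias") {
    g <- sim$config$geometry
    ylo <- min(g$stroma_depth + 1L, sim$H - 2L)
    ys <- ylo:(sim$H - 2L)
    xs <- intersect(c(1L, 2L), 0:(sim$W - 1L))
    return(as.integer(outer(xs, ys, function(x, y) x + sim$W * y)))
  }
  integer(0)
}

#' Advance a scalar field by one engine step
#'
#' Steps the named field over `dt` MCS with the configured scheme:
#' `"implicit"` (operator-split: exact exponential decay plus unconditionally
#' stable backward-Euler diffusion sweeps) or `"ftcs"` (forward-time
#' central-space with the substep count needed for stability).  Both use
#' harmonic-mean interface diffusivities so flux is conserved across material
#' boundaries, and both re-clamp source voxels after every substep.
#'
#' @param sim A `cornea_sim`.
#' @param name Field name (`"egf"`, `"bias"`, `"chem"`).
#' @param dt Time step in MCS.
#' @param scheme Override the configured scheme.
#' @param nsub Override the configured substep count.  For FTCS the stability
#'   requirement is `nsub > 4 * max(D) * dt`; the default uses
#'   `ceiling(4 * max(D) * dt) + 1`.
#' @return The sim, invisibly (field updated in place).
#' @export
step_field <- function(sim, name, dt = 1, scheme = NULL, nsub = NULL) {
  fp <- sim$config$fields[[name]]
  if (is.null(fp)) stop("unknown field: ", name)
  if (is.null(sim$fields[[name]])) stop("field not initialized: ", name)
  scheme <- scheme %||% fp$scheme
  D <- unname(fp$D_by_type[names(CELL_TYPES)])
  src <- field_source_voxels(sim, name)
  if (is.null(nsub)) {
    nsub <- if (scheme == "ftcs") as.integer(ceiling(4 * max(D) * dt)) + 1L
            else max(1L, as.integer(ceiling(fp$nsub * dt)))
  }
  ct <- sim$cells$ctype
  if (sim$cells$n == 0L) ct <- integer(1)
  kd <- if (length(fp$kd) > 1) unname(fp$kd[names(CELL_TYPES)]) else unname(fp$kd)
  if (scheme == "implicit") {
    field_step_implicit(sim$fields[[name]], sim$spin, ct, sim$W, sim$H,
                        D, kd, dt, nsub, src, fp$source_value,
                        isTRUE(fp$dirichlet_tb))
  } else if (scheme == "ftcs") {
    field_step_ftcs(sim$fields[[name]], sim$spin, ct, sim$W, sim$H,
                    D, kd, dt, nsub, src, fp$source_value,
                    isTRUE(fp$dirichlet_tb))
  } else stop("unknown scheme: ", scheme)
  if (min(sim$fields[[name]]) < 0)
    stop("field step produced a negative concentration (solver instability)")
  invisible(sim)
}

#' Clamp the tear-film source region of a field
#'
#' Sets every tear voxel of the named field to the fixed source value
#' (continuous lacrimal replenishment).  Voxels that become tear after an
#' injury are clamped from the next step onward.
#'
#' @inheritParams step_field
#' @export
apply_source <- function(sim, name = "egf") {
  fp <- sim$config$fields[[name]]
  src <- field_source_voxels(sim, name)
  if (length(src)) sim$fields[[name]][src + 1L] <- fp$source_value
  invisible(sim)
}

#' Mean concentration over a cell's voxels
#'
#' @param sim A `cornea_sim`.
#' @param name Field name.
#' @param cell_id Cell id (must be a registered live cell with volume >= 1).
#' @return Arithmetic mean concentration (arb. units).
#' @export
cell_mean_concentration <- function(sim, name, cell_id) {
  cl <- sim$cells
  if (cell_id < 1 || cell_id > cl$n || !cl$alive[cell_id] || cl$volume[cell_id] < 1)
    stop("unknown or empty cell id: ", cell_id)
  idx <- which(sim$spin == cell_id)
  mean(sim$fields[[name]][idx])
}

# Mean field value for every live cell (vectorized engine path).
all_cell_means <- function(sim, name) {
  cl <- sim$cells
  if (cl$n == 0L) return(numeric(0))
  s <- cpm_field_sums(sim$fields[[name]], sim$spin, cl$n)
  out <- rep(NA_real_, cl$n)
  ok <- cl$volume[seq_len(cl$n)] > 0
  out[ok] <- s[ok] / cl$volume[seq_len(cl$n)][ok]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
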