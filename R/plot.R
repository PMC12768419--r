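# Rendering: lattice rasters, field heatmaps, run trajectories, exports.

#' Type palette for lattice renderings
#'
#' Colors approximate the conventional histology-style rendering: stroma
#' lilac, membrane pink/magenta, stem rose-red, basal peach, wing blue,
#' superficial cyan, tear green, medium black.
#'
#' @return Named character vector of hex colors by type name.
#' @export
type_palette <- function() {
  c(MEDIUM = "#000000", STEM = "#E75480", BASAL = "#F5A26F", WING = "#3B6FD4",
    SUPER = "#39C5CF", TEAR = "#3DBE4E", LIMB = "#F8A8C8", MEMB = "#C72B8E",
    STROMA = "#B89FD9", WALL = "#666666")
}

#' Lattice state as a tidy voxel table
#'
#' @param sim A `cornea_sim`.
#' @return A tibble: x, y (0-based voxels), cell_id, type.
#' @export
state_table <- function(sim) {
  idx0 <- seq_len(sim$W * sim$H) - 1L
  types <- occupancy_types(sim)
  tibble::tibble(x = idx0 %% sim$W, y = idx0 %/% sim$W,
                 cell_id = sim$spin, type = type_name(types))
}

#' Plot the lattice state
#'
#' @param object A `cornea_sim`.
#' @param ... Unused.
#' @return A ggplot raster of the lattice colored by cell type.
#' @export
autoplot.cornea_sim <- function(object, ...) {
  df <- state_table(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$type)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = type_palette(), name = NULL) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (voxels; limbus at left)", y = "y (voxels)") +
    ggplot2::theme_minimal()
}

#' Plot a scalar field
#'
#' @param sim A `cornea_sim`.
#' @param name Field name.
#' @param normalize Rescale to `[0, 1]` for display.
#' @return A ggplot heatmap (blue = 0 to red = max).
#' @export
plot_field <- function(sim, name = "egf", normalize = TRUE) {
  f <- sim$fields[[name]]
  if (is.null(f)) stop("field not initialized: ", name)
  if (normalize && max(f) > 0) f <- f / max(f)
  idx0 <- seq_along(f) - 1L
  df <- tibble::tibble(x = idx0 %% sim$W, y = idx0 %/% sim$W, c = f)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colors = c("#2166AC", "#F7F7F7", "#B2182B"),
                                  name = name) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' Plot a run's cell-count trajectories
#'
#' @param object A `cornea_run`.
#' @param ... Unused.
#' @return A ggplot of per-type counts (and thickness) over simulated days.
#' @export
autoplot.cornea_run <- function(object, ...) {
  long <- tidy(object)
  pal <- c(STEM = "#E75480", BASAL = "#F5A26F", WING = "#3B6FD4",
           SUPER = "#39C5CF")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$count,
                                     color = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = pal, name = NULL) +
    ggplot2::labs(x = "simulated day", y = "cell count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export a state snapshot to file
#'
#' Writes the lattice (`kind = "png"` via the type palette, `kind = "vtk"`
#' as legacy VTK structured points with the type code per voxel, `kind =
#' "csv"` as the cell registry) or a field heatmap (`kind = "field_png"`,
#' `kind = "field_csv"`).
#'
#' @param sim A `cornea_sim`.
#' @param path Output file path.
#' @param kind One of `"png"`, `"vtk"`, `"csv"`, `"field_png"`,
#'   `"field_csv"`.
#' @param field Field name for the field kinds.
#' @return The path, invisibly.
#' @export
snapshot <- function(sim, path, kind = c("png", "vtk", "csv", "field_png",
                                         "field_csv"), field = "egf") {
  kind <- match.arg(kind)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (kind == "png") {
    grDevices::png(path, width = 5 * sim$W, height = 5 * sim$H, res = 150)
    print(autoplot.cornea_sim(sim))
    grDevices::dev.off()
  } else if (kind == "field_png") {
    grDevices::png(path, width = 5 * sim$W, height = 5 * sim$H, res = 150)
    print(plot_field(sim, field))
    grDevices::dev.off()
  } else if (kind == "vtk") {
    types <- occupancy_types(sim)
    con <- file(path, "w")
    writeLines(c("# vtk DataFile Version 2.0",
                 "corneasim lattice snapshot", "ASCII",
                 "DATASET STRUCTURED_POINTS",
                 sprintf("DIMENSIONS %d %d 1", sim$W, sim$H),
                 "ORIGIN 0 0 0", "SPACING 1 1 1",
                 sprintf("POINT_DATA %d", sim$W * sim$H),
                 "SCALARS cell_type int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(types), con)
    close(con)
  } else if (kind == "csv") {
    write.csv(cell_table(sim), path, row.names = FALSE)
  } else if (kind == "field_csv") {
    f <- matrix(sim$fields[[field]], nrow = sim$W)
    write.csv(t(f), path, row.names = FALSE)
  }
  invisible(path)
}
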