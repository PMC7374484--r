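#' Antenna grid specification
#'
#' Geometric model of a floor-mounted RFID antenna grid covering a rectangular
#' pen. Antennas are identical rectangles laid out on a regular column pitch;
#' rows are grouped into panels of `panel_rows` antennas, so the vertical
#' centre-to-centre spacing alternates between a within-panel and a
#' between-panel pitch. The defaults reproduce a 1.8 x 2.6 m broiler pen fully
#' covered by 30 antennas of 32 x 41 cm mounted pairwise on fifteen panels,
#' with antenna 7 dead: 5 columns at 36 cm pitch (5 x 0.36 = 1.80 m) and 6
#' rows spaced 45 cm within a panel and 42 cm across panels
#' (3 x 0.45 + 2 x 0.42 + 0.41 = 2.60 m).
#'
#' The shortest centre-to-centre distance between two distinct antennas (36 cm
#' under the defaults) defines one "switch unit"; all inter-antenna distances
#' are expressed relative to it, so a 45 cm move counts as 1.25 switch units.
#'
#' @param n_cols,n_rows Number of antenna columns (across the pen width) and
#'   rows (along the pen length).
#' @param antenna_width,antenna_length Antenna rectangle dimensions in metres
#'   (x and y respectively).
#' @param col_pitch Centre-to-centre spacing between adjacent columns, metres.
#' @param row_pitch_within_panel,row_pitch_between_panels Centre-to-centre
#'   spacing between vertically adjacent antennas on the same panel and on
#'   adjacent panels, metres.
#' @param panel_rows Number of antenna rows per panel.
#' @param dead_antennas Integer IDs of antennas that never emit registrations
#'   (they keep their geometry: centres, distances and neighbourhoods are
#'   defined for them).
#' @param unit_switch_distance Distance in metres defining one switch unit.
#' @param pen_width,pen_length Pen dimensions in metres (x and y).
#' @param origin_x,origin_y Pen coordinates of the centre of the antenna in
#'   column 1, row 1.
#' @param numbering `"row-major"` (antenna 1 at col 1/row 1, numbers increase
#'   along rows first) or `"column-major"`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec()
#' switch_units(g, 1, 6) # vertically adjacent on one panel: 0.45/0.36 = 1.25
#' @export
grid_spec <- function(n_cols = 5L, n_rows = 6L,
                      antenna_width = 0.32, antenna_length = 0.41,
                      col_pitch = 0.36,
                      row_pitch_within_panel = 0.45,
                      row_pitch_between_panels = 0.42,
                      panel_rows = 2L,
                      dead_antennas = 7L,
                      unit_switch_distance = 0.36,
                      pen_width = 1.8, pen_length = 2.6,
                      origin_x = col_pitch / 2,
                      origin_y = antenna_length / 2,
                      numbering = c("row-major", "column-major")) {
  numbering <- match.arg(numbering)
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  panel_rows <- as.integer(panel_rows)
  stopifnot(n_cols >= 1, n_rows >= 1, panel_rows >= 1,
            antenna_width > 0, antenna_length > 0,
            col_pitch > 0, row_pitch_within_panel > 0,
            row_pitch_between_panels > 0,
            unit_switch_distance > 0, pen_width > 0, pen_length > 0)
  if (col_pitch < antenna_width)
    stop("col_pitch smaller than antenna_width: antenna rectangles overlap")
  if (min(row_pitch_within_panel, row_pitch_between_panels) < antenna_length)
    stop("row pitch smaller than antenna_length: antenna rectangles overlap")

  n <- n_cols * n_rows
  # y centre of each row: pitch to the next row depends on whether the panel
  # boundary is crossed
  row_y <- numeric(n_rows)
  row_y[1] <- origin_y
  if (n_rows > 1) {
    for (r in 2:n_rows) {
      within <- ((r - 1L) %% panel_rows) != 0L
      row_y[r] <- row_y[r - 1] +
        if (within) row_pitch_within_panel else row_pitch_between_panels
    }
  }
  col_x <- origin_x + (seq_len(n_cols) - 1L) * col_pitch

  idx <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  id <- if (numbering == "row-major") {
    (idx$row - 1L) * n_cols + idx$col
  } else {
    (idx$col - 1L) * n_rows + idx$row
  }
  layout <- data.frame(antenna = id, col = idx$col, row = idx$row,
                       x = col_x[idx$col], y = row_y[idx$row])
  layout <- layout[order(layout$antenna), , drop = FALSE]
  rownames(layout) <- NULL

  dead_antennas <- as.integer(dead_antennas)
  if (length(dead_antennas) && !all(dead_antennas %in% layout$antenna))
    stop("dead_antennas contains IDs outside 1..", n)
  layout$dead <- layout$antenna %in% dead_antennas

  g <- list(n_cols = n_cols, n_rows = n_rows,
            antenna_width = antenna_width, antenna_length = antenna_length,
            col_pitch = col_pitch,
            row_pitch_within_panel = row_pitch_within_panel,
            row_pitch_between_panels = row_pitch_between_panels,
            panel_rows = panel_rows,
            dead_antennas = sort(dead_antennas),
            unit_switch_distance = unit_switch_distance,
            pen_width = pen_width, pen_length = pen_length,
            origin_x = origin_x, origin_y = origin_y,
            numbering = numbering,
            layout = layout)
  class(g) <- "grid_spec"

  mind <- min_centre_distance(g)
  if (n > 1 && abs(mind - unit_switch_distance) > 1e-9)
    warning(sprintf(paste("minimum centre-to-centre distance (%.4f m) does",
                          "not equal unit_switch_distance (%.4f m)"),
                    mind, unit_switch_distance))
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("RFID antenna grid: %d x %d = %d antennas (%.0f x %.0f cm)\n",
              x$n_cols, x$n_rows, nrow(x$layout),
              100 * x$antenna_width, 100 * x$antenna_length))
  cat(sprintf("  pen %.2f x %.2f m; 1 switch unit = %.2f m\n",
              x$pen_width, x$pen_length, x$unit_switch_distance))
  if (length(x$dead_antennas))
    cat("  dead antennas:", paste(x$dead_antennas, collapse = ", "), "\n")
  invisible(x)
}

n_antennas <- function(grid) nrow(grid$layout)

check_antenna <- function(grid, antenna) {
  antenna <- as.integer(antenna)
  bad <- !antenna %in% grid$layout$antenna
  if (any(bad))
    stop("unknown antenna ID: ", paste(unique(antenna[bad]), collapse = ", "))
  antenna
}

# row index into grid$layout for antenna IDs (layout is sorted by antenna)
layout_index <- function(grid, antenna) {
  match(check_antenna(grid, antenna), grid$layout$antenna)
}

#' Antenna centre coordinates
#'
#' @param grid A [grid_spec()].
#' @param antenna Antenna ID(s).
#' @return A two-column matrix of centre coordinates (x, y) in metres, one row
#'   per antenna.
#' @export
antenna_centre <- function(grid, antenna) {
  i <- layout_index(grid, antenna)
  cbind(x = grid$layout$x[i], y = grid$layout$y[i])
}

#' Locate the antenna containing a point
#'
#' Maps pen coordinates to the antenna whose rectangle contains them.
#' Rectangles are half-open (left and bottom edges inclusive, right and top
#' exclusive) so that every point maps to at most one antenna. Points in the
#' uncovered gaps between antennas, or outside the grid, map to `NA`; dead
#' antennas are still reported (they have geometry, they just never register).
#'
#' @param grid A [grid_spec()].
#' @param x,y Pen coordinates in metres (vectorized).
#' @return Integer vector of antenna IDs, `NA` where no antenna covers the
#'   point.
#' @export
antenna_at <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  lay <- grid$layout
  hw <- grid$antenna_width / 2
  hl <- grid$antenna_length / 2
  col_x <- sort(unique(lay$x))
  row_y <- sort(unique(lay$y))
  xx <- ifelse(is.finite(x), x, -Inf)
  yy <- ifelse(is.finite(y), y, -Inf)
  # candidate column/row: last rectangle whose inclusive lower edge is <= point
  ci <- findInterval(xx, col_x - hw)
  ri <- findInterval(yy, row_y - hl)
  ok <- ci >= 1L & ri >= 1L
  ci[!ok] <- 1L; ri[!ok] <- 1L # safe placeholder indices
  inside <- ok & xx < col_x[ci] + hw & yy < row_y[ri] + hl
  id_mat <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  id_mat[cbind(lay$row, lay$col)] <- lay$antenna
  out <- ifelse(inside, id_mat[cbind(ri, ci)], NA_integer_)
  as.integer(out)
}

#' Centre-to-centre distance between two antennas
#'
#' Straight-line (Euclidean) distance between antenna centres, the shortest
#' possible route between them.
#'
#' @param grid A [grid_spec()].
#' @param a,b Antenna IDs (vectorized, recycled).
#' @return Distance(s) in metres.
#' @export
centre_distance <- function(grid, a, b) {
  pa <- antenna_centre(grid, a)
  pb <- antenna_centre(grid, b)
  unname(sqrt((pa[, 1] - pb[, 1])^2 + (pa[, 2] - pb[, 2])^2))
}

min_centre_distance <- function(grid) {
  p <- as.matrix(grid$layout[, c("x", "y")])
  if (nrow(p) < 2) return(NA_real_)
  min(stats::dist(p))
}

#' Switch units between two antennas
#'
#' Inter-antenna distance expressed in switch units: the centre-to-centre
#' distance divided by the grid's unit switch distance (the minimum
#' centre-to-centre distance, 36 cm by default). Multiplying switch units by
#' the unit distance recovers metres.
#'
#' @inheritParams centre_distance
#' @return Switch unit count(s), non-negative; 0 iff `a == b`.
#' @export
switch_units <- function(grid, a, b) {
  centre_distance(grid, a, b) / grid$unit_switch_distance
}

#' Moore neighbourhood of an antenna
#'
#' The up-to-eight antennas within one grid step (Chebyshev distance 1 in
#' column/row indices) of an antenna. Used for "near match" validation, where
#' a registration is accepted if it deviates from ground truth by at most one
#' antenna. Dead antennas are included: adjacency is geometric.
#'
#' @param grid A [grid_spec()].
#' @param antenna A single antenna ID.
#' @return Sorted integer vector of neighbouring antenna IDs (length 3 for a
#'   corner, 5 for an edge, 8 for an interior antenna).
#' @export
neighbours <- function(grid, antenna) {
  i <- layout_index(grid, antenna)
  stopifnot(length(i) == 1)
  lay <- grid$layout
  dc <- abs(lay$col - lay$col[i])
  dr <- abs(lay$row - lay$row[i])
  sort(lay$antenna[dc <= 1 & dr <= 1 & (dc + dr) > 0])
}

#' Tabulate the antenna layout
#'
#' @param grid A [grid_spec()].
#' @return A data frame with one row per antenna: `antenna`, `col`, `row`,
#'   centre `x`/`y` in metres and a `dead` flag.
#' @export
antenna_table <- function(grid) grid$layout

#' Read / write a grid configuration file
#'
#' The configuration is a YAML mapping of the [grid_spec()] arguments. A file
#' reproducing the default 30-antenna broiler pen ships with the package
#' (`system.file("extdata", "default_grid.yaml", package = "rfidtrack")`).
#'
#' @param path File path.
#' @return `read_grid_config()` returns a `grid_spec`;
#'   `write_grid_config()` invisibly returns `path`.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(grid_spec)), "")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown grid configuration field(s): ", paste(extra, collapse = ", "))
  do.call(grid_spec, cfg)
}

#' @param grid A [grid_spec()].
#' @rdname read_grid_config
#' @export
write_grid_config <- function(grid, path) {
  fields <- c("n_cols", "n_rows", "antenna_width", "antenna_length",
              "col_pitch", "row_pitch_within_panel", "row_pitch_between_panels",
              "panel_rows", "dead_antennas", "unit_switch_distance",
              "pen_width", "pen_length", "origin_x", "origin_y", "numbering")
  yaml::write_yaml(grid[fields], path)
  invisible(path)
}

#' Export a plain-text grid summary
#'
#' Writes the [antenna_table()] as a tab-delimited file.
#'
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @export
write_grid_summary <- function(grid, path) {
  utils::write.table(antenna_table(grid), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
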