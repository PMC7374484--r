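#' Pixel-to-pen calibration
#'
#' Builds the affine (axis-aligned) map from image pixel coordinates to pen
#' metres from a reference image of the empty pen: two reference points with
#' known pixel and pen coordinates (typically opposite pen corners) define
#' the per-axis scale and offset.
#'
#' @param px A 2x2 matrix (rows = reference points, columns = pixel x, y).
#' @param metres A 2x2 matrix of the same points in pen metres.
#' @return A function `(x_px, y_px) -> data.frame(x, y)` in metres.
#' @export
make_calibration <- function(px, metres) {
  px <- as.matrix(px); metres <- as.matrix(metres)
  stopifnot(dim(px) == c(2, 2), dim(metres) == c(2, 2))
  if (any(px[2, ] == px[1, ])) stop("degenerate calibration points")
  sx <- (metres[2, 1] - metres[1, 1]) / (px[2, 1] - px[1, 1])
  sy <- (metres[2, 2] - metres[1, 2]) / (px[2, 2] - px[1, 2])
  function(x_px, y_px) {
    data.frame(x = metres[1, 1] + (x_px - px[1, 1]) * sx,
               y = metres[1, 2] + (y_px - px[1, 2]) * sy)
  }
}

#' Clean ground-truth annotations into a location series
#'
#' Converts raw frame annotations (one row per individual per frame) into a
#' per-second antenna series, applying the cleaning rules used for location
#' validation:
#' * annotations outside the antenna range (e.g. a bird leaning against the
#'   pen wall) become missing;
#' * annotations at a dead antenna become missing — the sensor cannot confirm
#'   or refute them;
#' * an annotation placing a bird for a single frame at an antenna
#'   non-adjacent (Chebyshev distance > 1) to the preceding retained frame's
#'   antenna is an annotation error and becomes missing.
#'
#' @param raw A data frame with columns `time`, `individual` and either
#'   `antenna` or pixel coordinates `x_px`, `y_px`.
#' @param grid A [grid_spec()].
#' @param calibration A [make_calibration()] function; required when `raw`
#'   has pixel coordinates instead of antenna IDs.
#' @return A [location_series()].
#' @export
clean_annotations <- function(raw, grid, calibration = NULL) {
  stopifnot(all(c("time", "individual") %in% names(raw)))
  if (!"antenna" %in% names(raw)) {
    if (is.null(calibration))
      stop("pixel annotations need a calibration (see make_calibration)")
    if (!all(c("x_px", "y_px") %in% names(raw)))
      stop("raw annotations need either `antenna` or `x_px`/`y_px` columns")
    m <- calibration(raw$x_px, raw$y_px)
    raw$antenna <- antenna_at(grid, m$x, m$y)
  }
  ok <- raw$antenna %in% grid$layout$antenna
  raw$antenna[!ok] <- NA_integer_ # out of grid
  raw$antenna[raw$antenna %in% grid$dead_antennas] <- NA_integer_

  parts <- lapply(split(raw, raw$individual), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    d$antenna <- drop_single_frame_jumps(d$antenna, grid)
    d
  })
  d <- do.call(rbind, parts)
  location_series(d$individual, d$time, d$antenna)
}

# Blank single-frame excursions to an antenna non-adjacent to the preceding
# retained frame. The first frame can never be declared a jump.
drop_single_frame_jumps <- function(ant, grid) {
  n <- length(ant)
  if (n < 2) return(ant)
  out <- ant
  prev <- NA_integer_ # preceding retained antenna
  i <- 1L
  while (i <= n) {
    a <- out[i]
    if (!is.na(a)) {
      run_end <- i
      while (run_end < n && !is.na(out[run_end + 1L]) &&
             out[run_end + 1L] == a) run_end <- run_end + 1L
      single <- run_end == i
      if (single && !is.na(prev) && a != prev &&
          !(a %in% neighbours(grid, prev))) {
        out[i] <- NA_integer_ # jump removed; `prev` unchanged
      } else {
        prev <- a
      }
      i <- run_end + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Align a ground-truth and an RFID location series
#'
#' Pairs the two streams per (individual, second) over the intersection of
#' their time grids. Rows where either side is missing are excluded from
#' matching but counted.
#'
#' @param truth,rfid [location_series()] objects covering the same
#'   individuals.
#' @param group Optional data frame with columns `time` and `group` (e.g. a
#'   video segment label) carried onto the paired rows for per-video
#'   reporting.
#' @return A data frame of class `paired_locations` with columns
#'   `individual`, `time`, `truth`, `rfid` (and `group` when given), plus
#'   attributes `n_excluded` and `n_total`.
#' @export
align_streams <- function(truth, rfid, group = NULL) {
  m <- merge(data.frame(individual = truth$individual, time = truth$time,
                        truth = truth$antenna),
             data.frame(individual = rfid$individual, time = rfid$time,
                        rfid = rfid$antenna),
             by = c("individual", "time"))
  if (nrow(m) == 0) stop("location series have no overlapping (individual, time) rows")
  if (!is.null(group))
    m$group <- group$group[match(m$time, group$time)]
  m <- m[order(m$individual, m$time), , drop = FALSE]
  rownames(m) <- NULL
  incl <- !is.na(m$truth) & !is.na(m$rfid)
  attr(m, "n_total") <- nrow(m)
  attr(m, "n_excluded") <- sum(!incl)
  class(m) <- c("paired_locations", "data.frame")
  m
}

chebyshev_1 <- function(grid, a, b) {
  ia <- layout_index(grid, a); ib <- layout_index(grid, b)
  lay <- grid$layout
  pmax(abs(lay$col[ia] - lay$col[ib]), abs(lay$row[ia] - lay$row[ib])) <= 1
}

#' Exact and near match statistics
#'
#' For each paired (truth, RFID) second: an exact match is the same antenna; a
#' near match additionally allows a deviation of one antenna, i.e. the truth
#' antenna being one of the (maximum eight) Moore neighbours of the RFID
#' antenna. Percentages are over the included rows (both sides observed),
#' pooled and per group when the paired table carries a `group` column.
#'
#' @param paired A [align_streams()] table.
#' @param grid A [grid_spec()].
#' @return A list of class `match_report`: `pooled` and `per_group` data
#'   frames with columns `registrations_included`, `exact`, `near`,
#'   `exact_pct`, `near_pct`.
#' @export
match_stats <- function(paired, grid) {
  d <- paired[!is.na(paired$truth) & !is.na(paired$rfid), , drop = FALSE]
  if (nrow(d) == 0) stop("no included registrations to compare")
  d$exact <- d$truth == d$rfid
  d$near <- d$exact | chebyshev_1(grid, d$truth, d$rfid)
  summarize <- function(dd) {
    data.frame(registrations_included = nrow(dd),
               exact = sum(dd$exact), near = sum(dd$near),
               exact_pct = 100 * mean(dd$exact),
               near_pct = 100 * mean(dd$near))
  }
  per_group <- NULL
  if (!is.null(d$group)) {
    parts <- lapply(split(d, d$group), summarize)
    per_group <- cbind(data.frame(group = names(parts)),
                       do.call(rbind, parts))
    rownames(per_group) <- NULL
  }
  rep <- list(pooled = summarize(d), per_group = per_group,
              n_excluded = attr(paired, "n_excluded"))
  class(rep) <- "match_report"
  rep
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Location match report: %d included registrations (%s excluded)\n",
              x$pooled$registrations_included,
              if (is.null(x$n_excluded)) "?" else x$n_excluded))
  cat(sprintf("  exact matches: %d (%.1f%%)\n", x$pooled$exact,
              x$pooled$exact_pct))
  cat(sprintf("  near matches:  %d (%.1f%%)\n", x$pooled$near,
              x$pooled$near_pct))
  if (!is.null(x$per_group)) {
    cat("  per group:\n")
    print(x$per_group, row.names = FALSE)
  }
  invisible(x)
}

#' Export a match report
#'
#' Writes the per-group breakdown (when present) with a pooled total row as a
#' tab-delimited table.
#'
#' @param report A [match_stats()] report.
#' @param path Output file path.
#' @export
write_match_report <- function(report, path) {
  pooled <- cbind(data.frame(group = "total"), report$pooled)
  tab <- if (is.null(report$per_group)) pooled else
    rbind(report$per_group, pooled)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trajectory of an individual
#'
#' Collapses a location series to the chronological sequence of distinct
#' consecutive antennas (missing seconds dropped), the path suitable for
#' overlaying sensor-derived and ground-truth walks.
#'
#' @param series A [location_series()].
#' @param individual Individual ID.
#' @return A data frame with columns `step`, `antenna`, `time` (arrival time);
#'   zero rows when the individual's series is all missing.
#' @export
trajectory <- function(series, individual) {
  d <- series[series$individual == as.character(individual) &
                !is.na(series$antenna), , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(step = integer(0), antenna = integer(0),
                      time = numeric(0)))
  d <- d[order(d$time), , drop = FALSE]
  r <- rle(d$antenna)
  arrive <- d$time[cumsum(c(1L, utils::head(r$lengths, -1)))]
  data.frame(step = seq_along(r$values), antenna = r$values, time = arrive)
}

#' Plot two trajectories over the antenna grid
#'
#' Simple overlay of a ground-truth and a sensor-derived path through antenna
#' centres, drawn on the grid outline.
#'
#' @param grid A [grid_spec()].
#' @param truth,rfid [trajectory()] tables.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_trajectories <- function(grid, truth, rfid = NULL, ...) {
  lay <- grid$layout
  hw <- grid$antenna_width / 2; hl <- grid$antenna_length / 2
  graphics::plot(NA, xlim = c(0, grid$pen_width),
                 ylim = c(0, grid$pen_length), asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  graphics::rect(lay$x - hw, lay$y - hl, lay$x + hw, lay$y + hl,
                 border = "grey70")
  graphics::text(lay$x, lay$y, lay$antenna, col = "grey70", cex = 0.7)
  draw <- function(traj, col) {
    p <- antenna_centre(grid, traj$antenna)
    graphics::lines(p[, 1], p[, 2], col = col, lwd = 2)
    graphics::points(p[, 1], p[, 2], col = col, pch = 16, cex = 0.6)
  }
  if (nrow(truth)) draw(truth, "#3366CC")
  if (!is.null(rfid) && nrow(rfid)) draw(rfid, "#CC3366")
  invisible(NULL)
}
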