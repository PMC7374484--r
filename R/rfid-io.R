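#' Construct an RFID registration stream
#'
#' A registration stream is a time-ordered table of tag registrations, one row
#' per read: the reader polls each antenna at 1 Hz and logs the second of
#' registration, the tag's hexadecimal ID and the antenna. Rows are sorted by
#' time, stably, so that two registrations within the same second (a
#' same-second antenna switch) keep their input order.
#'
#' @param time Registration times in seconds (numeric; 1-s resolution).
#' @param tag_id Tag IDs; normalized to uppercase hexadecimal without a
#'   leading `0x`.
#' @param antenna Antenna IDs (integer).
#' @param grid Optional [grid_spec()]; when given, registrations at dead
#'   antennas are dropped with a warning (a dead antenna cannot read a tag, so
#'   such rows are log corruption) and unknown antenna IDs are an error.
#' @return A data frame of class `rfid_stream` with columns `time`, `tag_id`,
#'   `antenna`, and an attribute `n_rejected` counting dropped rows.
#' @export
rfid_stream <- function(time, tag_id, antenna, grid = NULL) {
  stopifnot(length(time) == length(tag_id), length(time) == length(antenna))
  time <- as.numeric(time)
  if (any(!is.finite(time))) stop("non-finite registration time")
  tag_id <- normalize_tag(tag_id)
  antenna <- as.integer(antenna)
  n_rejected <- 0L
  if (!is.null(grid)) {
    check_antenna(grid, antenna)
    dead <- antenna %in% grid$dead_antennas
    if (any(dead)) {
      warning(sum(dead), " registration(s) at dead antenna(s) dropped")
      n_rejected <- sum(dead)
      time <- time[!dead]; tag_id <- tag_id[!dead]; antenna <- antenna[!dead]
    }
  }
  ord <- order(time) # stable: ties keep input order
  s <- data.frame(time = time[ord], tag_id = tag_id[ord],
                  antenna = antenna[ord])
  attr(s, "n_rejected") <- n_rejected
  class(s) <- c("rfid_stream", "data.frame")
  s
}

normalize_tag <- function(tag_id) {
  tag_id <- toupper(trimws(as.character(tag_id)))
  tag_id <- sub("^0X", "", tag_id)
  if (any(!nzchar(tag_id))) stop("empty tag ID")
  if (any(grepl("[^0-9A-F]", tag_id)))
    stop("tag ID is not hexadecimal: ",
         paste(utils::head(unique(tag_id[grepl("[^0-9A-F]", tag_id)]), 3),
               collapse = ", "))
  tag_id
}

#' Read / write an RFID registration log
#'
#' The log is delimited text with a header and columns `time`, `tag_id`,
#' `antenna` (any order, configurable names). Times may be numeric seconds or
#' timestamps parsed with `time_format` (ISO-8601 `"%Y-%m-%d %H:%M:%S"` by
#' default); timestamp logs are written back in the same format, making the
#' reader/writer pair a round trip.
#'
#' @param path File path.
#' @param grid Optional [grid_spec()] used to validate antenna IDs and reject
#'   dead-antenna rows (see [rfid_stream()]).
#' @param delim Field delimiter (tab by default).
#' @param columns Named character vector mapping the internal names `time`,
#'   `tag_id`, `antenna` to the column names used in the file.
#' @param time_format Format string for timestamp parsing/formatting; ignored
#'   when the time column is numeric.
#' @param tz Time zone used for timestamp conversion.
#' @return `read_rfid_log()` returns an `rfid_stream` (with attribute
#'   `time_origin` if timestamps were parsed); `write_rfid_log()` invisibly
#'   returns `path`.
#' @export
read_rfid_log <- function(path, grid = NULL, delim = "\t",
                          columns = c(time = "time", tag_id = "tag_id",
                                      antenna = "antenna"),
                          time_format = "%Y-%m-%d %H:%M:%S", tz = "UTC") {
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- columns[c("time", "tag_id", "antenna")]
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("log is missing column(s): ", paste(missing_cols, collapse = ", "))
  tvec <- raw[[need[["time"]]]]
  is_numeric_time <- !anyNA(suppressWarnings(as.numeric(tvec))) || nrow(raw) == 0
  if (is_numeric_time) {
    time <- as.numeric(tvec)
    origin <- NULL
  } else {
    pt <- as.POSIXct(tvec, format = time_format, tz = tz)
    bad <- which(is.na(pt))
    if (length(bad))
      stop("unparseable timestamp at data line ", bad[1], ": ", tvec[bad[1]])
    time <- as.numeric(pt)
    origin <- list(format = time_format, tz = tz)
  }
  ant <- suppressWarnings(as.integer(raw[[need[["antenna"]]]]))
  bad <- which(is.na(ant))
  if (length(bad))
    stop("malformed antenna ID at data line ", bad[1])
  s <- rfid_stream(time, raw[[need[["tag_id"]]]], ant, grid = grid)
  attr(s, "time_origin") <- origin
  s
}

#' @param stream An `rfid_stream`.
#' @rdname read_rfid_log
#' @export
write_rfid_log <- function(stream, path, delim = "\t",
                           columns = c(time = "time", tag_id = "tag_id",
                                       antenna = "antenna")) {
  origin <- attr(stream, "time_origin")
  tcol <- if (is.null(origin)) {
    format(stream$time, scientific = FALSE, trim = TRUE)
  } else {
    format(as.POSIXct(stream$time, origin = "1970-01-01", tz = origin$tz),
           format = origin$format, tz = origin$tz)
  }
  out <- data.frame(tcol, stream$tag_id, stream$antenna)
  names(out) <- columns[c("time", "tag_id", "antenna")]
  utils::write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recording schedule
#'
#' A schedule is a set of non-overlapping half-open intervals
#' `[start, end)` in seconds during which the system was recording; gaps
#' between intervals correspond to handling periods (weighing, leg-band
#' checks) during which registrations are absent and positions may have been
#' moved by humans.
#'
#' @param start,end Interval bounds in seconds.
#' @return A data frame of class `rfid_schedule`, sorted by `start`.
#' @export
rfid_schedule <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) stop("empty schedule")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end <= start)) stop("schedule intervals must have end > start")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (any(utils::head(end, -1) > utils::tail(start, -1) + 1e-9))
    stop("schedule intervals overlap")
  s <- data.frame(start = start, end = end)
  class(s) <- c("rfid_schedule", "data.frame")
  s
}

#' @param path File path for the delimited (tab) schedule table with columns
#'   `start`, `end`.
#' @rdname rfid_schedule
#' @export
read_schedule <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  rfid_schedule(d$start, d$end)
}

#' @param schedule An `rfid_schedule`.
#' @rdname rfid_schedule
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

in_schedule <- function(time, schedule) {
  if (is.null(schedule)) return(rep(TRUE, length(time)))
  hit <- rep(FALSE, length(time))
  for (i in seq_len(nrow(schedule)))
    hit <- hit | (time >= schedule$start[i] & time < schedule$end[i])
  hit
}

tag_slice <- function(stream, tag) {
  tag <- normalize_tag(tag)
  stream[stream$tag_id == tag, , drop = FALSE]
}

#' Forward-fill a tag's location series
#'
#' Completes a tag's per-second location by the last-known-position rule: as
#' long as a tag is not registered elsewhere, the animal is assumed to still
#' be at the antenna where it was last registered. Seconds before the tag's
#' first registration stay missing. This completion is meant for second-by-
#' second location comparison only; distance estimation works on the raw
#' switch sequence and needs no filling.
#'
#' @param stream An `rfid_stream`.
#' @param tag Tag ID.
#' @param times Integer-second time grid to fill (e.g. `0:3599`).
#' @return A data frame of class `location_series` with columns `individual`,
#'   `time`, `antenna` (`NA` before the first registration).
#' @export
fill_forward <- function(stream, tag, times) {
  s <- tag_slice(stream, tag)
  times <- as.numeric(times)
  if (nrow(s) == 0) {
    ant <- rep(NA_integer_, length(times))
  } else {
    # last registration at or before each grid second
    i <- findInterval(times, s$time)
    ant <- ifelse(i >= 1, s$antenna[pmax(i, 1L)], NA_integer_)
  }
  location_series(individual = rep(normalize_tag(tag), length(times)),
                  time = times, antenna = as.integer(ant))
}

#' Per-second location series
#'
#' @param individual Individual/tag IDs.
#' @param time Times in seconds.
#' @param antenna Antenna IDs (`NA` = missing location).
#' @return A data frame of class `location_series`, one row per
#'   (individual, second), sorted.
#' @export
location_series <- function(individual, time, antenna) {
  d <- data.frame(individual = as.character(individual),
                  time = as.numeric(time),
                  antenna = as.integer(antenna))
  if (anyDuplicated(d[c("individual", "time")]))
    stop("duplicate (individual, time) rows in location series")
  d <- d[order(d$individual, d$time), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("location_series", "data.frame")
  d
}

#' Debounce a tag's antenna-switch sequence
#'
#' Extracts the chronological antenna switches of one tag and removes false
#' switches caused by a tag sitting on the boundary between two antennas,
#' where alternating registrations at the two antennas mimic movement. The
#' rule: a switch into antenna X at time t is a bounce-return if X was also
#' registered (in the original, unfiltered stream) less than `window` seconds
#' before t; a bounce-return is excluded, and when the immediately preceding
#' surviving switch was the matching move out of X, that switch is excluded
#' with it, so a stationary boundary bird nets zero movement. Genuine
#' sub-`window` round trips are removed too; that is the cost of the filter.
#'
#' When a `schedule` is given the stream is debounced per recording interval,
#' so switches spanning a handling gap are discarded.
#'
#' @param stream An `rfid_stream`.
#' @param tag Tag ID.
#' @param window Lookback in seconds; strictly-less-than comparison (open
#'   interval `(t - window, t)`).
#' @param schedule Optional [rfid_schedule()].
#' @return A data frame with one row per surviving switch: `time` (arrival at
#'   the new antenna), `from`, `to`.
#' @export
debounce <- function(stream, tag, window = 5, schedule = NULL) {
  stopifnot(window > 0)
  s <- tag_slice(stream, tag)
  if (is.null(schedule)) {
    return(debounce_one(s, window))
  }
  parts <- lapply(seq_len(nrow(schedule)), function(i) {
    seg <- s[s$time >= schedule$start[i] & s$time < schedule$end[i], ,
             drop = FALSE]
    debounce_one(seg, window)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

debounce_one <- function(s, window) {
  empty <- data.frame(time = numeric(0), from = integer(0), to = integer(0))
  if (nrow(s) < 2) return(empty)
  # collapse to runs of consecutive identical antennas; raw switches are the
  # run boundaries, stamped with the arrival time at the new antenna
  r <- rle(s$antenna)
  if (length(r$values) < 2) return(empty)
  run_start <- s$time[cumsum(c(1L, utils::head(r$lengths, -1)))]
  by_ant <- split(s$time, s$antenna)

  # walk: stack of visited antennas; each push records a switch, a paired
  # bounce pops the excursion
  walk_ant <- r$values[1]
  sw_time <- numeric(0); sw_from <- integer(0)
  for (k in 2:length(r$values)) {
    to <- r$values[k]
    t <- run_start[k]
    tx <- by_ant[[as.character(to)]]
    bounce <- any(tx > t - window & tx < t)
    if (bounce) {
      n <- length(walk_ant)
      if (n >= 2 && walk_ant[n - 1] == to) {
        # cancel the matching out-of-`to` switch together with this return
        walk_ant <- walk_ant[-n]
        sw_time <- sw_time[-(n - 1)]
        sw_from <- sw_from[-(n - 1)]
      }
      # else: drop the return switch alone (its partner is already gone)
    } else {
      sw_time <- c(sw_time, t)
      sw_from <- c(sw_from, walk_ant[length(walk_ant)])
      walk_ant <- c(walk_ant, to)
    }
  }
  data.frame(time = sw_time, from = sw_from,
             to = walk_ant[-1][seq_along(sw_time)])
}

#' Data completeness of a tag
#'
#' Fraction of scheduled hours containing at least one registration for the
#' tag. Animals with less than 75% of data available are flagged for
#' exclusion; the boundary is strict (exactly 75% is not excluded). Hours are
#' clock hours (`floor(time / 3600)`) intersecting the schedule, a denominator
#' robust to lying-down non-detection within an hour.
#'
#' @param stream An `rfid_stream`.
#' @param tag Tag ID.
#' @param schedule An [rfid_schedule()] (required).
#' @param threshold Exclusion threshold on the completeness fraction.
#' @return A list with `fraction`, `excluded`, `hours_with_data`,
#'   `scheduled_hours`.
#' @export
completeness <- function(stream, tag, schedule, threshold = 0.75) {
  if (is.null(schedule) || nrow(schedule) == 0) stop("empty schedule")
  hrs <- unlist(lapply(seq_len(nrow(schedule)), function(i) {
    seq(floor(schedule$start[i] / 3600),
        ceiling(schedule$end[i] / 3600) - 1)
  }))
  hrs <- unique(hrs)
  s <- tag_slice(stream, tag)
  s <- s[in_schedule(s$time, schedule), , drop = FALSE]
  with_data <- unique(floor(s$time / 3600))
  frac <- sum(hrs %in% with_data) / length(hrs)
  list(fraction = frac, excluded = frac < threshold,
       hours_with_data = sum(hrs %in% with_data),
       scheduled_hours = length(hrs))
}
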