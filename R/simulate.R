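#' Simulation configuration
#'
#' Parameters of the synthetic broiler-pen world: a two-state
#' (rest/active) behaviour process with per-bird activity multipliers, a
#' correlated random walk while active, a leg-mounted tag offset from the
#' body centre, and the three observers — the RFID floor grid (posture-
#' dependent detection, boundary flicker, dead antennas), a centre-point
#' video observer with a half-body-width movement threshold, and a UWB-style
#' observer sampling noisy positions every 6.91 s.
#'
#' Defaults aim at broiler-like behaviour: birds rest most of the time
#' (active fraction around 6%), walk at about 0.1 m/s when moving, and differ
#' stably in activity through a lognormal multiplier, giving hourly distances
#' of roughly 5 to 60 m across a flock.
#'
#' @param n_birds Number of birds.
#' @param duration Simulated seconds.
#' @param seed Base integer seed; with the config it fully determines every
#'   output stream.
#' @param grid A [grid_spec()].
#' @param p_rest_to_active,p_active_to_rest Per-second transition
#'   probabilities of the behaviour process.
#' @param activity_sdlog Lognormal sd of the per-bird activity multiplier
#'   applied to `p_rest_to_active`.
#' @param activity_multipliers Optional explicit per-bird multipliers
#'   (overrides the lognormal draw).
#' @param standing_idle_fraction Fraction of rest bouts spent standing
#'   (readable) rather than lying.
#' @param speed_mean Mean walking speed, m/s.
#' @param speed_shape Gamma shape of the per-second step length.
#' @param turning_sd Sd of the per-second heading increment, radians.
#' @param leg_offset,leg_offset_sd Mean and sd of the per-bird distance
#'   between body centre and the tagged leg, metres (grows with body size in
#'   real birds; sampled per bird here).
#' @param p_read_standing,p_read_walking,p_read_lying Per-second probability
#'   that the tag is read when the bird stands still, walks, or lies. A lying
#'   tag is parallel to the antenna plane and rarely couples; a walking tag is
#'   lifted through the stride cycle and out of the shallow read field part of
#'   the time, so briefly visited antennas can go unrecorded.
#' @param boundary_band Distance from an antenna edge, metres, within which a
#'   standing tag may also be read by the flanking antenna.
#' @param flicker_prob Per-read probability that a standing in-band tag is
#'   registered at the flanking antenna instead.
#' @param same_second_pair_prob Probability that a flicker read emits both
#'   antennas within the same second.
#' @param uwb_interval UWB sampling interval, seconds.
#' @param uwb_noise_sd Isotropic positional noise of the UWB observer, metres.
#' @param body_width Bird body width, metres; the video observer counts
#'   movement only once the centre shifts at least half of it.
#' @param annotation_jitter_sd Sd of the annotation error on the video
#'   centre-point, metres.
#' @param degraded_antennas,degrade_onset Antennas that stop recording from
#'   `degrade_onset` seconds onward (e.g. moisture under a drinker).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 40L, duration = 3600L, seed = 1L,
                       grid = grid_spec(),
                       p_rest_to_active = 0.005, p_active_to_rest = 0.08,
                       activity_sdlog = 0.6, activity_multipliers = NULL,
                       standing_idle_fraction = 0.2,
                       speed_mean = 0.10, speed_shape = 2, turning_sd = 0.4,
                       leg_offset = 0.05, leg_offset_sd = 0.01,
                       p_read_standing = 0.95, p_read_walking = 0.5,
                       p_read_lying = 0.05,
                       boundary_band = 0.03, flicker_prob = 0.2,
                       same_second_pair_prob = 0.02,
                       uwb_interval = 6.91, uwb_noise_sd = 0.15,
                       body_width = 0.12, annotation_jitter_sd = 0.02,
                       degraded_antennas = integer(0), degrade_onset = Inf) {
  probs <- c(p_rest_to_active, p_active_to_rest, standing_idle_fraction,
             p_read_standing, p_read_walking, p_read_lying, flicker_prob,
             same_second_pair_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(n_birds >= 1, duration >= 1, inherits(grid, "grid_spec"),
            speed_mean >= 0, speed_shape > 0, turning_sd >= 0,
            leg_offset >= 0, leg_offset_sd >= 0, boundary_band >= 0,
            uwb_interval > 0, uwb_noise_sd >= 0, body_width >= 0,
            annotation_jitter_sd >= 0)
  if (!is.null(activity_multipliers)) {
    stopifnot(length(activity_multipliers) == n_birds,
              all(activity_multipliers >= 0))
  }
  if (length(degraded_antennas)) check_antenna(grid, degraded_antennas)
  cfg <- as.list(environment())
  cfg$probs <- NULL
  cfg$n_birds <- as.integer(n_birds)
  cfg$duration <- as.integer(duration)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

bird_tags <- function(n) sprintf("%04X", 0xA000 + seq_len(n))

#' Simulate ground-truth bird movement
#'
#' Two-state semi-Markov behaviour per bird (rest/active, geometric bout
#' lengths) with a correlated random walk while active, reflected at the pen
#' walls. Resting birds lie with probability `1 - standing_idle_fraction` per
#' bout. The tagged leg sits `leg_offset` metres lateral to the body centre.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (`NULL` = continue the current RNG stream).
#' @return A data frame of class `sim_trajectory` with one row per
#'   (bird, second): `bird`, `time`, `x`, `y`, `leg_x`, `leg_y`, `posture`
#'   (`"lying"`, `"standing"` or `"walking"`), plus an attribute
#'   `activity_multiplier` (named per-bird vector).
#' @export
simulate_movement <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_birds
  dur <- config$duration
  W <- config$grid$pen_width; L <- config$grid$pen_length
  mult <- config$activity_multipliers
  if (is.null(mult))
    mult <- stats::rlnorm(n, 0, config$activity_sdlog)
  p_on <- pmin(1, config$p_rest_to_active * mult)
  p_off <- config$p_active_to_rest

  x <- matrix(0, dur, n); y <- matrix(0, dur, n)
  active_m <- matrix(FALSE, dur, n)
  lying_m <- matrix(FALSE, dur, n)

  px <- stats::runif(n, 0, W); py <- stats::runif(n, 0, L)
  heading <- stats::runif(n, -pi, pi)
  active <- rep(FALSE, n)
  lying <- stats::runif(n) > config$standing_idle_fraction

  rate <- config$speed_shape / max(config$speed_mean, 1e-12)
  for (t in seq_len(dur)) {
    wake <- !active & stats::runif(n) < p_on
    sleep <- active & stats::runif(n) < p_off
    active[wake] <- TRUE
    active[sleep] <- FALSE
    if (any(sleep))
      lying[sleep] <- stats::runif(sum(sleep)) > config$standing_idle_fraction
    turn <- stats::rnorm(n, 0, config$turning_sd)
    heading[active] <- heading[active] + turn[active] # resting birds do not turn
    step <- if (config$speed_mean > 0)
      stats::rgamma(n, shape = config$speed_shape, rate = rate) else
      numeric(n)
    step[!active] <- 0
    px <- px + step * cos(heading)
    py <- py + step * sin(heading)
    # reflect at walls
    ref_x <- px < 0 | px > W
    px[px < 0] <- -px[px < 0]; px[px > W] <- 2 * W - px[px > W]
    ref_y <- py < 0 | py > L
    py[py < 0] <- -py[py < 0]; py[py > L] <- 2 * L - py[py > L]
    heading[ref_x] <- pi - heading[ref_x]
    heading[ref_y] <- -heading[ref_y]
    px <- pmin(pmax(px, 0), W); py <- pmin(pmax(py, 0), L)
    x[t, ] <- px; y[t, ] <- py
    active_m[t, ] <- active
    lying_m[t, ] <- lying & !active
  }

  # tagged leg: lateral displacement from the body centre, fixed direction per
  # bird — the leg travels with the body (same path length) but sits in a
  # possibly different antenna cell, the centre-vs-leg mismatch mechanism
  off <- pmax(0, stats::rnorm(n, config$leg_offset, config$leg_offset_sd))
  phi <- stats::runif(n, -pi, pi)
  off_x <- matrix(off * cos(phi), dur, n, byrow = TRUE)
  off_y <- matrix(off * sin(phi), dur, n, byrow = TRUE)
  leg_x <- pmin(pmax(x + off_x, 0), W)
  leg_y <- pmin(pmax(y + off_y, 0), L)

  posture <- ifelse(active_m, "walking",
                    ifelse(lying_m, "lying", "standing"))
  tags <- bird_tags(n)
  traj <- data.frame(
    bird = rep(tags, each = dur),
    time = rep(seq_len(dur) - 1L, n),
    x = as.vector(x), y = as.vector(y),
    leg_x = as.vector(leg_x), leg_y = as.vector(leg_y),
    posture = as.vector(posture))
  names(mult) <- tags
  attr(traj, "activity_multiplier") <- mult
  attr(traj, "duration") <- dur
  class(traj) <- c("sim_trajectory", "data.frame")
  traj
}

#' Scripted deterministic trajectory
#'
#' Builds a trajectory from explicit waypoints, bypassing all randomness:
#' the bird dwells at each waypoint, then walks to the next in a straight
#' line at `speed` metres per second. Useful as an exact oracle: the true
#' path length is the sum of the straight segment lengths.
#'
#' @param waypoints A data frame with columns `x`, `y` and optionally `dwell`
#'   (seconds to pause at the waypoint, default 6).
#' @param speed Walking speed, m/s (one step per second).
#' @param bird Tag ID for the bird.
#' @param posture Posture while dwelling (`"standing"` by default; movement
#'   seconds are always `"walking"`).
#' @return A `sim_trajectory` (leg position equal to the centre) with
#'   attribute `true_path_length`.
#' @export
scripted_trajectory <- function(waypoints, speed = 0.36, bird = "A001",
                                posture = "standing") {
  stopifnot(all(c("x", "y") %in% names(waypoints)), nrow(waypoints) >= 1,
            speed > 0)
  dwell <- if ("dwell" %in% names(waypoints)) waypoints$dwell else
    rep(6, nrow(waypoints))
  xs <- ys <- numeric(0); post <- character(0)
  path_len <- 0
  for (i in seq_len(nrow(waypoints))) {
    xs <- c(xs, rep(waypoints$x[i], dwell[i]))
    ys <- c(ys, rep(waypoints$y[i], dwell[i]))
    post <- c(post, rep(posture, dwell[i]))
    if (i < nrow(waypoints)) {
      dx <- waypoints$x[i + 1] - waypoints$x[i]
      dy <- waypoints$y[i + 1] - waypoints$y[i]
      d <- sqrt(dx^2 + dy^2)
      path_len <- path_len + d
      if (d > 0) {
        k <- ceiling(d / speed)
        frac <- seq_len(k) / k
        xs <- c(xs, waypoints$x[i] + frac * dx)
        ys <- c(ys, waypoints$y[i] + frac * dy)
        post <- c(post, rep("walking", k))
      }
    }
  }
  traj <- data.frame(bird = bird, time = seq_along(xs) - 1,
                     x = xs, y = ys, leg_x = xs, leg_y = ys,
                     posture = post)
  attr(traj, "true_path_length") <- path_len
  attr(traj, "duration") <- length(xs)
  class(traj) <- c("sim_trajectory", "data.frame")
  traj
}

#' RFID sensor model
#'
#' Converts ground-truth trajectories into a registration stream. Each
#' second, the antenna under the tagged leg reads the tag with probability
#' `p_read_standing` (standing/walking) or `p_read_lying` (lying; the tag
#' lies parallel to the antenna plane and rarely couples). Positions in the
#' uncovered gaps between antennas are never read. A standing tag within
#' `boundary_band` of an antenna edge may be registered by the flanking
#' antenna instead (probability `flicker_prob` per read), occasionally by
#' both in the same second — the false-switch mechanism the 5-s debounce
#' filter removes. Dead and degraded antennas never register.
#'
#' @param traj A `sim_trajectory`.
#' @param grid A [grid_spec()].
#' @param config A [sim_config()].
#' @param seed Integer seed (`NULL` = continue the current RNG stream).
#' @return An `rfid_stream`.
#' @export
rfid_sensor <- function(traj, grid, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ant <- antenna_at(grid, traj$leg_x, traj$leg_y)
  p <- c(lying = config$p_read_lying, standing = config$p_read_standing,
         walking = config$p_read_walking)[traj$posture]
  read <- !is.na(ant) & stats::runif(nrow(traj)) < p

  time <- traj$time[read]
  tag <- traj$bird[read]
  a <- ant[read]

  # boundary flicker for standing tags near an edge with a flanking antenna
  lay <- grid$layout
  i <- match(a, lay$antenna)
  hw <- grid$antenna_width / 2; hl <- grid$antenna_length / 2
  ex <- traj$leg_x[read] - lay$x[i]
  ey <- traj$leg_y[read] - lay$y[i]
  edge_d <- cbind(hw + ex, hw - ex, hl + ey, hl - ey) # left right bottom top
  nearest <- max.col(-edge_d, ties.method = "first")
  in_band <- edge_d[cbind(seq_along(a), nearest)] < config$boundary_band
  dcol <- c(-1L, 1L, 0L, 0L)[nearest]
  drow <- c(0L, 0L, -1L, 1L)[nearest]
  key <- paste(lay$col, lay$row)
  flank <- lay$antenna[match(paste(lay$col[i] + dcol, lay$row[i] + drow), key)]
  # alternation needs a tag sitting on the boundary: standing still, readable
  # by both antennas; a walking tag registers the antenna it is over and a
  # lying tag barely couples at all
  standing_still <- traj$posture[read] == "standing"
  can_flick <- standing_still & in_band & !is.na(flank)
  flick <- can_flick & stats::runif(length(a)) < config$flicker_prob
  both <- flick & stats::runif(length(a)) < config$same_second_pair_prob
  a2 <- a
  a2[flick] <- flank[flick]

  time_all <- c(time, time[both])
  tag_all <- c(tag, tag[both])
  ant_all <- c(a2, a[both])

  # dead and degraded antennas never emit registrations
  drop <- ant_all %in% grid$dead_antennas |
    (ant_all %in% config$degraded_antennas & time_all >= config$degrade_onset)
  rfid_stream(time_all[!drop], tag_all[!drop], ant_all[!drop])
}

#' Video observer
#'
#' Emulates frame-by-frame human annotation and distance tracking from
#' top-view video. The location series annotates the antenna under the
#' bird's body centre (not the tagged leg) plus annotation jitter. The
#' per-period distance sums centre displacements, counting movement only
#' when the centre has shifted at least half a body width since the last
#' counted point — the movement threshold of circle-based video tracking.
#'
#' @param traj A `sim_trajectory`.
#' @param grid A [grid_spec()].
#' @param config A [sim_config()].
#' @param periods An [rfid_periods()] table (default: one period spanning
#'   the trajectory).
#' @param seed Integer seed (`NULL` = continue the current RNG stream).
#' @return A list with `series` (a [location_series()], including dead-
#'   antenna annotations — cleaning is the validator's job) and `distances`
#'   (data frame `bird`, `period`, `metres`).
#' @export
video_observer <- function(traj, grid, config, periods = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(periods)) periods <- whole_period(traj)
  jx <- stats::rnorm(nrow(traj), 0, config$annotation_jitter_sd)
  jy <- stats::rnorm(nrow(traj), 0, config$annotation_jitter_sd)
  ant <- antenna_at(grid, traj$x + jx, traj$y + jy)
  series <- location_series(traj$bird, traj$time, ant)

  thr <- config$body_width / 2
  distances <- per_bird_period(traj, periods, function(d) {
    threshold_distance(d$x, d$y, thr)
  })
  list(series = series, distances = distances)
}

# Circle-and-track distance: while idle, a circle of radius `thr` is kept
# around the bird and nothing is counted; once the centre leaves the circle a
# tracker follows the full path until the bird stops moving, after which the
# circle is re-placed. Sub-threshold idle drift is the only loss.
threshold_distance <- function(x, y, thr, stop_eps = 0.005) {
  n <- length(x)
  if (n < 2) return(0)
  total <- 0
  tracking <- FALSE
  ax <- x[1]; ay <- y[1]
  for (i in 2:n) {
    if (!tracking) {
      d <- sqrt((x[i] - ax)^2 + (y[i] - ay)^2)
      if (d >= thr) {
        total <- total + d
        tracking <- TRUE
      }
    } else {
      step <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
      if (step < stop_eps) {
        tracking <- FALSE
        ax <- x[i]; ay <- y[i]
      } else {
        total <- total + step
      }
    }
  }
  total
}

#' UWB observer
#'
#' Samples the body-centre position every `uwb_interval` seconds with
#' isotropic Gaussian positional noise and sums consecutive-sample
#' displacements per period. The noise inflates the recorded distance: for a
#' stationary tag the expected total is `(n - 1) * sd * sqrt(pi)` over `n`
#' samples (each step is the norm of a difference of two independent
#' bivariate normals, a Rayleigh variable with scale `sd * sqrt(2)`).
#'
#' @param traj A `sim_trajectory`.
#' @param config A [sim_config()].
#' @param periods An [rfid_periods()] table (default: one period).
#' @param seed Integer seed (`NULL` = continue the current RNG stream).
#' @return A data frame `bird`, `period`, `metres`.
#' @export
uwb_observer <- function(traj, config, periods = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(periods)) periods <- whole_period(traj)
  dur <- max(traj$time) + 1
  sample_t <- unique(floor(seq(0, dur - 1, by = config$uwb_interval)))
  parts <- lapply(split(traj, traj$bird), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    keep <- d$time %in% sample_t
    sx <- d$x[keep] + stats::rnorm(sum(keep), 0, config$uwb_noise_sd)
    sy <- d$y[keep] + stats::rnorm(sum(keep), 0, config$uwb_noise_sd)
    st <- d$time[keep]
    step <- sqrt(diff(sx)^2 + diff(sy)^2)
    arrive <- st[-1]
    metres <- vapply(seq_len(nrow(periods)), function(i) {
      sum(step[arrive >= periods$start[i] & arrive < periods$end[i]])
    }, numeric(1))
    data.frame(bird = d$bird[1], period = periods$period, metres = metres)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' True distances moved
#'
#' Ground-truth body-centre path length per bird and period (steps assigned
#' by arrival second).
#'
#' @param traj A `sim_trajectory`.
#' @param periods An [rfid_periods()] table (default: one period).
#' @return A data frame `bird`, `period`, `metres`.
#' @export
true_distances <- function(traj, periods = NULL) {
  if (is.null(periods)) periods <- whole_period(traj)
  per_bird_period(traj, periods, function(d) {
    sum(sqrt(diff(d$x)^2 + diff(d$y)^2))
  })
}

whole_period <- function(traj) {
  rfid_periods("P1", min(traj$time), max(traj$time) + 1)
}

per_bird_period <- function(traj, periods, f) {
  parts <- lapply(split(traj, traj$bird), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    metres <- vapply(seq_len(nrow(periods)), function(i) {
      keep <- d$time >= periods$start[i] & d$time < periods$end[i]
      f(d[keep, , drop = FALSE])
    }, numeric(1))
    data.frame(bird = d$bird[1], period = periods$period, metres = metres)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate annotation ratings for observer-reliability analysis
#'
#' Draws a set of frames from one trajectory and lets `n_raters` independent
#' observers annotate the antenna under the body centre, each rating subject
#' to a per-frame probability of mislabelling to a random Moore neighbour and
#' of missing the bird entirely.
#'
#' @param traj A `sim_trajectory`.
#' @param grid A [grid_spec()].
#' @param n_frames,n_raters Numbers of rated frames and raters.
#' @param error_prob Probability a rating lands on a random neighbour.
#' @param miss_prob Probability of a missing rating.
#' @param seed Integer seed.
#' @return A subjects x raters matrix of antenna labels (`NA` = missing).
#' @export
simulate_ratings <- function(traj, grid, n_frames = 25, n_raters = 12,
                             error_prob = 0.05, miss_prob = 0.03,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  birds <- unique(traj$bird)
  d <- traj[traj$bird == birds[1], , drop = FALSE]
  truth <- antenna_at(grid, d$x, d$y)
  ok <- which(!is.na(truth))
  frames <- sort(sample(ok, min(n_frames, length(ok))))
  m <- matrix(NA_integer_, length(frames), n_raters)
  for (j in seq_len(n_raters)) {
    for (i in seq_along(frames)) {
      if (stats::runif(1) < miss_prob) next
      a <- truth[frames[i]]
      if (stats::runif(1) < error_prob) {
        nb <- neighbours(grid, a)
        a <- nb[sample.int(length(nb), 1)]
      }
      m[i, j] <- a
    }
  }
  colnames(m) <- paste0("rater", seq_len(n_raters))
  m
}

#' Generate a full simulation bundle
#'
#' Runs the movement model and all three observers from one config and seed,
#' producing every input the validation pipeline needs: ground-truth
#' trajectories and distances, the RFID registration log, the video-style
#' location series and distances, and the UWB-style distances. Deterministic
#' given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param periods An [rfid_periods()] table (default: one period spanning
#'   the run).
#' @return A list of class `sim_bundle`: `config`, `periods`,
#'   `trajectories`, `rfid_log`, `video` (series + distances),
#'   `uwb_distances`, `true_distances`, `schedule`.
#' @export
make_bundle <- function(config, periods = NULL) {
  base <- config$seed %% (2^31 - 5)
  traj <- simulate_movement(config, seed = base)
  if (is.null(periods)) periods <- whole_period(traj)
  bundle <- list(
    config = config,
    periods = periods,
    trajectories = traj,
    rfid_log = rfid_sensor(traj, config$grid, config, seed = base + 1),
    video = video_observer(traj, config$grid, config, periods,
                           seed = base + 2),
    uwb_distances = uwb_observer(traj, config, periods, seed = base + 3),
    true_distances = true_distances(traj, periods),
    schedule = rfid_schedule(min(traj$time), max(traj$time) + 1))
  class(bundle) <- "sim_bundle"
  bundle
}

#' Write a simulation bundle to plain-text files
#'
#' Emits the bundle in exactly the formats the other modules read: the RFID
#' log, the video annotation table, the schedule, the distance tables, the
#' grid configuration, and a JSON manifest recording config and seed.
#'
#' @param bundle A [make_bundle()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    rfid_log = file.path(dir, "rfid_log.tsv"),
    annotations = file.path(dir, "video_annotations.tsv"),
    schedule = file.path(dir, "schedule.tsv"),
    video_distances = file.path(dir, "video_distances.tsv"),
    uwb_distances = file.path(dir, "uwb_distances.tsv"),
    true_distances = file.path(dir, "true_distances.tsv"),
    grid = file.path(dir, "grid.yaml"),
    manifest = file.path(dir, "manifest.json"))
  write_rfid_log(bundle$rfid_log, paths["rfid_log"])
  utils::write.table(as.data.frame(bundle$video$series), paths["annotations"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_schedule(bundle$schedule, paths["schedule"])
  for (nm in c("video_distances", "uwb_distances", "true_distances")) {
    d <- switch(nm, video_distances = bundle$video$distances,
                uwb_distances = bundle$uwb_distances,
                true_distances = bundle$true_distances)
    utils::write.table(d, paths[nm], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_grid_config(bundle$config$grid, paths["grid"])
  cfg <- bundle$config
  cfg$grid <- NULL
  cfg$activity_multipliers <- unname(cfg$activity_multipliers)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
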