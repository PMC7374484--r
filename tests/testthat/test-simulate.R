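test_that("bundles are fully reproducible from config and seed", {
  cfg <- sim_config(n_birds = 4, duration = 300, seed = 5)
  b1 <- make_bundle(cfg)
  b2 <- make_bundle(cfg)
  expect_identical(b1$trajectories, b2$trajectories)
  expect_identical(as.data.frame(b1$rfid_log), as.data.frame(b2$rfid_log))
  expect_identical(b1$uwb_distances, b2$uwb_distances)
  b3 <- make_bundle(sim_config(n_birds = 4, duration = 300, seed = 6))
  expect_false(identical(as.data.frame(b1$rfid_log),
                         as.data.frame(b3$rfid_log)))
})

test_that("zero activity multipliers freeze every bird", {
  cfg <- sim_config(n_birds = 3, duration = 200, seed = 2,
                    activity_multipliers = c(0, 0, 0))
  traj <- simulate_movement(cfg)
  for (b in unique(traj$bird)) {
    d <- traj[traj$bird == b, ]
    expect_equal(sum(sqrt(diff(d$x)^2 + diff(d$y)^2)), 0)
  }
})

test_that("scripted paths know their exact length", {
  wp <- data.frame(x = c(0.2, 1.2, 1.2), y = c(0.2, 0.2, 1.7),
                   dwell = c(6, 6, 6))
  traj <- scripted_trajectory(wp, speed = 0.5)
  expect_equal(attr(traj, "true_path_length"), 2.5)
  expect_equal(true_distances(traj)$metres, 2.5)
  expect_equal(traj$x, traj$leg_x)
})

test_that("lying birds with zero read probability produce no registrations", {
  cfg <- sim_config(n_birds = 2, duration = 400, seed = 3,
                    p_rest_to_active = 0, standing_idle_fraction = 0,
                    p_read_lying = 0)
  traj <- simulate_movement(cfg)
  expect_true(all(traj$posture == "lying"))
  stream <- rfid_sensor(traj, cfg$grid, cfg, seed = 4)
  expect_equal(nrow(stream), 0)
})

test_that("the noiseless sensor reproduces true antenna occupancy", {
  cfg <- noiseless_config(n_birds = 3, duration = 400, seed = 9)
  traj <- simulate_movement(cfg)
  stream <- rfid_sensor(traj, cfg$grid, cfg, seed = 10)
  truth_ant <- antenna_at(cfg$grid, traj$x, traj$y)
  live <- !is.na(truth_ant) & !truth_ant %in% cfg$grid$dead_antennas
  got <- merge(data.frame(bird = traj$bird, time = traj$time,
                          truth = truth_ant)[live, ],
               data.frame(bird = stream$tag_id, time = stream$time,
                          reg = stream$antenna),
               by = c("bird", "time"), all.x = TRUE)
  expect_equal(got$reg, got$truth)
})

test_that("sustained boundary flicker is removed by the debounce filter", {
  g <- grid_spec()
  # a bird standing just inside the right edge of antenna 13, within the
  # boundary band flanking antenna 14
  pos <- data.frame(x = antenna_centre(g, 13)[1, 1] + g$antenna_width / 2 -
                      0.015,
                    y = antenna_centre(g, 13)[1, 2], dwell = 1200)
  traj <- scripted_trajectory(pos, bird = "A001")
  cfg <- sim_config(n_birds = 1, duration = 1200, seed = 12)
  stream <- rfid_sensor(traj, g, cfg, seed = 12)
  raw_switches <- sum(diff(stream$antenna) != 0)
  expect_gt(raw_switches, 20) # the flicker is really there
  surviving <- nrow(debounce(stream, "A001"))
  expect_lte(surviving, 0.05 * raw_switches)
})

test_that("degraded antennas stop registering at the configured onset", {
  g <- grid_spec()
  p <- antenna_centre(g, 21)
  traj <- scripted_trajectory(data.frame(x = p[1, 1], y = p[1, 2],
                                         dwell = 600))
  cfg <- sim_config(n_birds = 1, duration = 600, seed = 8,
                    degraded_antennas = 21L, degrade_onset = 300)
  stream <- rfid_sensor(traj, g, cfg, seed = 8)
  expect_gt(sum(stream$time < 300), 0)
  expect_equal(sum(stream$time >= 300), 0)
})

test_that("the default configuration reproduces the pen of the study", {
  cfg <- sim_config()
  expect_equal(nrow(antenna_table(cfg$grid)), 30)
  expect_equal(cfg$grid$pen_width, 1.8)
  expect_equal(cfg$grid$pen_length, 2.6)
  expect_equal(cfg$grid$dead_antennas, 7L)
  expect_equal(cfg$uwb_interval, 6.91)
  expect_error(sim_config(p_read_standing = 1.4), "probabilities")
})

test_that("a stationary tag's UWB distance follows the Rayleigh mean", {
  # positions every 6.91 s for an hour: n samples, steps are norms of
  # differences of two independent N(0, sd^2) pairs -> Rayleigh(sd*sqrt(2)),
  # mean sd*sqrt(pi) per step
  cfg <- sim_config(n_birds = 1, duration = 3600, seed = 1)
  traj <- scripted_trajectory(data.frame(x = 0.9, y = 1.3, dwell = 3600))
  d <- uwb_observer(traj, cfg, seed = 77)
  n <- length(unique(floor(seq(0, 3599, by = 6.91))))
  expected <- (n - 1) * cfg$uwb_noise_sd * sqrt(pi)
  expect_equal(d$metres, expected, tolerance = 0.05)
  # and exactly zero without noise
  cfg0 <- noiseless_config(n_birds = 1, duration = 3600, seed = 1)
  expect_equal(uwb_observer(traj, cfg0, seed = 77)$metres, 0)
})

test_that("the video observer ignores sub-threshold oscillation", {
  cfg <- sim_config(n_birds = 1, duration = 100, seed = 1)
  # wander within 0.4 body widths of the start: never leaves the half-width
  # circle around the tracking anchor
  amp <- 0.4 * cfg$body_width
  x <- 0.9 + amp * c(0, rep(c(1, -1), length.out = 99))
  traj <- data.frame(bird = "A001", time = 0:99, x = x, y = 1.3,
                     leg_x = x, leg_y = 1.3, posture = "standing")
  class(traj) <- c("sim_trajectory", "data.frame")
  v <- video_observer(traj, cfg$grid, cfg, seed = 2)
  expect_equal(v$distances$metres, 0)
})

test_that("simulated ratings give a high-agreement table", {
  cfg <- sim_config(n_birds = 2, duration = 600, seed = 4)
  traj <- simulate_movement(cfg)
  m <- simulate_ratings(traj, cfg$grid, n_frames = 25, n_raters = 12,
                        seed = 6)
  expect_equal(dim(m), c(25, 12))
  k <- fleiss_kappa(m)
  expect_gt(k$estimate, 0.7)
})

test_that("bundles write to the formats the readers accept", {
  cfg <- sim_config(n_birds = 3, duration = 200, seed = 15)
  b <- make_bundle(cfg)
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  s <- read_rfid_log(paths["rfid_log"], grid = cfg$grid)
  expect_equal(as.data.frame(s)[c("time", "tag_id", "antenna")],
               as.data.frame(b$rfid_log)[c("time", "tag_id", "antenna")])
  g2 <- read_grid_config(paths["grid"])
  expect_equal(antenna_table(g2), antenna_table(cfg$grid))
  manifest <- jsonlite::read_json(paths["manifest"])
  expect_equal(manifest$seed, 15)
})
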