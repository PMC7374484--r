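# Build a one-tag registration stream from parallel time/antenna vectors.
make_stream <- function(times, antennas, tag = "AB12") {
  rfid_stream(times, rep(tag, length(times)), antennas)
}

# Simulation config with every noise source switched off: perfect detection in
# all postures, no flicker, no annotation jitter, tag exactly at the body
# centre, no UWB noise.
noiseless_config <- function(...) {
  sim_config(p_read_standing = 1, p_read_walking = 1, p_read_lying = 1,
             flicker_prob = 0, same_second_pair_prob = 0,
             annotation_jitter_sd = 0, leg_offset = 0, leg_offset_sd = 0,
             uwb_noise_sd = 0, ...)
}

# A scripted rook walk over antenna centres: consecutive waypoints are
# horizontally or vertically adjacent antennas, with dwells long enough that
# no switch falls inside the debounce window.
rook_walk <- function(grid, antennas, dwell = 8, speed = 0.36) {
  p <- antenna_centre(grid, antennas)
  scripted_trajectory(data.frame(x = p[, 1], y = p[, 2], dwell = dwell),
                      speed = speed)
}
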