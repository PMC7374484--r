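test_that("streams sort by time with stable ties and normalized tags", {
  s <- rfid_stream(c(5, 1, 5, 3), c("0xab", "CD", "ab", "cd"), c(1, 2, 3, 4))
  expect_equal(s$time, c(1, 3, 5, 5))
  expect_equal(s$tag_id, c("CD", "CD", "AB", "AB"))
  # same-second rows keep input order (antenna 1 before antenna 3)
  expect_equal(s$antenna[s$time == 5], c(1L, 3L))
  expect_error(rfid_stream(1, "ZZ!", 1), "hexadecimal")
  expect_error(rfid_stream(1, "", 1), "empty tag")
})

test_that("dead-antenna registrations are rejected with a count", {
  g <- grid_spec()
  expect_warning(
    s <- rfid_stream(c(0, 1, 2), c("AA", "AA", "AA"), c(1, 7, 2), grid = g),
    "dead antenna")
  expect_equal(nrow(s), 2)
  expect_equal(attr(s, "n_rejected"), 1L)
  expect_error(rfid_stream(0, "AA", 99, grid = g), "unknown antenna")
})

test_that("log files round-trip bit-exactly", {
  s <- make_stream(c(0, 1, 1, 10), c(1, 2, 1, 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rfid_log(s, path)
  s2 <- read_rfid_log(path)
  expect_equal(as.data.frame(s2), as.data.frame(s))
  # and again: write(read(x)) is identical text
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_rfid_log(s2, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty stream gives a header-only file
  empty <- rfid_stream(numeric(0), character(0), integer(0))
  write_rfid_log(empty, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_rfid_log(path)), 0)
})

test_that("timestamp logs parse and format symmetrically", {
  txt <- c("time\ttag_id\tantenna",
           "2020-05-01 10:00:00\tAB\t1",
           "2020-05-01 10:00:01\tAB\t2")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(txt, path)
  s <- read_rfid_log(path)
  expect_equal(diff(s$time), 1)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_rfid_log(s, path2)
  expect_identical(readLines(path2), txt)
  writeLines(c("time\ttag_id\tantenna", "not-a-time\tAB\t1"), path)
  expect_error(read_rfid_log(path), "timestamp")
})

test_that("forward fill applies the last-known-position rule", {
  s <- make_stream(c(0, 10), c(1, 2))
  f <- fill_forward(s, "AB12", 0:14)
  expect_equal(f$antenna, c(rep(1L, 10), rep(2L, 5)))
  # seconds before the first registration stay missing
  f2 <- fill_forward(make_stream(5, 3), "AB12", 0:9)
  expect_equal(f2$antenna, c(rep(NA_integer_, 5), rep(3L, 5)))
  # continuous 1 Hz registrations are reproduced unchanged
  f3 <- fill_forward(make_stream(0:9, rep(c(1L, 2L), 5)), "AB12", 0:9)
  expect_equal(f3$antenna, rep(c(1L, 2L), 5))
  # absent tag: all missing, no error
  f4 <- fill_forward(s, "FFFF", 0:4)
  expect_true(all(is.na(f4$antenna)))
  # no missing values after the first registration (property)
  set.seed(1)
  for (i in 1:20) {
    t0 <- sort(sample(0:99, 10))
    f <- fill_forward(make_stream(t0, sample(1:5, 10, TRUE)), "AB12", 0:99)
    expect_false(anyNA(f$antenna[f$time >= t0[1]]))
  }
})

test_that("debounce removes boundary bounces exactly as specified", {
  # quick excursion removed together with its outbound switch
  expect_equal(nrow(debounce(make_stream(c(0, 1, 3), c(1, 2, 1)), "AB12")), 0)
  # moves outside the window all survive
  sw <- debounce(make_stream(c(0, 10, 20), c(1, 2, 1)), "AB12")
  expect_equal(nrow(sw), 2)
  expect_equal(sw$to, c(2L, 1L))
  # sustained boundary flicker nets zero movement
  expect_equal(nrow(debounce(make_stream(0:5, rep(c(1L, 2L), 3)), "AB12")), 0)
  # the lookback is strict: a return exactly `window` seconds after the last
  # registration at that antenna survives, one just inside is removed
  expect_equal(nrow(debounce(make_stream(c(0, 1, 5), c(1, 2, 1)), "AB12",
                             window = 5)), 2)
  expect_equal(nrow(debounce(make_stream(c(0, 1, 4.9), c(1, 2, 1)), "AB12",
                             window = 5)), 0)
})

test_that("debounce is a no-op on well-separated streams and never adds", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    ants <- sample(1:30, n, TRUE)
    ants <- ants[c(TRUE, diff(ants) != 0)]
    times_far <- cumsum(c(0, rep(6, length(ants) - 1)))
    sw <- debounce(make_stream(times_far, ants), "AB12")
    expect_equal(nrow(sw), length(ants) - 1) # no-op when spacing >= window
    # arbitrary timing: never more switches than raw, and the walk connects
    times_any <- cumsum(c(0, sample(1:8, length(ants) - 1, TRUE)))
    sw2 <- debounce(make_stream(times_any, ants), "AB12")
    expect_lte(nrow(sw2), length(ants) - 1)
    if (nrow(sw2) > 1)
      expect_equal(sw2$from[-1], sw2$to[-nrow(sw2)])
  }
})

test_that("debounce respects recording gaps", {
  # a switch spanning a handling gap is discarded
  s <- make_stream(c(0, 10, 100, 110), c(1, 2, 3, 4))
  sched <- rfid_schedule(c(0, 95), c(20, 130))
  sw <- debounce(s, "AB12", schedule = sched)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$to, c(2L, 4L)) # 2 -> 3 across the gap is dropped
})

test_that("completeness counts scheduled hours with data", {
  sched <- rfid_schedule(0, 24 * 3600)
  every_hour <- make_stream((0:23) * 3600 + 5, rep(1L, 24))
  c1 <- completeness(every_hour, "AB12", sched)
  expect_equal(c1$fraction, 1)
  expect_false(c1$excluded)
  c0 <- completeness(make_stream(numeric(0), integer(0)), "AB12", sched)
  expect_equal(c0$fraction, 0)
  expect_true(c0$excluded)
  # 18 of 24 hours = exactly 75%: the rule is strictly "< 75%", so not excluded
  c18 <- completeness(make_stream((0:17) * 3600, rep(1L, 18)), "AB12", sched)
  expect_equal(c18$fraction, 0.75)
  expect_false(c18$excluded)
  c17 <- completeness(make_stream((0:16) * 3600, rep(1L, 17)), "AB12", sched)
  expect_true(c17$excluded)
  expect_error(completeness(every_hour, "AB12", NULL), "empty schedule")
})

test_that("schedules validate and round-trip", {
  expect_error(rfid_schedule(c(0, 5), c(10, 20)), "overlap")
  expect_error(rfid_schedule(10, 5), "end > start")
  sch <- rfid_schedule(c(0, 50), c(20, 80))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(sch, path)
  expect_equal(as.data.frame(read_schedule(path)), as.data.frame(sch))
})
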