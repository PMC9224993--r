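test_that("zone occupancy integrates frame durations inside polygons", {
  zm <- make_zonemap("open_field")
  # never leaves the center
  kin <- kin_from_path(rep(17, 300), rep(17, 300))
  occ <- zone_occupancy(kin, zm)
  expect_equal(occ$seconds[occ$zone == "center"], 10)
  expect_equal(occ$seconds[occ$zone == "corner_sw"], 0)

  # a point exactly on a zone boundary counts inside (closed polygons)
  kin2 <- kin_from_path(rep(8.5, 30), rep(4, 30))   # on corner_sw edge
  occ2 <- zone_occupancy(kin2, zm)
  expect_equal(occ2$seconds[occ2$zone == "corner_sw"], 1)

  # gross calibration failure is rejected
  kin3 <- kin_from_path(rep(100, 30), rep(100, 30))
  expect_error(zone_occupancy(kin3, zm), "calibration")
})

test_that("itinerary-driven occupancy matches the planted schedule", {
  zm <- make_zonemap("lte")
  iti <- data.frame(zone = c("corner_sw", "burrow", "corner_se", "burrow"),
                    dwell_s = c(20, 30, 10, 15))
  s <- simulate_itinerary_track(zm, iti, seed = 77)
  path <- tempfile(fileext = ".csv")
  write_pose_table(s$pose, path)
  kin <- compute_kinematics(read_pose_table(path), smoothing_window = 1)
  occ <- zone_occupancy(kin, zm)
  secs <- setNames(occ$seconds, occ$zone)
  for (z in names(s$truth$zone_seconds)) {
    expect_lt(abs(secs[[z]] - s$truth$zone_seconds[[z]]), 1 / 30 + 1e-9)
  }
})

test_that("entry counting debounces boundary grazes", {
  zm <- make_zonemap("open_field")
  # never enters
  kin <- kin_from_path(rep(17, 100), rep(17, 100))
  expect_equal(count_entries(kin, zm, "corner_sw")$count, 0)

  # six constructed crossings into a corner, each sustained 1 s
  x <- rep(17, 0); y <- rep(17, 0)
  for (i in 1:6) {
    x <- c(x, rep(17, 30), rep(4, 30))
    y <- c(y, rep(17, 30), rep(4, 30))
  }
  kin2 <- kin_from_path(x, y)
  res <- count_entries(kin2, zm, "corner_sw")
  expect_equal(res$count, 6)
  expect_length(res$entry_times, 6)

  # a single-frame graze with a 0.2-s debounce does not count
  x <- c(rep(17, 30), 4, rep(17, 30)); y <- c(rep(17, 30), 4, rep(17, 30))
  expect_equal(count_entries(kin_from_path(x, y), zm, "corner_sw")$count, 0)
  expect_error(count_entries(kin, zm, "nosuch"), "unknown zone")
})

test_that("threat distance is the Euclidean distance to the rat-wall
           midpoint", {
  zm <- make_zonemap("corridor")
  kin <- kin_from_path(rep(0, 30), rep(12.5, 30))    # at the safe wall
  expect_equal(threat_distance(kin, zm)$mean_cm, 70)
  kin2 <- kin_from_path(rep(35, 30), rep(12.5, 30))  # corridor midpoint
  expect_equal(threat_distance(kin2, zm)$mean_cm, 35)

  # brute-force recomputation on a simulated trajectory
  s <- corridor_session(401)
  k <- pipeline_kin(s)
  td <- threat_distance(k, s$zonemap)
  oracle <- sqrt((k$head_x - 70)^2 + (k$head_y - 12.5)^2)
  expect_lt(max(abs(td$distance_cm - oracle)), 1e-9)
  expect_error(threat_distance(kin, make_zonemap("open_field")), "threat")
})

test_that("latency-to-enter trials are scored with the 61-s no-entry
           convention", {
  # planted entry time recovered within a frame
  tr <- simulate_lte_trial(entry_s = 12.4, seed = 5)
  lat <- score_lte_trial(compute_kinematics(tr$pose, smoothing_window = 1),
                         tr$zonemap)
  expect_lt(abs(lat - 12.4), 1 / 30 + 1e-9)

  # no entry in 60 s scores 61
  tr2 <- simulate_lte_trial(entry_s = NULL, seed = 6)
  expect_equal(score_lte_trial(compute_kinematics(tr2$pose, smoothing_window = 1),
                               tr2$zonemap), 61)

  # entry on the first frame scores one frame duration
  zm <- make_zonemap("lte")
  kin <- kin_from_path(rep(6.5, 90), rep(43.5, 90))
  expect_equal(score_lte_trial(kin, zm), 1 / 30)
  # a segment shorter than the limit with no entry is an error
  kin_short <- kin_from_path(rep(30, 60), rep(10, 60))
  expect_error(score_lte_trial(kin_short, zm), "shorter")
})

test_that("latency contrasts are balanced ON minus OFF means", {
  tt <- data.frame(trial_index = 1:10,
                   laser_on = rep(c(FALSE, TRUE), 5),
                   latency_s = rep(15, 10))
  expect_equal(lte_contrast(tt), 0)
  tt$latency_s <- ifelse(tt$laser_on, 10, 20)
  expect_equal(lte_contrast(tt), -10)
  # antisymmetric under swapping the condition labels
  tt2 <- tt; tt2$laser_on <- !tt2$laser_on
  expect_equal(lte_contrast(tt2), -lte_contrast(tt))
  expect_error(lte_contrast(tt[1:9, ]), "unbalanced")
})

test_that("a planted laser effect on latency is recovered across a cohort", {
  contrasts <- vapply(1:6, function(i) {
    lte_contrast(simulate_lte_block(base_latency_s = 25, on_effect_s = -8,
                                    sd_s = 3, seed = 100 + i)$trials)
  }, numeric(1))
  # planted -8 s within the cohort confidence interval
  expect_lt(abs(mean(contrasts) - (-8)),
            2.6 * sd(contrasts) / sqrt(length(contrasts)) + 1)
})

test_that("burrow preference requires strictly more burrow time than every
           corner", {
  zm <- make_zonemap("lte")
  # always in the burrow
  kin <- kin_from_path(rep(6.5, 300), rep(43.5, 300))
  expect_true(burrow_preference(kin, zm)$pass)
  # exact tie with one corner fails (strict inequality)
  kin2 <- kin_from_path(c(rep(6.5, 150), rep(41, 150)),
                        c(rep(43.5, 150), rep(41, 150)))
  pref <- burrow_preference(kin2, zm)
  expect_equal(unname(pref$seconds["burrow"]),
               unname(pref$seconds["corner_ne"]))
  expect_false(pref$pass)
})

test_that("a planted 63-of-69 screening cohort passes exactly 63", {
  zm <- make_zonemap("lte")
  pass <- logical(69)
  for (i in 1:69) {
    prefers <- i <= 63
    iti <- if (prefers) {
      data.frame(zone = c("burrow", "corner_sw", "corner_ne", "corner_se"),
                 dwell_s = c(24, 6, 6, 6))
    } else {
      data.frame(zone = c("burrow", "corner_sw", "corner_ne", "corner_se"),
                 dwell_s = c(5, 14, 6, 6))
    }
    s <- simulate_itinerary_track(zm, iti, seed = 500 + i)
    kin <- compute_kinematics(s$pose, smoothing_window = 1)
    pass[i] <- burrow_preference(kin, zm)$pass
  }
  expect_equal(sum(pass), 63)
  expect_equal(cohort_screen_fraction(sum(pass), 69), 91.3)
})

test_that("place-test preference subtracts pre-exposure occupancy", {
  zm <- make_zonemap("rtpt")
  same <- kin_from_path(c(rep(10, 150), rep(30, 150)), rep(10, 300))
  expect_equal(rtpt_preference(same, same, zm), 0)
  pre <- kin_from_path(c(rep(10, 300 * 30)), rep(10, 300 * 30))   # 300 s stim
  test <- kin_from_path(c(rep(10, 200 * 30), rep(30, 100 * 30)),
                        rep(10, 300 * 30))                        # 200 s stim
  expect_equal(rtpt_preference(pre, test, zm), -100)
  expect_error(rtpt_preference(pre, test, zm, stim_zone = "left"), "left")
})

test_that("epoch metrics contrast ON and OFF conditions", {
  zm <- make_zonemap("open_field")
  sched <- make_schedule(120, 30)   # OFF ON OFF ON
  # identical behavior in all epochs: all contrasts zero
  kin <- kin_from_path(rep(17, 120 * 30), rep(17, 120 * 30))
  b <- data.frame(label = character(), start_s = numeric(), end_s = numeric(),
                  duration_s = numeric(), mean_speed_cms = numeric(),
                  peak_speed_cms = numeric())
  em <- epoch_metrics(kin, b, sched, zm,
                      metrics = c("mean_speed_cms", "pct_freezing",
                                  "center_time_s"))
  expect_equal(em$contrast, c(0, 0, 0))

  # freezing planted only in ON epochs at 50% of epoch time
  b2 <- data.frame(label = "freeze", start_s = c(30, 90), end_s = c(45, 105),
                   duration_s = 15, mean_speed_cms = 0, peak_speed_cms = 0)
  em2 <- epoch_metrics(kin, b2, sched, zm, metrics = "pct_freezing")
  expect_equal(em2$contrast, 50)

  # a fifth epoch is excluded when n_epochs = 4
  sched5 <- make_schedule(150, 30)
  b3 <- rbind(b2, data.frame(label = "freeze", start_s = 121, end_s = 149,
                             duration_s = 28, mean_speed_cms = 0,
                             peak_speed_cms = 0))
  kin5 <- kin_from_path(rep(17, 150 * 30), rep(17, 150 * 30))
  em3 <- epoch_metrics(kin5, b3, sched5, zm, metrics = "pct_freezing",
                       n_epochs = 4)
  expect_equal(em3$contrast, 50)   # the epoch-5 freezing does not leak in

  # a single whole-session ON epoch reproduces whole-session metrics
  sched1 <- data.frame(epoch = 1:2, condition = c("ON", "OFF"),
                       start_s = c(0, 120), end_s = c(120, 120))
  em4 <- epoch_metrics(kin, b2, sched1, zm, metrics = "pct_freezing")
  expect_equal(em4$on, 100 * 30 / 120)
})
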