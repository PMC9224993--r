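mk_kin <- function(head_speed, tail_speed = head_speed, ntd = 7,
                   signed_v = NA_real_, rate = 30, bl = 7) {
  n <- length(head_speed)
  df <- data.frame(timestamp_s = (seq_len(n) - 1) / rate,
                   head_x = 0, head_y = 0,
                   head_speed_cms = head_speed,
                   tailbase_speed_cms = tail_speed,
                   nose_tail_distance_cm = ntd,
                   signed_velocity_to_threat_cms = signed_v)
  attr(df, "body_length_cm") <- bl
  attr(df, "frame_rate_hz") <- rate
  class(df) <- c("kinematics_series", "data.frame")
  df
}

test_that("freezing detection applies both speed conditions and the
           minimum duration", {
  # fully immobile 10-s session: one bout, 100% freezing
  kin <- mk_kin(rep(0, 300))
  b <- detect_freezing(kin)
  expect_equal(nrow(b), 1)
  expect_equal(b$start_s, 0)
  expect_equal(b$end_s, 10)
  expect_equal(attr(b, "percent_time_freezing"), 100)

  # a sub-threshold run of 0.30 s (9 frames) is below the 0.33-s minimum
  sp <- rep(1, 100); sp[40:48] <- 0
  expect_equal(nrow(detect_freezing(mk_kin(sp))), 0)
  # 10 frames (0.333 s) is retained
  sp[40:49] <- 0
  expect_equal(nrow(detect_freezing(mk_kin(sp))), 1)

  # both head AND tailbase must be slow
  expect_equal(nrow(detect_freezing(mk_kin(rep(0, 100), rep(1, 100)))), 0)

  # raising the speed ceiling never decreases percent freezing
  set.seed(7)
  sp <- abs(rnorm(600, 0.3, 0.3))
  pcts <- vapply(c(0.1, 0.25, 0.5, 1), function(thr) {
    attr(detect_freezing(mk_kin(sp), classifier_params(freeze_speed_max_cms = thr)),
         "percent_time_freezing")
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("stretch-attend detection uses the stretch and tail-speed gates", {
  # at exactly one body length there is no stretch
  expect_equal(nrow(detect_sap(mk_kin(rep(1, 100), rep(0, 100), ntd = 7))), 0)
  # 1.3 body lengths with slow tail for 1 s: one posture
  ntd <- rep(7, 100); ntd[30:59] <- 1.3 * 7
  b <- detect_sap(mk_kin(rep(1, 100), rep(0.5, 100), ntd = ntd))
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 1)
  # fast tail suppresses it
  expect_equal(nrow(detect_sap(mk_kin(rep(1, 100), rep(2, 100), ntd = ntd))), 0)
  expect_error(detect_sap(mk_kin(rep(1, 10), bl = 0)), "body length")
})

test_that("approach/escape detection is threshold-strict and antisymmetric
           under time reversal", {
  # stationary: nothing
  expect_equal(nrow(detect_runs(mk_kin(rep(0, 50), signed_v = rep(0, 50)))), 0)
  # 2 cm/s away from threat is below the 3 cm/s minimum
  expect_equal(nrow(detect_runs(mk_kin(rep(2, 50), signed_v = rep(-2, 50)))), 0)
  v <- rep(0, 120); v[11:40] <- 8; v[71:100] <- -12
  b <- detect_runs(mk_kin(abs(v), signed_v = v))
  expect_equal(b$label, c("approach", "escape"))
  # reversing time swaps the labels
  b2 <- detect_runs(mk_kin(abs(rev(v)), signed_v = -rev(v)))
  expect_equal(b2$label, c("approach", "escape"))
  expect_equal(b2[b2$label == "approach", "duration_s"],
               b[b$label == "escape", "duration_s"])
  expect_error(detect_runs(mk_kin(rep(1, 10))), "threat")
})

test_that("bout post-processing merges, filters, and is idempotent", {
  b <- data.frame(label = "freeze",
                  start_s = c(0, 1.05, 5), end_s = c(1, 2, 5.05),
                  duration_s = c(1, 0.95, 0.05),
                  mean_speed_cms = 0.1, peak_speed_cms = 0.2)
  expect_equal(postprocess_bouts(b, 0, 0)$start_s, b$start_s)
  m <- postprocess_bouts(b, merge_gap_s = 0.2, min_dur_s = 0.1)
  expect_equal(nrow(m), 1)
  expect_equal(m$start_s, 0)
  expect_equal(m$end_s, 2)
  expect_identical(postprocess_bouts(m, 0.2, 0.1), m)
  expect_error(postprocess_bouts(b, -1, 0), "non-negative")

  # random bout sets: merged total time matches a brute-force union oracle
  set.seed(11)
  for (rep in 1:5) {
    st <- sort(runif(12, 0, 30))
    b <- data.frame(label = "x", start_s = st, end_s = st + runif(12, 0.1, 2),
                    duration_s = NA, mean_speed_cms = 1, peak_speed_cms = 1)
    b$duration_s <- b$end_s - b$start_s
    gap <- 0.3
    m <- postprocess_bouts(b, merge_gap_s = gap)
    expect_equal(sum(m$duration_s) + gap * nrow(m),
                 oracle_merge_time(b, gap), tolerance = 0.02)
  }
})

test_that("planted behavior bouts are recovered exactly through the full
           pipeline", {
  for (seed in 403:405) {
    s <- corridor_session(seed)
    kin <- pipeline_kin(s)
    bouts <- classify_session(kin)
    iv <- s$truth$state_intervals
    for (lab in c("freeze", "sap", "approach", "escape")) {
      det <- bouts[bouts$label == lab, ]
      tru <- iv[iv$label == lab, ]
      expect_equal(nrow(det), nrow(tru),
                   info = sprintf("%s seed %d", lab, seed))
      if (nrow(tru) > 0 && nrow(det) == nrow(tru)) {
        err <- max(abs(det$start_s - tru$start_s),
                   abs(det$end_s - tru$end_s)) * 30
        expect_lte(err, 1 + 1e-6)
      }
    }
  }
})

test_that("percent-freezing robustness across minimum bout durations", {
  # all bouts longer than 1 s: identical vectors, r = 1
  kins <- lapply(c(0.2, 0.45, 0.7), function(f) {
    sp <- rep(1, 900)
    sp[seq_len(900 * f)] <- 0   # one long freeze block
    mk_kin(sp)
  })
  rb <- bout_robustness(kins)
  expect_equal(rb$r, 1)

  # all bouts between 0.33 and 1 s: the 1-s vector is all zero, r undefined
  kins2 <- lapply(c(3, 5, 7), function(k) {
    sp <- rep(1, 900)
    for (i in seq_len(k)) sp[(i * 100):(i * 100 + 14)] <- 0  # 0.5-s bouts
    mk_kin(sp)
  })
  rb2 <- bout_robustness(kins2)
  expect_true(is.na(rb2$r))
  expect_match(rb2$diagnostic, "degenerate")

  expect_error(bout_robustness(kins[1:2]), "3 sessions")
})
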