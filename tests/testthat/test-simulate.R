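test_that("configurations are validated", {
  expect_error(sim_config(duration_s = -1), "duration")
  expect_error(sim_config(frame_rate_hz = 0), "frame_rate")
  expect_error(sim_config(tuning_sign = 0.5), "tuning_sign")
  # burrow states cannot occur outside the latency-to-enter box
  expect_error(sim_config(arena = "epm",
                          state_weights = c(locomote = 1, burrow = 1)),
               "burrow")
  expect_error(sim_config(arena = "open_field",
                          state_weights = c(approach = 1)), "approach")
  # distance tuning needs a threat point
  expect_error(sim_config(arena = "open_field", tuning_sign = -1), "corridor")
})

test_that("a freeze-only configuration yields one full-session freeze", {
  cfg <- sim_config(arena = "open_field", duration_s = 60, seed = 5,
                    state_weights = c(freeze = 1), photometry = FALSE)
  s <- simulate_session(cfg)
  iv <- s$truth$state_intervals
  expect_equal(nrow(iv), 1)
  expect_equal(iv$label, "freeze")
  expect_gte(iv$end_s - iv$start_s, 0.99 * 60)
  kin <- pipeline_kin(s)
  expect_lt(max(kin$head_speed_cms), 0.25)
})

test_that("sessions are deterministic and physically consistent", {
  cfg <- sim_config(arena = "corridor", duration_s = 60, seed = 9)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$pose, s2$pose)
  expect_identical(s1$photometry, s2$photometry)
  expect_identical(s1$truth$state_intervals, s2$truth$state_intervals)

  # frame-to-frame displacement bounded by the configured top speed
  track <- interpolate_low_confidence(s1$pose)
  dt <- 1 / cfg$frame_rate_hz
  for (bp in c("nose", "ear_left", "ear_right", "tailbase")) {
    d <- sqrt(diff(track[[paste0(bp, "_x")]])^2 +
                diff(track[[paste0(bp, "_y")]])^2)
    expect_lte(max(d), cfg$max_speed_cms * dt)
  }

  # all high-confidence coordinates inside the arena polygon
  for (bp in c("nose", "ear_left", "ear_right", "tailbase")) {
    good <- s1$pose[[paste0(bp, "_likelihood")]] >= 0.9
    expect_true(all(point_in_polygon(s1$pose[[paste0(bp, "_x")]][good],
                                     s1$pose[[paste0(bp, "_y")]][good],
                                     s1$zonemap$bounds)))
  }

  # planted intervals are sorted, non-overlapping, within the session
  iv <- s1$truth$state_intervals
  expect_true(all(diff(iv$start_s) > 0))
  expect_true(all(iv$end_s[-nrow(iv)] <= iv$start_s[-1] + 1e-9))
  expect_gte(min(iv$start_s), 0)
  expect_lte(max(iv$end_s), 60 + 1e-9)
  expect_true(!is.unsorted(s1$truth$transient_times))
})

test_that("distance tuning of the transient rate has the planted structure", {
  # no modulation: realized transient trace uncorrelated with threat distance
  s0 <- cached("tune0", simulate_session(
    sim_config(arena = "corridor", duration_s = 600, seed = 31,
               tuning_sign = 0)))
  expect_equal(sd(s0$truth$latent_rate$rate), 0)
  tp <- s0$zonemap$threat_point
  kin <- pipeline_kin(s0, smoothing_window = 1)
  d <- sqrt((kin$head_x - tp[1])^2 + (kin$head_y - tp[2])^2)
  dsig <- approx(kin$timestamp_s, d, xout = s0$truth$transient_trace$timestamp_s,
                 rule = 2)$y
  expect_lt(abs(cor(s0$truth$transient_trace$value, dsig)), 0.1)

  # avoidance-like tuning: latent rate higher in the distal third
  s1 <- cached("tune_neg", simulate_session(
    sim_config(arena = "corridor", duration_s = 600, seed = 32,
               tuning_sign = -1)))
  kin <- pipeline_kin(s1, smoothing_window = 1)
  d <- sqrt((kin$head_x - tp[1])^2 + (kin$head_y - tp[2])^2)
  dr <- approx(kin$timestamp_s, d, xout = s1$truth$latent_rate$timestamp_s,
               rule = 2)$y
  rate <- s1$truth$latent_rate$rate
  far <- dr > 70 * 2 / 3
  expect_gt(mean(rate[far]), mean(rate[!far]))
})

test_that("with no noise and no transients the channels are proportional", {
  cfg <- sim_config(arena = "corridor", duration_s = 120, seed = 3,
                    noise_sd = 0, base_rate_hz = 0)
  s <- simulate_session(cfg)
  sig <- s$photometry$value[s$photometry$channel == 470]
  ref <- s$photometry$value[s$photometry$channel == 405]
  ratio <- sig / ref
  expect_lt(max(ratio) - min(ratio), 1e-9)
})

test_that("cohorts are seeded, labeled, and reproducible", {
  cfgs <- list(ctl = sim_config(arena = "open_field", duration_s = 40,
                                photometry = FALSE))
  c1 <- simulate_cohort(cfgs, n_per_group = 1, seed = 4)
  expect_length(c1$sessions, 1)
  c2 <- simulate_cohort(cfgs, n_per_group = 1, seed = 4)
  expect_identical(c1$sessions[[1]]$pose, c2$sessions[[1]]$pose)
  expect_error(simulate_cohort(list(a = cfgs$ctl, a = cfgs$ctl)),
               "duplicate")

  # heterogeneous freeze propensity yields spread in planted freezing time
  pf <- vapply(1:6, function(i) {
    cfg <- freezing_config(0.1 + 0.09 * i, duration_s = 120, seed = 50 + i,
                           photometry = FALSE)
    iv <- simulate_session(cfg)$truth$state_intervals
    sum(iv$end_s[iv$label == "freeze"] - iv$start_s[iv$label == "freeze"])
  }, numeric(1))
  expect_gt(var(pf), 0)
  expect_gt(max(pf) - min(pf), 10)
})

test_that("running the kinematic definitions on the emitted trajectory
           reproduces the planted labels", {
  s <- corridor_session(402)
  kin <- pipeline_kin(s)
  bouts <- classify_session(kin)
  iv <- s$truth$state_intervals
  for (lab in c("freeze", "sap", "approach", "escape")) {
    det <- bouts[bouts$label == lab, ]
    tru <- iv[iv$label == lab, ]
    expect_equal(nrow(det), nrow(tru), info = lab)
    if (nrow(tru) > 0) {
      err <- max(abs(det$start_s - tru$start_s), abs(det$end_s - tru$end_s))
      expect_lte(err * 30, 1 + 1e-6)
    }
  }
})
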