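mk_zframes <- function(z, rate = 30) {
  n <- length(z)
  df <- data.frame(frame = seq_len(n), timestamp_s = (seq_len(n) - 1) / rate,
                   zdff = z, sample_index = seq_len(n))
  class(df) <- c("zdff_frames", "data.frame")
  df
}

test_that("peri-event averaging aligns to onsets and drops edge events", {
  zf <- mk_zframes(rep(2.5, 600))
  pe <- peri_event_average(zf, c(8, 10, 12), window_s = 5)
  expect_equal(unname(pe$mean_trace), rep(2.5, length(pe$offsets_s)))
  expect_equal(pe$n_events, 3)
  # offsets symmetric about zero
  expect_equal(pe$offsets_s, -rev(pe$offsets_s))

  # planted bump 1 s after every event peaks at +1 s
  z <- rep(0, 1800)
  ev <- c(10, 25, 40)
  for (e in ev) z[round((e + 1) * 30) + 1] <- 5
  pe2 <- peri_event_average(mk_zframes(z), ev)
  expect_equal(pe2$offsets_s[which.max(pe2$mean_trace)], 1, tolerance = 1e-6)
  expect_equal(max(pe2$mean_trace), 5)

  # an event 2 s into the recording cannot fit a 5-s window
  expect_error(peri_event_average(mk_zframes(rep(0, 600)), 2, 5), "window")
  pe3 <- peri_event_average(mk_zframes(rep(0, 600)), c(2, 10), 5)
  expect_equal(pe3$dropped, 1)
})

test_that("peri-event mean of stationary noise stays near zero", {
  set.seed(3)
  z <- rnorm(18000)
  ev <- seq(20, 580, by = 20)
  pe <- peri_event_average(mk_zframes(z), ev)
  # per-offset means of unit-variance noise; 3.5 sigma allows for the
  # maximum over the ~300 offsets
  expect_lt(max(abs(pe$mean_trace)), 3.5 / sqrt(pe$n_events))
})

test_that("arm-entry responses contrast open and closed entries", {
  # identical signal after every entry: zero contrast
  zf <- mk_zframes(rep(1, 3000))
  entries <- data.frame(time_s = c(10, 30, 50, 70),
                        arm = c("open", "closed", "open", "closed"))
  expect_equal(arm_entry_response(zf, entries)$contrast, 0)

  # planted +1 bump in the second after open entries only
  z <- rep(0, 3000)
  for (e in c(10, 50)) z[(e * 30 + 1):((e + 1) * 30)] <- 1
  res <- arm_entry_response(mk_zframes(z), entries)
  expect_equal(res$contrast, 1, tolerance = 0.05)

  # an entry within 1 s of the end is excluded
  entries2 <- rbind(entries, data.frame(time_s = 99.8, arm = "open"))
  res2 <- arm_entry_response(mk_zframes(z), entries2)
  expect_equal(nrow(res2$per_entry), 4)
  expect_error(arm_entry_response(zf, data.frame(time_s = 1, arm = "open")),
               "both arm types")
})

test_that("spatial binning recovers exact linear tuning and rejects null
           tuning", {
  s <- corridor_session(406, duration_s = 300)
  kin <- pipeline_kin(s)
  bouts <- classify_session(kin)
  skip_if(sum(bouts$label == "approach") == 0)

  # signal exactly linear in distance from the safe wall (r deviates from
  # +-1 only because occupancy centroids differ slightly from bin centers)
  zf_lin <- mk_zframes(2 - 0.05 * kin$head_x)
  tun <- spatial_bin_dff(zf_lin, kin, bouts, s$zonemap)
  expect_equal(tun$approach$r, -1, tolerance = 0.005)
  zf_lin2 <- mk_zframes(0.05 * kin$head_x)
  tun2 <- spatial_bin_dff(zf_lin2, kin, bouts, s$zonemap)
  expect_equal(tun2$approach$r, 1, tolerance = 0.005)

  # sample counts are conserved within the mask
  expect_equal(sum(tun$approach$bins$n), tun$approach$n_samples)

  # the reported r equals a brute-force Pearson on (center, mean) pairs
  b <- tun$approach$bins
  ok <- !is.na(b$mean_zdff)
  expect_equal(tun$approach$r,
               oracle_pearson(b$center_cm[ok], b$mean_zdff[ok])$r,
               tolerance = 1e-12)

  # position-independent signal: weak correlation
  set.seed(8)
  tun3 <- spatial_bin_dff(mk_zframes(rnorm(nrow(kin))), kin, bouts, s$zonemap)
  expect_lt(abs(tun3$approach$r_sample), 0.2)
})

test_that("zone means partition the corridor and recombine exactly", {
  s <- corridor_session(406, duration_s = 300)
  kin <- pipeline_kin(s)
  # safe third of a 70-cm corridor spans 0-23.33 cm from the safe wall
  expect_equal(70 / 3, 23.333333, tolerance = 1e-6)

  # uniform signal: zero contrast
  zm0 <- zone_mean_dff(mk_zframes(rep(1.5, nrow(kin))), kin, s$zonemap)
  expect_equal(zm0$contrast, 0)

  # planted +0.5 offset in the distal two-thirds
  z <- ifelse(kin$head_x > 70 / 3, 0.5, 0)
  zm1 <- zone_mean_dff(mk_zframes(z), kin, s$zonemap)
  expect_equal(zm1$contrast, 0.5)

  # occupancy-weighted recombination equals the whole-corridor mean
  set.seed(9)
  z2 <- rnorm(nrow(kin))
  zm2 <- zone_mean_dff(mk_zframes(z2), kin, s$zonemap)
  wmean <- (zm2$safe_mean * zm2$safe_n + zm2$threat_mean * zm2$threat_n) /
    (zm2$safe_n + zm2$threat_n)
  expect_equal(wmean, mean(z2), tolerance = 1e-9)
})

test_that("the speed control correlation behaves at its extremes", {
  s <- corridor_session(406, duration_s = 300)
  kin <- pipeline_kin(s)
  sp <- kin$head_speed_cms
  # signal equal to speed: r = 1
  expect_equal(speed_dff_control(mk_zframes(sp), sp)$r, 1, tolerance = 1e-12)
  # shuffled signal: negligible correlation
  set.seed(4)
  r0 <- speed_dff_control(mk_zframes(sample(sp)), sp)$r
  expect_lt(abs(r0), 2 / sqrt(length(sp)) * 3)
  expect_error(speed_dff_control(mk_zframes(sp), rep(1, length(sp))),
               "constant")
})

test_that("distance tuning dominates the speed control in tuned sessions", {
  s <- cached("tuned_ctl", simulate_session(
    sim_config(arena = "corridor", duration_s = 600, seed = 81,
               tuning_sign = -1)))
  kin <- pipeline_kin(s)
  ph <- process_photometry(s$photometry, kin$timestamp_s)
  r_speed <- abs(speed_dff_control(ph$frames, kin$head_speed_cms)$r)
  d <- sqrt((kin$head_x - 70)^2 + (kin$head_y - 12.5)^2)
  ok <- !is.na(ph$frames$zdff)
  r_dist <- abs(cor(d[ok], ph$frames$zdff[ok]))
  expect_lt(r_speed, r_dist)
})
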