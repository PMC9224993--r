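mk_rec <- function(sig, ref, dt = 0.05) {
  n <- length(sig)
  photometry_recording(data.frame(
    timestamp_s = seq(0, by = dt, length.out = 2 * n),
    channel = rep(c(470L, 405L), n),
    value = as.vector(rbind(sig, ref))))
}

test_that("de-interleaving splits alternating channels and aligns the
           reference", {
  rec <- mk_rec(1:5, 11:15)
  de <- deinterleave(rec)
  expect_equal(nrow(de$signal), 5)
  expect_equal(nrow(de$reference), 5)
  expect_equal(de$signal$value, 1:5)

  # constant reference interpolates to that constant everywhere
  de2 <- deinterleave(mk_rec(rnorm(20) + 10, rep(7, 20)))
  expect_equal(de2$reference$value, rep(7, 20))

  # consecutive same-channel tags are rejected
  bad <- as.data.frame(mk_rec(1:5, 11:15))
  bad$channel[2] <- 470L
  expect_error(deinterleave(photometry_recording(bad)), "alternating")

  # simulated stream reconstructs the planted channels
  s <- cached("phot1", simulate_session(
    sim_config(arena = "corridor", duration_s = 300, seed = 61)))
  de3 <- deinterleave(s$photometry)
  raw_sig <- s$photometry$value[s$photometry$channel == 470]
  expect_equal(de3$signal$value, raw_sig)
})

test_that("reference correction removes shared structure exactly for
           linear channels", {
  set.seed(1)
  x <- 100 + cumsum(rnorm(500, 0, 0.5))
  # reference identical to signal: dff ~ 0
  d1 <- correct_reference(data.frame(timestamp_s = 1:500, value = x),
                          data.frame(timestamp_s = 1:500, value = x))
  expect_lt(max(abs(d1$dff)), 1e-9)
  # exact linear relation: residual zero
  d2 <- correct_reference(data.frame(timestamp_s = 1:500, value = 2 * x + 3),
                          data.frame(timestamp_s = 1:500, value = x))
  expect_lt(max(abs(d2$dff)), 1e-12)
  expect_error(correct_reference(
    data.frame(timestamp_s = 1:500, value = x),
    data.frame(timestamp_s = 1:500, value = rep(1, 500))), "zero-variance")
  expect_error(correct_reference(
    data.frame(timestamp_s = 1:50, value = x[1:50]),
    data.frame(timestamp_s = 1:50, value = x[1:50])), "100")
})

test_that("corrected signal recovers the planted transient trace and beats
           the raw signal", {
  for (seed in 61:63) {
    s <- cached(sprintf("phot%d", seed - 60), simulate_session(
      sim_config(arena = "corridor", duration_s = 300, seed = seed)))
    ph <- process_photometry(s$photometry)
    tru <- s$truth$transient_trace$value
    r_corr <- cor(ph$dff$zdff, tru)
    r_raw <- cor(s$photometry$value[s$photometry$channel == 470], tru)
    expect_gt(r_corr, 0.95)
    expect_lt(r_raw, r_corr)
  }
})

test_that("correction is invariant to a common gain on both channels", {
  s <- cached("phot1", simulate_session(
    sim_config(arena = "corridor", duration_s = 300, seed = 61)))
  de <- deinterleave(s$photometry)
  d1 <- correct_reference(de$signal, de$reference)
  sig2 <- de$signal; sig2$value <- sig2$value * 3.7
  ref2 <- de$reference; ref2$value <- ref2$value * 3.7
  d2 <- correct_reference(sig2, ref2)
  expect_lt(max(abs(d1$dff - d2$dff)), 1e-9)
})

test_that("z-scoring normalizes to mean 0 and sd 1 over the window", {
  # a symmetric two-level series maps to symmetric z-levels (+-1 up to the
  # sample-sd normalization)
  d <- data.frame(timestamp_s = 1:40, dff = rep(c(-1, 1), 20))
  class(d) <- c("dff_series", "data.frame")
  z <- zscore_dff(d)
  lev <- sort(unique(z$zdff))
  expect_length(lev, 2)
  expect_equal(lev[1], -lev[2])
  expect_equal(lev[2], 1, tolerance = 0.02)

  set.seed(2)
  d2 <- data.frame(timestamp_s = seq(0, 99.9, 0.1), dff = rnorm(1000))
  class(d2) <- c("dff_series", "data.frame")
  z2 <- zscore_dff(d2)
  expect_lt(abs(mean(z2$zdff)), 1e-9)
  expect_lt(abs(sd(z2$zdff) - 1), 1e-9)
  # windowed normalization applies window statistics to the whole series
  z3 <- zscore_dff(d2, window = c(0, 50))
  sel <- d2$timestamp_s <= 50
  expect_lt(abs(mean(z3$zdff[sel])), 1e-9)

  d3 <- data.frame(timestamp_s = 1:10, dff = rep(2, 10))
  class(d3) <- c("dff_series", "data.frame")
  expect_error(zscore_dff(d3), "variance")
})

test_that("frame alignment picks the nearest sample within one period", {
  z <- data.frame(timestamp_s = seq(0, 10, 0.1), dff = 0,
                  zdff = sin(seq(0, 10, 0.1)))
  class(z) <- c("dff_series", "data.frame")
  # identical clocks: identity mapping
  a1 <- align_to_frames(z, z$timestamp_s)
  expect_equal(a1$zdff, z$zdff)
  # 30-Hz frames against 10-Hz samples: each sample serves ~3 frames
  fts <- seq(0, 10, 1 / 30)
  a2 <- align_to_frames(z, fts)
  expect_true(all(!is.na(a2$zdff)))
  expect_lte(max(table(a2$sample_index)), 4)
  # max alignment error bounded by half a sample period
  err <- abs(z$timestamp_s[a2$sample_index] - fts)
  expect_lte(max(err), 0.05 + 1e-9)
  # frames outside coverage are flagged missing
  a3 <- align_to_frames(z, c(5, 11.5))
  expect_true(is.na(a3$zdff[2]))
  expect_error(align_to_frames(z, c(100, 101)), "overlap")
})

test_that("with noise only, the corrected z-scored series is white", {
  cfg <- sim_config(arena = "corridor", duration_s = 600, seed = 71,
                    base_rate_hz = 0, artifact_sd = 0)
  s <- simulate_session(cfg)
  ph <- process_photometry(s$photometry)
  z <- ph$dff$zdff
  rho <- cor(z[-1], z[-length(z)])
  expect_lt(abs(rho), 0.1)
})
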