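# Shared fixtures (cached simulated sessions) and independent brute-force
# oracles used to verify the statistical routines.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.session_cache[[key]])) .session_cache[[key]] <- force(expr)
  .session_cache[[key]]
}

# Full pose pipeline on a simulated session, as the analyses run it.
pipeline_kin <- function(session, smoothing_window = 5) {
  tr <- interpolate_low_confidence(session$pose)
  compute_kinematics(tr, smoothing_window,
                     threat_point = session$zonemap$threat_point)
}

corridor_session <- function(seed, duration_s = 120, ...) {
  cached(sprintf("corr_%d_%d", seed, duration_s), {
    simulate_session(sim_config(arena = "corridor", duration_s = duration_s,
                                seed = seed, ...))
  })
}

# --- independent oracles ----------------------------------------------------

# Pooled-variance two-sample t-test from the textbook formulas.
oracle_ttest <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson r from the covariance formula, p via the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Benjamini-Hochberg step-up computed directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Interval union by brute force on a fine grid (for bout merging).
oracle_merge_time <- function(bouts, gap, grid = 0.005) {
  if (nrow(bouts) == 0) return(0)
  lo <- min(bouts$start_s) - 1; hi <- max(bouts$end_s) + 1
  g <- seq(lo, hi, by = grid)
  covered <- rep(FALSE, length(g))
  for (i in seq_len(nrow(bouts))) {
    covered <- covered | (g >= bouts$start_s[i] - 1e-12 &
                            g < bouts$end_s[i] + gap - 1e-12)
  }
  sum(covered) * grid
}

# Straight-line pose track moving at constant velocity, with all bodyparts
# coincident offsets (used for analytic kinematics checks).
synthetic_track <- function(n = 200, v = c(2, 0), start = c(5, 5),
                            rate = 30, lik = 1) {
  t <- (seq_len(n) - 1) / rate
  x <- start[1] + v[1] * t
  y <- start[2] + v[2] * t
  df <- data.frame(frame = seq_len(n), timestamp_s = t)
  offs <- list(nose = c(1, 0), ear_left = c(0.5, 0.5),
               ear_right = c(0.5, -0.5), tailbase = c(-1, 0))
  for (bp in names(offs)) {
    df[[paste0(bp, "_x")]] <- x + offs[[bp]][1]
    df[[paste0(bp, "_y")]] <- y + offs[[bp]][2]
    df[[paste0(bp, "_likelihood")]] <- lik
  }
  pose_track(df)
}

# Kinematics-like frame for zone tests: a head path on a frame clock.
kin_from_path <- function(x, y, rate = 30) {
  n <- length(x)
  df <- data.frame(timestamp_s = (seq_len(n) - 1) / rate,
                   head_x = x, head_y = y,
                   head_speed_cms = c(sqrt(diff(x)^2 + diff(y)^2) * rate, 0),
                   tailbase_speed_cms = 0,
                   nose_tail_distance_cm = 7,
                   signed_velocity_to_threat_cms = NA_real_)
  attr(df, "body_length_cm") <- 7
  attr(df, "frame_rate_hz") <- rate
  class(df) <- c("kinematics_series", "data.frame")
  df
}
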