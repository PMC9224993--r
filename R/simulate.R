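## Synthetic session generator.
##
## Sessions are built from a semi-Markov state machine over defensive
## behavior states (locomote, pause, freeze, stretch-attend, approach,
## escape, burrow dwell).  Special states always alternate with a short
## "pause" hub state (slow ambling at 1 cm/s) so that every classifier
## threshold crossing happens between a known pair of speeds.  Raw motion
## transitions are shifted by the analytic step response of the downstream
## boxcar-smoothed forward-difference speed estimator so that the planted
## bout boundaries are recoverable to within one frame.  Turning pivots
## about the head centroid, which keeps orienting movements out of the
## signed-velocity-to-threat channel.

#' Simulation configuration
#'
#' Defaults describe a typical 10-min assay session at 30 frames/s with a
#' 7-cm mouse.  Behavior-state dwell times are exponential except freezing,
#' which is log-normal (median `freeze_median_s`, log-sd `freeze_sigma`) to
#' give a realistic heavy-tailed bout distribution.  Photometry follows a
#' 20-Hz stream alternating between a 470-nm calcium channel and a 405-nm
#' reference channel; both share a double-exponential bleach and a slow
#' motion artifact, while calcium transients (Poisson events convolved with
#' a rise/decay kernel) enter the signal channel only.  In the corridor
#' arena the transient rate is modulated by distance to the threat:
#' `tuning_sign = +1` raises the rate near the rat (pan-neuronal-like),
#' `-1` raises it far from the rat (CCK-like), `0` disables modulation.
#'
#' @param arena arena name, see [arena_dims()].
#' @param duration_s session length, seconds.
#' @param frame_rate_hz video frame rate (default 30).
#' @param seed RNG seed for the session.
#' @param state_weights named non-negative weights over special states
#'   (subset of `locomote`, `freeze`, `sap`, `approach`, `escape`,
#'   `burrow`); states unavailable in the arena must be absent or zero.
#' @param freeze_median_s,freeze_sigma log-normal freeze dwell parameters.
#' @param dwell_means_s named mean dwell times (s) for the exponential
#'   states (`pause`, `locomote`, `sap`, `approach`, `escape`, `burrow`).
#' @param locomotion_speed_cms c(mean, sd) of locomotion speed.
#' @param pause_speed_cms ambling speed of the pause hub state.
#' @param approach_speed_cms,escape_speed_cms run speeds (cm/s).
#' @param body_length_cm nose-tailbase distance.
#' @param sap_stretch planted stretch in body lengths (default 1.35, above
#'   the 1.2 classification threshold).
#' @param jitter_sd_cm tracking jitter added to every coordinate.
#' @param dropout_prob per-frame per-bodypart probability of a tracking
#'   glitch (coordinate teleports inside the arena, likelihood drops).
#' @param max_speed_cms physical cap: no bodypart moves faster than this
#'   between consecutive frames of the clean trajectory.
#' @param smooth_window boxcar width (frames) the downstream kinematics are
#'   expected to use; boundary shifts are calibrated against it.
#' @param epoch_s laser epoch length for the ON/OFF schedule (default 120).
#' @param epoch_effects optional named multipliers applied to state weights
#'   while the laser is ON (e.g. `list(freeze = 8)`).
#' @param photometry logical; simulate the two-channel recording.
#' @param photometry_rate_hz total interleaved sample rate (default 20).
#' @param base_rate_hz baseline calcium transient rate.
#' @param tuning_sign -1, 0 or +1 distance-to-threat rate modulation.
#' @param tuning_depth modulation depth in (0, 1).
#' @param tuning_states optional character vector of behavior states; when
#'   given, modulation applies only during those states.
#' @param tuning_lead_s anticipatory lead of state-gated modulation: the
#'   rate change begins this many seconds before each gated bout.
#' @param transient_amp,transient_rise_s,transient_decay_s kernel shape
#'   (peak dF/F amplitude, rise and decay time constants).
#' @param bleach c(a1, tau1, a2, tau2) double-exponential bleach; the
#'   constant term is `1 - a1 - a2`.
#' @param channel_gain reference channel gain relative to signal.
#' @param artifact_sd,artifact_tau_s shared motion artifact (fractional sd,
#'   AR(1) time constant).
#' @param noise_sd additive per-channel white noise (raw units).
#' @param f0 baseline fluorescence (raw units).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(arena = "open_field",
                       duration_s = 600,
                       frame_rate_hz = 30,
                       seed = 1,
                       state_weights = NULL,
                       freeze_median_s = 2,
                       freeze_sigma = 0.8,
                       dwell_means_s = c(pause = 0.8, locomote = 2.5,
                                         sap = 1.5, approach = 1.0,
                                         escape = 0.8, burrow = 6),
                       locomotion_speed_cms = c(mean = 8, sd = 2),
                       pause_speed_cms = 1,
                       approach_speed_cms = 15,
                       escape_speed_cms = 25,
                       body_length_cm = 7,
                       sap_stretch = 1.35,
                       jitter_sd_cm = 0.005,
                       dropout_prob = 0.01,
                       max_speed_cms = 70,
                       smooth_window = 5,
                       epoch_s = 120,
                       epoch_effects = NULL,
                       photometry = TRUE,
                       photometry_rate_hz = 20,
                       base_rate_hz = 2,
                       tuning_sign = 0,
                       tuning_depth = 0.8,
                       tuning_states = NULL,
                       tuning_lead_s = 1.5,
                       transient_amp = 0.05,
                       transient_rise_s = 0.1,
                       transient_decay_s = 1,
                       bleach = c(a1 = 0.25, tau1 = 60, a2 = 0.15, tau2 = 500),
                       channel_gain = 0.6,
                       artifact_sd = 0.02,
                       artifact_tau_s = 0.3,
                       noise_sd = 0.1,
                       f0 = 100) {
  arena <- match.arg(arena, c("open_field", "epm", "lte", "corridor", "rtpt"))
  .assert(duration_s > 0, "duration_s must be positive")
  .assert(frame_rate_hz > 0, "frame_rate_hz must be positive")
  .assert(tuning_sign %in% c(-1, 0, 1), "tuning_sign must be -1, 0 or +1")
  .assert(all(dwell_means_s > 0) && freeze_median_s > 0 && freeze_sigma > 0,
          "dwell parameters must be strictly positive")
  .assert(transient_rise_s > 0 && transient_decay_s > transient_rise_s,
          "transient kernel needs 0 < rise < decay")
  if (is.null(state_weights)) {
    state_weights <- switch(arena,
      open_field = c(locomote = 0.45, freeze = 0.25, sap = 0.10),
      epm        = c(locomote = 0.50, freeze = 0.20, sap = 0.10),
      rtpt       = c(locomote = 0.55, freeze = 0.15, sap = 0.05),
      lte        = c(locomote = 0.40, freeze = 0.15, sap = 0.05, burrow = 0.20),
      corridor   = c(locomote = 0.35, freeze = 0.15, sap = 0.10,
                     approach = 0.12, escape = 0.12)
    )
  }
  allowed <- c("locomote", "freeze", "sap",
               if (arena == "corridor") c("approach", "escape"),
               if (arena == "lte") "burrow")
  bad <- setdiff(names(state_weights)[state_weights > 0], allowed)
  .assert(length(bad) == 0,
          sprintf("state(s) %s cannot occur in arena '%s'",
                  paste(bad, collapse = ", "), arena))
  .assert(all(state_weights >= 0) && sum(state_weights) > 0,
          "state_weights must be non-negative with positive sum")
  if (tuning_sign != 0) {
    .assert(arena == "corridor",
            "distance-to-threat tuning requires the corridor arena")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## --- boundary-shift calibration -------------------------------------------
## The downstream speed estimate at frame i is the mean of the raw per-frame
## speeds over [i-h, i+h] (boxcar width w = 2h+1 on positions, then forward
## difference).  For a raw transition between constant speeds v0 -> v1 this
## gives the frame shift to apply to the raw transition so that the
## classifier condition first flips exactly at the planted boundary.
.boundary_shift <- function(v0, v1, cond, w) {
  h <- (w - 1L) %/% 2L
  for (k in 0:w) {
    m <- (v0 * (w - k) + v1 * k) / w
    if (cond(m)) return(h + 1L - k)
  }
  0L
}

## Dwell samplers (frames)
.sample_dwell <- function(state, cfg, rate) {
  ## the pause floor leaves room for a full in-place reorientation plus the
  ## stretch-posture pre/post-roll inside a single pause
  min_f <- c(pause = 26, locomote = 15, freeze = 12, sap = 15,
             approach = 12, escape = 10, burrow = 45)
  s <- if (state == "freeze") {
    stats::rlnorm(1, meanlog = log(cfg$freeze_median_s), sdlog = cfg$freeze_sigma)
  } else {
    stats::rexp(1, 1 / cfg$dwell_means_s[[state]])
  }
  max(min_f[[state]], round(s * rate))
}

## Sample the planted bout sequence.  Returns data.frame(state, f0, f1)
## with 1-based frame indices, f1 exclusive, alternating pause / special.
.sample_bouts <- function(cfg, n, rate, schedule) {
  specials <- names(cfg$state_weights)[cfg$state_weights > 0]
  weights_at <- function(f) {
    w <- cfg$state_weights[specials]
    if (!is.null(cfg$epoch_effects) && nrow(schedule) > 0) {
      t <- (f - 1) / rate
      on <- any(schedule$condition == "ON" & schedule$start_s <= t &
                  t < schedule$end_s)
      if (on) {
        for (s in intersect(names(cfg$epoch_effects), specials)) {
          w[s] <- w[s] * cfg$epoch_effects[[s]]
        }
      }
    }
    w
  }
  ## degenerate chain: with freezing as the only permitted state the whole
  ## session is one freeze bout
  if (identical(specials, "freeze")) {
    return(data.frame(state = "freeze", f0 = 1L, f1 = n + 1L, speed = 0))
  }
  rows <- list(); f <- 1L; x <- NA_real_  # x tracked for corridor clipping
  if (cfg$arena == "corridor") x <- 30
  want_pause <- TRUE
  while (f <= n) {
    if (want_pause) {
      d <- .sample_dwell("pause", cfg, rate)
      rows[[length(rows) + 1L]] <- data.frame(state = "pause", f0 = f,
                                              f1 = f + d, speed = cfg$pause_speed_cms)
      f <- f + d
      want_pause <- FALSE
    } else {
      w <- weights_at(f)
      st <- sample(specials, 1, prob = w)
      d <- .sample_dwell(st, cfg, rate)
      sp <- switch(st,
        locomote = max(4, stats::rnorm(1, cfg$locomotion_speed_cms[["mean"]],
                                       cfg$locomotion_speed_cms[["sd"]])),
        approach = cfg$approach_speed_cms,
        escape = cfg$escape_speed_cms,
        freeze = 0, sap = 0, burrow = 10)
      ok <- TRUE
      if (st == "approach") {
        avail <- floor((62 - x) / sp * rate)
        if (avail < 12) ok <- FALSE else { d <- min(d, avail) }
      } else if (st == "escape") {
        avail <- floor((x - 6) / sp * rate)
        if (avail < 10) ok <- FALSE else { d <- min(d, avail) }
      } else if (cfg$arena == "corridor" && st %in% c("locomote", "sap")) {
        ## near the rat the radial component of lateral motion exceeds the
        ## 3 cm/s run threshold; keep these states in the far two-thirds
        if (x > 45) ok <- FALSE
        if (st == "locomote") sp <- 8
      }
      ## specials must end well before the session so their realization
      ## (including the stretch pre/post-roll) fits; otherwise pause fills
      if (!ok || f + d > n - 15) {
        st <- "pause"; sp <- cfg$pause_speed_cms
        if (f + d > n - 15) d <- n + 1L - f
      }
      ## runs are realized over [f0 + shift_on, f1 + shift_off); track x
      ## with the effective raw duration so clipping stays exact
      if (st %in% c("approach", "escape")) {
        don <- .boundary_shift(0, sp, function(m) m > 3, cfg$smooth_window)
        doff <- .boundary_shift(sp, 0, function(m) m <= 3, cfg$smooth_window)
        eff <- max(0, d - don + doff)
        if (st == "approach") x <- x + sp * eff / rate
        if (st == "escape") x <- x - sp * eff / rate
      }
      rows[[length(rows) + 1L]] <- data.frame(state = st, f0 = f, f1 = f + d,
                                              speed = sp)
      f <- f + d
      want_pause <- TRUE
    }
  }
  b <- do.call(rbind, rows)
  b <- b[b$f0 <= n, , drop = FALSE]
  b$f1[nrow(b)] <- n + 1L
  if (b$state[nrow(b)] != "pause") {
    b$state[nrow(b)] <- "pause"
    b$speed[nrow(b)] <- cfg$pause_speed_cms
  }
  rownames(b) <- NULL
  b
}

## Raw-transition shifts per planted boundary (vector, one per boundary
## between bout k and k+1).  Thresholds: 0.25 cm/s for freeze boundaries,
## 3 cm/s (on the threat-axis component) for approach/escape boundaries.
.boundary_shifts <- function(bouts, cfg) {
  w <- cfg$smooth_window
  nb <- nrow(bouts)
  if (nb < 2) return(integer(0))
  shifts <- integer(nb - 1L)
  for (k in seq_len(nb - 1L)) {
    s0 <- bouts$state[k]; s1 <- bouts$state[k + 1L]
    v0 <- bouts$speed[k]; v1 <- bouts$speed[k + 1L]
    if (s1 == "freeze") {
      shifts[k] <- .boundary_shift(v0, 0, function(m) m < 0.25, w)
    } else if (s0 == "freeze") {
      shifts[k] <- .boundary_shift(0, v1, function(m) m >= 0.25, w)
    } else if (s1 %in% c("approach", "escape")) {
      ## threat-axis component: pause/locomote contribute ~0
      shifts[k] <- .boundary_shift(0, v1, function(m) m > 3, w)
    } else if (s0 %in% c("approach", "escape")) {
      shifts[k] <- .boundary_shift(v0, 0, function(m) m <= 3, w)
    } else {
      shifts[k] <- 0L
    }
  }
  shifts
}

## Waypoint sampling margins keep the whole emitted pose inside the arena
## for straight travel (the tailbase sits 0.65 body lengths behind the head).
.way_margin <- 5.5

## Project points into the arena polygon (axis-aligned union of rectangles).
## Emitted bodyparts are clamped so occluded parts pressed against a wall
## never leave the arena; the head path itself always stays inside.
.clamp_to_arena <- function(xy, zm) {
  rects <- if (zm$arena == "epm") {
    list(c(0, 67, 30, 37), c(30, 37, 0, 67))
  } else {
    b <- c(range(zm$bounds$x), range(zm$bounds$y))
    list(b)
  }
  out <- xy
  inside <- point_in_polygon(xy[, 1], xy[, 2], zm$bounds)
  for (i in which(!inside)) {
    best <- NULL; bd <- Inf
    for (r in rects) {
      p <- c(min(max(xy[i, 1], r[1]), r[2]), min(max(xy[i, 2], r[3]), r[4]))
      d <- sum((p - xy[i, ])^2)
      if (d < bd) { bd <- d; best <- p }
    }
    out[i, ] <- best
  }
  out
}

.sample_waypoint <- function(cfg, cur) {
  d <- arena_dims(cfg$arena)
  m <- .way_margin
  if (cfg$arena == "epm") {
    aw <- 7; al <- 30
    arm <- sample(c("ol", "or", "cb", "ct", "c"), 1)
    ## waypoints hug the arm centerline so the nose and ears stay inside
    ## the 7-cm-wide arms even while pivoting
    p <- switch(arm,
      ol = c(stats::runif(1, m, al), stats::runif(1, al + 3, al + aw - 3)),
      or = c(stats::runif(1, al + aw, 2 * al + aw - m),
             stats::runif(1, al + 3, al + aw - 3)),
      cb = c(stats::runif(1, al + 3, al + aw - 3), stats::runif(1, m, al)),
      ct = c(stats::runif(1, al + 3, al + aw - 3),
             stats::runif(1, al + aw, 2 * al + aw - m)),
      c  = c(stats::runif(1, al + 3, al + aw - 3),
             stats::runif(1, al + 3, al + aw - 3)))
    return(p)
  }
  c(stats::runif(1, m, d[1] - m), stats::runif(1, m, d[2] - m))
}

## In the EPM movement is routed via the maze center so the path stays
## inside the cross.
.route_legs <- function(cfg, cur, target) {
  if (cfg$arena != "epm") return(list(target))
  ctr <- c(33.5, 33.5)
  same_band <- function(p, q) {
    (abs(p[1] - 33.5) <= 2.5 && abs(q[1] - 33.5) <= 2.5) ||
      (abs(p[2] - 33.5) <= 2.5 && abs(q[2] - 33.5) <= 2.5)
  }
  if (same_band(cur, target)) list(target) else list(ctr, target)
}

## Constant-speed amble: straight vertical segments with semicircular
## velocity turnarounds.  The speed never changes, so the smoothed speed
## never dips (freeze-boundary guards stay valid), and alternating the turn
## side bounds the cumulative lateral drift to a fraction of a centimeter.
## `state` carries (psi, dir, parity, turn_remaining) across calls.
.amble <- function(p0, band, sp, nf, dt, state) {
  rho <- 8                                  # turn rate, rad/s
  psi <- state$psi; dir <- state$dir; parity <- state$parity
  rem <- state$rem
  y <- p0[2]
  vel <- matrix(0, nf, 2)
  if (y < band[1]) dir <- 1 else if (y > band[2]) dir <- -1
  if (rem <= 0) psi <- pi / 2 * dir
  for (i in seq_len(nf)) {
    if (rem > 0) {
      dpsi <- min(rho * dt, rem)
      psi <- psi + parity * dpsi
      rem <- rem - dpsi
      if (rem <= 0) {
        dir <- -dir
        psi <- pi / 2 * dir
        parity <- -parity
      }
    } else {
      yn <- y + sp * sin(psi) * dt
      if ((dir > 0 && yn > band[2]) || (dir < 0 && yn < band[1])) rem <- pi
    }
    vel[i, ] <- sp * c(cos(psi), sin(psi))
    y <- y + vel[i, 2] * dt
  }
  list(vel = vel, state = list(psi = psi, dir = dir, parity = parity, rem = rem))
}

## --- trajectory realization ------------------------------------------------
## Returns head positions, per-frame heading, and SAP override info.
.realize_trajectory <- function(bouts, shifts, cfg, n, rate) {
  dt <- 1 / rate
  d <- arena_dims(cfg$arena)
  BL <- cfg$body_length_cm
  a_n <- 0.35 * BL
  omega_max <- 12         # rad/s, pivot about the head
  vel <- matrix(0, n, 2)
  theta <- numeric(n)
  start <- switch(cfg$arena,
    corridor = c(30, d[2] / 2), lte = c(23.5, 12), epm = c(33.5, 33.5),
    rtpt = c(d[1] / 4, d[2] / 2), c(d[1] / 2, d[2] / 2))
  nb <- nrow(bouts)
  raw0 <- pmax(1L, pmin(n, bouts$f0 + c(0L, shifts)))
  raw1 <- c(raw0[-1L], n + 1L)
  pos <- start
  th <- if (cfg$arena == "corridor") pi / 2 else 0
  sap_info <- list()
  amble_state <- list(psi = pi / 2, dir = 1, parity = 1, rem = 0)

  ## entry heading required by a bout, given the position it starts from
  entry_heading <- function(k, pos) {
    st <- bouts$state[k]
    if (st == "approach") return(0)
    if (st == "escape") return(pi)
    if (st == "sap") {
      if (cfg$arena == "corridor") {
        return(if (pos[2] <= d[2] / 2) pi / 2 else -pi / 2)
      }
      if (cfg$arena == "epm") return(NA_real_)  # snapped to the arm axis
      v <- d / 2 - pos
      if (sqrt(sum(v^2)) < 1) return(NA_real_)
      return(atan2(v[2], v[1]))
    }
    NA_real_
  }

  for (k in seq_len(nb)) {
    f_lo <- raw0[k]; f_hi <- raw1[k] - 1L
    if (f_hi < f_lo) next
    st <- bouts$state[k]
    frames <- f_lo:f_hi
    nf <- length(frames)
    tgt_th <- if (k < nb) entry_heading(k + 1L, pos) else NA_real_

    if (st == "freeze") {
      theta[frames] <- th
    } else if (st == "pause") {
      sp <- bouts$speed[k]
      band <- c(.way_margin, d[2] - .way_margin)
      if (cfg$arena == "epm") band <- c(pos[2] - 0.4, pos[2] + 0.4)
      am <- .amble(pos, band, sp, nf, dt, amble_state)
      amble_state <- am$state
      vel[frames, ] <- am$vel
      ## rotate toward the next bout's entry heading during the pause;
      ## delayed after a freeze (tail swing must stay out of the smoothed
      ## speed window at the freeze offset) and after a stretch posture
      ## (the nose is still retracting under the posture override)
      delay <- 0L
      if (k > 1L) {
        if (bouts$state[k - 1L] == "freeze") delay <- cfg$smooth_window
        if (bouts$state[k - 1L] == "sap") delay <- 8L
      }
      theta[frames] <- th
      if (!is.na(tgt_th) && nf > delay) {
        for (i in (delay + 1L):nf) {
          th <- th + sign(.angdiff(tgt_th, th)) *
            min(abs(.angdiff(tgt_th, th)), omega_max * dt)
          theta[frames[i]] <- th
        }
      }
    } else if (st == "locomote") {
      sp <- bouts$speed[k]
      p <- pos
      if (cfg$arena == "corridor") {
        ## vertical bounce only: no component along the threat axis; flip
        ## only when moving outward so out-of-band starts re-enter cleanly
        dir <- if (p[2] < d[2] / 2) 1 else -1
        for (i in seq_len(nf)) {
          q <- p + c(0, dir * sp * dt)
          if ((q[2] > d[2] - .way_margin && dir > 0) ||
              (q[2] < .way_margin && dir < 0)) {
            dir <- -dir; q <- p + c(0, dir * sp * dt)
          }
          vel[frames[i], ] <- (q - p) / dt
          tt <- atan2(q[2] - p[2], q[1] - p[1])
          th <- th + sign(.angdiff(tt, th)) *
            min(abs(.angdiff(tt, th)), omega_max * dt)
          theta[frames[i]] <- th
          p <- q
        }
      } else {
        legs <- .route_legs(cfg, p, .sample_waypoint(cfg, p))
        li <- 1L
        for (i in seq_len(nf)) {
          tgt <- legs[[li]]
          v <- tgt - p
          dist <- sqrt(sum(v^2))
          while (dist < sp * dt) {
            if (li < length(legs)) li <- li + 1L else {
              legs <- .route_legs(cfg, p, .sample_waypoint(cfg, p)); li <- 1L
            }
            tgt <- legs[[li]]; v <- tgt - p; dist <- sqrt(sum(v^2))
          }
          u <- v / dist
          vel[frames[i], ] <- u * sp
          tt <- atan2(u[2], u[1])
          th <- th + sign(.angdiff(tt, th)) *
            min(abs(.angdiff(tt, th)), omega_max * dt)
          theta[frames[i]] <- th
          p <- p + u * sp * dt
        }
      }
      pos <- p
      next
    } else if (st == "approach") {
      vel[frames, 1] <- bouts$speed[k]
      th <- 0; theta[frames] <- 0
    } else if (st == "escape") {
      vel[frames, 1] <- -bouts$speed[k]
      th <- pi; theta[frames] <- pi
    } else if (st == "burrow") {
      ctr <- c(6.5, 43.5)
      p <- pos; sp <- 10
      arrive <- NA_integer_
      i <- 1L
      while (i <= nf) {
        v <- ctr - p
        dist <- sqrt(sum(v^2))
        if (!is.na(arrive) || dist <= 1) {
          if (is.na(arrive)) arrive <- frames[i]
          am <- .amble(p, c(41.5, 45.5), cfg$pause_speed_cms,
                       nf - i + 1L, dt, amble_state)
          amble_state <- am$state
          vel[frames[i:nf], ] <- am$vel
          theta[frames[i:nf]] <- th
          p <- p + colSums(am$vel) * dt
          break
        }
        u <- v / dist
        vel[frames[i], ] <- u * min(sp, dist / dt)
        tt <- atan2(u[2], u[1])
        th <- th + sign(.angdiff(tt, th)) *
          min(abs(.angdiff(tt, th)), omega_max * dt)
        p <- p + vel[frames[i], ] * dt
        theta[frames[i]] <- th
        i <- i + 1L
      }
      attr(vel, paste0("burrow_arrive_", k)) <- arrive
      pos <- p
      next
    } else if (st == "sap") {
      sap_ok <- TRUE
      if (cfg$arena == "epm") {
        ## the stretch must run along an arm axis to stay inside the cross;
        ## snap the heading when close, otherwise degrade the bout to pause
        snap <- round(th / (pi / 2)) * (pi / 2)
        if (abs(.angdiff(snap, th)) > 0.25) sap_ok <- FALSE else th <- snap
      } else {
        ## the full stretched pose (tail anchor through extended nose)
        ## must fit inside the arena, otherwise wall clamping would cut
        ## the stretch below threshold; degrade to pause in that case
        u <- c(cos(th), sin(th))
        tf <- pos - 0.65 * BL * u
        ne <- tf + cfg$sap_stretch * BL * u
        dd2 <- arena_dims(cfg$arena)
        sap_ok <- all(c(tf, ne) >= 0.8) && tf[1] <= dd2[1] - 0.8 &&
          ne[1] <= dd2[1] - 0.8 && tf[2] <= dd2[2] - 0.8 &&
          ne[2] <= dd2[2] - 0.8
      }
      if (!sap_ok) {
        bouts$state[k] <- "pause"
        bouts$speed[k] <- cfg$pause_speed_cms
        band <- if (cfg$arena == "epm") c(pos[2] - 0.4, pos[2] + 0.4) else
          c(.way_margin, d[2] - .way_margin)
        am <- .amble(pos, band, cfg$pause_speed_cms, nf, dt, amble_state)
        amble_state <- am$state
        vel[frames, ] <- am$vel
        theta[frames] <- th
        pos <- pos + colSums(vel[frames, , drop = FALSE]) * dt
        next
      }
      ## tail stays put; the nose extends, bobs, and retracts around the
      ## planted interval (applied after integration as an override); the
      ## roll extents are computed here so the underlying pause velocity
      ## can be zeroed over them, keeping the integrated path continuous
      theta[frames] <- th
      BLc <- cfg$body_length_cm
      ext <- 8 * dt
      thr_d <- 1.2 * BLc
      smax <- cfg$sap_stretch * BLc
      es <- bouts$f0[k] - (floor((thr_d - BLc) / ext + 1e-9) + 1L)
      rs <- bouts$f1[k] - ceiling((smax - thr_d) / ext - 1e-9)
      fe <- rs + ceiling((smax - BLc) / ext)
      sap_info[[length(sap_info) + 1L]] <-
        list(k = k, f0 = bouts$f0[k], f1 = bouts$f1[k], theta = th,
             es = es, rs = rs, fe = fe)
    }
    pos <- pos + colSums(vel[frames, , drop = FALSE]) * dt
  }

  for (si in sap_info) {
    f <- max(1L, si$es):min(n, si$fe - 1L)
    vel[f, ] <- 0
  }
  head <- matrix(0, n, 2)
  head[, 1] <- start[1] + cumsum(c(0, vel[-n, 1])) * dt
  head[, 2] <- start[2] + cumsum(c(0, vel[-n, 2])) * dt
  list(head = head, theta = theta, sap_info = sap_info, vel = vel,
       bouts = bouts)
}

## Apply SAP overrides: tail fixed, nose extends along the entry heading to
## sap_stretch body lengths (the 1.2-BL crossing lands on the planted
## boundary), holds with a slow triangular sway, then retracts.
.apply_sap <- function(traj, cfg, n, rate) {
  BL <- cfg$body_length_cm
  a_n <- 0.35 * BL
  dt <- 1 / rate
  ext_rate <- 8 * dt                       # cm per frame
  thr <- 1.2 * BL
  smax <- cfg$sap_stretch * BL
  head <- traj$head; theta <- traj$theta
  overrides <- list()
  for (si in traj$sap_info) {
    f0 <- si$f0; f1 <- si$f1; th <- si$theta
    es <- si$es; rs <- si$rs; fe <- si$fe   # first frame back at BL
    if (es < 2L || fe > n) next
    u <- c(cos(th), sin(th))
    tail_fix <- head[es - 1L, ] - (BL - a_n) * u
    frames <- es:fe
    s <- pmin(smax, BL + ext_rate * (frames - es))
    s <- pmin(s, pmax(BL, smax - ext_rate * (frames - rs)))
    ## radial nose bob (0 -> -0.5 cm -> 0 triangle at 0.5 cm/s) during the
    ## hold keeps the head moving so the posture is never classified as
    ## freezing, while the stretch stays above the 1.2-BL threshold
    hold <- which(s >= smax - 1e-9)
    if (length(hold) > 2) {
      A <- 0.5
      ph <- 0.5 * dt * (seq_along(hold) - 1)
      s[hold] <- s[hold] - (A - abs((ph %% (2 * A)) - A))
    }
    ang <- rep(th, length(frames))
    nose <- cbind(tail_fix[1] + s * cos(ang), tail_fix[2] + s * sin(ang))
    overrides[[length(overrides) + 1L]] <-
      list(frames = frames, nose = nose, ang = ang, tail = tail_fix, s = s)
    head[frames, 1] <- nose[, 1] - a_n * cos(ang)
    head[frames, 2] <- nose[, 2] - a_n * sin(ang)
    theta[frames] <- ang
  }
  traj$head <- head; traj$theta <- theta; traj$overrides <- overrides
  traj
}

## Build bodypart coordinates from head + heading (rigid pose), then apply
## SAP overrides (stretched pose around a fixed tail).
.build_bodyparts <- function(traj, cfg) {
  BL <- cfg$body_length_cm
  a_n <- 0.35 * BL
  b <- 0.2 * BL
  ux <- cos(traj$theta); uy <- sin(traj$theta)
  px <- -uy; py <- ux
  nose_x <- traj$head[, 1] + a_n * ux
  nose_y <- traj$head[, 2] + a_n * uy
  earl_x <- nose_x - 1.5 * a_n * ux + b * px
  earl_y <- nose_y - 1.5 * a_n * uy + b * py
  earr_x <- nose_x - 1.5 * a_n * ux - b * px
  earr_y <- nose_y - 1.5 * a_n * uy - b * py
  tail_x <- traj$head[, 1] - (BL - a_n) * ux
  tail_y <- traj$head[, 2] - (BL - a_n) * uy
  for (ov in traj$overrides) {
    f <- ov$frames
    nose_x[f] <- ov$nose[, 1]; nose_y[f] <- ov$nose[, 2]
    ux2 <- cos(ov$ang); uy2 <- sin(ov$ang); px2 <- -uy2; py2 <- ux2
    earl_x[f] <- ov$nose[, 1] - 1.5 * a_n * ux2 + b * px2
    earl_y[f] <- ov$nose[, 2] - 1.5 * a_n * uy2 + b * py2
    earr_x[f] <- ov$nose[, 1] - 1.5 * a_n * ux2 - b * px2
    earr_y[f] <- ov$nose[, 2] - 1.5 * a_n * uy2 - b * py2
    tail_x[f] <- ov$tail[1]; tail_y[f] <- ov$tail[2]
  }
  list(nose = cbind(nose_x, nose_y), ear_left = cbind(earl_x, earl_y),
       ear_right = cbind(earr_x, earr_y), tailbase = cbind(tail_x, tail_y))
}

## Uniform random points inside the arena polygon (rejection from bbox).
.random_arena_points <- function(m, zm) {
  bb <- c(range(zm$bounds$x), range(zm$bounds$y))
  out <- matrix(NA_real_, m, 2)
  need <- seq_len(m)
  while (length(need) > 0) {
    xs <- stats::runif(length(need), bb[1], bb[2])
    ys <- stats::runif(length(need), bb[3], bb[4])
    ok <- point_in_polygon(xs, ys, zm$bounds)
    out[need[ok], ] <- cbind(xs[ok], ys[ok])
    need <- need[!ok]
  }
  out
}

#' Build an alternating laser ON/OFF epoch schedule
#'
#' Epochs alternate OFF, ON, ... from time zero (assays begin with a
#' light-off epoch).
#'
#' @param duration_s session length.
#' @param epoch_s epoch length (default 120).
#' @param n_epochs optional cap on the number of epochs.
#' @return data.frame of class `epoch_schedule` with columns `epoch`,
#'   `condition`, `start_s`, `end_s`.
#' @export
make_schedule <- function(duration_s, epoch_s = 120, n_epochs = NULL) {
  k <- max(1L, floor(duration_s / epoch_s))
  if (!is.null(n_epochs)) k <- min(k, n_epochs)
  st <- (seq_len(k) - 1) * epoch_s
  out <- data.frame(epoch = seq_len(k),
                    condition = rep(c("OFF", "ON"), length.out = k),
                    start_s = st, end_s = pmin(st + epoch_s, duration_s))
  class(out) <- c("epoch_schedule", "data.frame")
  out
}

## Behavior state at arbitrary times, from planted intervals.
.state_at <- function(intervals, times) {
  lab <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(intervals))) {
    sel <- times >= intervals$start_s[i] & times < intervals$end_s[i]
    lab[sel] <- intervals$label[i]
  }
  lab
}

## Two-channel photometry synthesis; see sim_config for the model.
.simulate_photometry <- function(cfg, head, frame_t, intervals, zm) {
  pair_dt <- 2 / cfg$photometry_rate_hz
  tp <- seq(0, cfg$duration_s - pair_dt, by = pair_dt)
  m <- length(tp)
  b <- cfg$bleach
  B <- b[["a1"]] * exp(-tp / b[["tau1"]]) + b[["a2"]] * exp(-tp / b[["tau2"]]) +
    (1 - b[["a1"]] - b[["a2"]])
  phi <- exp(-pair_dt / cfg$artifact_tau_s)
  art <- numeric(m)
  innov <- stats::rnorm(m, 0, cfg$artifact_sd * sqrt(1 - phi^2))
  art[1] <- stats::rnorm(1, 0, cfg$artifact_sd)
  for (i in 2:m) art[i] <- phi * art[i - 1] + innov[i]

  rate <- rep(cfg$base_rate_hz, m)
  if (cfg$tuning_sign != 0) {
    hx <- stats::approx(frame_t, head[, 1], xout = tp, rule = 2)$y
    hy <- stats::approx(frame_t, head[, 2], xout = tp, rule = 2)$y
    tpnt <- zm$threat_point
    L <- arena_dims(cfg$arena)[1]
    dthreat <- sqrt((hx - tpnt[1])^2 + (hy - tpnt[2])^2)
    g <- cfg$tuning_depth * (1 - pmin(dthreat, L) / L)   # high near threat
    mod <- 1 + cfg$tuning_sign * g
    if (!is.null(cfg$tuning_states)) {
      ## state-gated modulation anticipates the behavior: the rate change
      ## begins tuning_lead_s before each gated bout (activity ramps up
      ## before flight initiation), so the kernel-lagged signal is already
      ## elevated at bout onset
      stt <- .state_at(intervals, tp)
      on <- stt %in% cfg$tuning_states
      lead <- round(cfg$tuning_lead_s / pair_dt)
      if (lead > 0) {
        m <- length(on)
        on_d <- on
        for (s in seq_len(lead)) {
          on_d[seq_len(m - s)] <- on_d[seq_len(m - s)] | on[(s + 1):m]
        }
        on <- on_d
      }
      mod[!on] <- 1
    }
    rate <- pmax(0, rate * mod)
  }
  counts <- stats::rpois(m, rate * pair_dt)
  kt <- seq(0, 5 * cfg$transient_decay_s, by = pair_dt)
  ker <- exp(-kt / cfg$transient_decay_s) - exp(-kt / cfg$transient_rise_s)
  ker <- ker / max(ker) * cfg$transient_amp
  trace <- stats::convolve(counts, rev(ker), type = "open")[seq_len(m)]

  sig <- cfg$f0 * B * (1 + art + trace) + stats::rnorm(m, 0, cfg$noise_sd)
  ref <- cfg$f0 * cfg$channel_gain * B * (1 + art) +
    stats::rnorm(m, 0, cfg$noise_sd)
  rec <- data.frame(
    timestamp_s = as.vector(rbind(tp, tp + pair_dt / 2)),
    channel = rep(c(470L, 405L), m),
    value = as.vector(rbind(sig, ref)))
  class(rec) <- c("photometry_recording", "data.frame")
  attr(rec, "acquisition_rate_hz") <- cfg$photometry_rate_hz
  list(recording = rec,
       transient_times = rep(tp, counts),
       latent_rate = data.frame(timestamp_s = tp, rate = rate),
       transient_trace = data.frame(timestamp_s = tp, value = trace))
}

#' Simulate one session
#'
#' Generates a pose track, a two-channel photometry recording, a laser
#' epoch schedule, the arena zone map, and the planted ground truth for one
#' session under the given configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_session` with elements `pose`
#'   (a `pose_track`), `photometry` (a `photometry_recording` or NULL),
#'   `schedule`, `zonemap`, `truth` (see below) and `config`.  `truth`
#'   holds `state_intervals` (label, start_s, end_s), `zone_seconds`,
#'   `entry_times`, and for photometry `transient_times`, `latent_rate`
#'   and `transient_trace`.
#' @export
simulate_session <- function(config) {
  cfg <- config
  .assert(inherits(cfg, "sim_config"), "config must be a sim_config")
  with_seed(cfg$seed, {
    rate <- cfg$frame_rate_hz
    n <- round(cfg$duration_s * rate)
    .assert(n >= 3 * rate, "session too short")
    zm <- make_zonemap(cfg$arena)
    schedule <- make_schedule(cfg$duration_s, cfg$epoch_s)

    bouts <- .sample_bouts(cfg, n, rate, schedule)
    shifts <- .boundary_shifts(bouts, cfg)
    traj <- .realize_trajectory(bouts, shifts, cfg, n, rate)
    bouts <- traj$bouts
    traj$overrides <- list()
    traj <- .apply_sap(traj, cfg, n, rate)
    parts <- .build_bodyparts(traj, cfg)
    frame_t <- (seq_len(n) - 1) / rate

    ## tracking jitter on every coordinate; occluded parts pressed against
    ## a wall are clamped into the arena
    for (bp in names(parts)) {
      parts[[bp]] <- parts[[bp]] +
        matrix(stats::rnorm(2 * n, 0, cfg$jitter_sd_cm), n, 2)
      parts[[bp]] <- .clamp_to_arena(parts[[bp]], zm)
    }
    head_emit <- (parts$nose + parts$ear_left + parts$ear_right) / 3

    ## ground-truth intervals: burrow bouts split into travel + dwell
    iv <- bouts
    extra <- list()
    for (k in which(iv$state == "burrow")) {
      arr <- attr(traj$vel, paste0("burrow_arrive_", k))
      if (!is.null(arr) && !is.na(arr) && arr > iv$f0[k]) {
        extra[[length(extra) + 1L]] <-
          data.frame(state = "locomote", f0 = iv$f0[k], f1 = arr, speed = 10)
        iv$f0[k] <- arr
      }
    }
    iv <- rbind(iv, do.call(rbind, extra))
    iv <- iv[order(iv$f0), ]
    intervals <- data.frame(label = ifelse(iv$state == "burrow",
                                           "burrow_dwell", iv$state),
                            start_s = (iv$f0 - 1) / rate,
                            end_s = (pmin(iv$f1, n + 1L) - 1) / rate)

    ## ground-truth zone occupancy + entry times from the emitted head
    zone_seconds <- vapply(names(zm$zones), function(z) {
      sum(in_zone(head_emit[, 1], head_emit[, 2], zm, z)) / rate
    }, numeric(1))
    entry_times <- lapply(names(zm$zones), function(z) {
      r <- logical_runs(in_zone(head_emit[, 1], head_emit[, 2], zm, z))
      frame_t[r$start]
    })
    names(entry_times) <- names(zm$zones)

    ## photometry
    phot <- NULL
    truth_phot <- list(transient_times = numeric(0), latent_rate = NULL,
                       transient_trace = NULL)
    if (isTRUE(cfg$photometry)) {
      ph <- .simulate_photometry(cfg, traj$head, frame_t, intervals, zm)
      phot <- ph$recording
      truth_phot <- ph[c("transient_times", "latent_rate", "transient_trace")]
    }

    ## dropouts: coordinate teleports inside the arena with low likelihood
    lik <- matrix(stats::rbeta(4 * n, 20, 1), n, 4)
    colnames(lik) <- BODYPARTS
    drop <- matrix(stats::runif(4 * n) < cfg$dropout_prob, n, 4)
    for (j in seq_along(BODYPARTS)) {
      hit <- which(drop[, j])
      if (length(hit) > 0) {
        parts[[BODYPARTS[j]]][hit, ] <- .random_arena_points(length(hit), zm)
        lik[hit, j] <- stats::runif(length(hit), 0.1, 0.6)
      }
    }

    pose <- data.frame(frame = seq_len(n), timestamp_s = frame_t)
    for (j in seq_along(BODYPARTS)) {
      bp <- BODYPARTS[j]
      pose[[paste0(bp, "_x")]] <- parts[[bp]][, 1]
      pose[[paste0(bp, "_y")]] <- parts[[bp]][, 2]
      pose[[paste0(bp, "_likelihood")]] <- lik[, j]
    }
    pose <- pose_track(pose)

    truth <- c(list(state_intervals = intervals,
                    zone_seconds = zone_seconds,
                    entry_times = entry_times), truth_phot)
    out <- list(pose = pose, photometry = phot, schedule = schedule,
                zonemap = zm, truth = truth, config = cfg)
    class(out) <- "sim_session"
    out
  })
}
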