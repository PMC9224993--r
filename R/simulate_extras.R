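## Higher-level simulation helpers: itinerary-driven occupancy tracks,
## latency-to-enter trials, seeded cohorts, and the two standing in-silico
## experiments (freezing-robustness and distance-tuning recovery).

## Rigid pose emitted from a head path + heading; used by the itinerary and
## trial generators, which never feed the posture classifiers.
.pose_from_head <- function(head, theta, zm, rate, jitter_sd = 0.005,
                            body_length = 7) {
  n <- nrow(head)
  a_n <- 0.35 * body_length
  b <- 0.2 * body_length
  ux <- cos(theta); uy <- sin(theta); px <- -uy; py <- ux
  parts <- list(
    nose = cbind(head[, 1] + a_n * ux, head[, 2] + a_n * uy),
    ear_left = cbind(head[, 1] - a_n / 2 * ux + b * px,
                     head[, 2] - a_n / 2 * uy + b * py),
    ear_right = cbind(head[, 1] - a_n / 2 * ux - b * px,
                      head[, 2] - a_n / 2 * uy - b * py),
    tailbase = cbind(head[, 1] - (body_length - a_n) * ux,
                     head[, 2] - (body_length - a_n) * uy))
  pose <- data.frame(frame = seq_len(n), timestamp_s = (seq_len(n) - 1) / rate)
  for (bp in names(parts)) {
    p <- parts[[bp]] + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
    p <- .clamp_to_arena(p, zm)
    pose[[paste0(bp, "_x")]] <- p[, 1]
    pose[[paste0(bp, "_y")]] <- p[, 2]
    pose[[paste0(bp, "_likelihood")]] <- stats::rbeta(n, 50, 1)
  }
  pose_track(pose)
}

.zone_center <- function(zm, zone) {
  p <- zm$zones[[zone]]
  c(mean(range(p$x)), mean(range(p$y)))
}

#' Simulate a track that follows an explicit zone itinerary
#'
#' The animal travels between zone centers and dwells inside each zone for
#' the scheduled time, giving full control over planted occupancy.  Ground
#' truth occupancy and entry times are measured from the emitted head path.
#'
#' @param zonemap a [make_zonemap()] object.
#' @param itinerary data.frame with columns `zone` and `dwell_s`.
#' @param frame_rate_hz frames per second (default 30).
#' @param seed RNG seed.
#' @param travel_speed_cms speed between zones (default 12).
#' @return list of class `sim_session` with `pose`, `zonemap`, `truth`
#'   (`zone_seconds`, `entry_times`).
#' @export
simulate_itinerary_track <- function(zonemap, itinerary, frame_rate_hz = 30,
                                     seed = 1, travel_speed_cms = 12) {
  .assert(all(itinerary$zone %in% names(zonemap$zones)),
          "itinerary names an unknown zone")
  with_seed(seed, {
    dt <- 1 / frame_rate_hz
    pos <- .zone_center(zonemap, itinerary$zone[1])
    head <- list(); theta <- c(); th <- 0
    amb <- list(psi = pi / 2, dir = 1, parity = 1, rem = 0)
    for (i in seq_len(nrow(itinerary))) {
      tgt <- .zone_center(zonemap, itinerary$zone[i])
      while (sqrt(sum((tgt - pos)^2)) > travel_speed_cms * dt) {
        u <- (tgt - pos) / sqrt(sum((tgt - pos)^2))
        pos <- pos + u * travel_speed_cms * dt
        th <- atan2(u[2], u[1])
        head[[length(head) + 1L]] <- pos; theta <- c(theta, th)
      }
      nf <- max(1L, round(itinerary$dwell_s[i] * frame_rate_hz))
      bb <- zonemap$zones[[itinerary$zone[i]]]
      band <- c(min(bb$y) + 1.5, max(bb$y) - 1.5)
      am <- .amble(pos, band, 1, nf, dt, amb)
      amb <- am$state
      for (j in seq_len(nf)) {
        pos <- pos + am$vel[j, ] * dt
        head[[length(head) + 1L]] <- pos; theta <- c(theta, th)
      }
    }
    head <- do.call(rbind, head)
    pose <- .pose_from_head(head, theta, zonemap, frame_rate_hz)
    hx <- (pose$nose_x + pose$ear_left_x + pose$ear_right_x) / 3
    hy <- (pose$nose_y + pose$ear_left_y + pose$ear_right_y) / 3
    zone_seconds <- vapply(names(zonemap$zones), function(z)
      sum(in_zone(hx, hy, zonemap, z)) / frame_rate_hz, numeric(1))
    entry_times <- lapply(names(zonemap$zones), function(z) {
      r <- logical_runs(in_zone(hx, hy, zonemap, z))
      pose$timestamp_s[r$start]
    })
    names(entry_times) <- names(zonemap$zones)
    out <- list(pose = pose, zonemap = zonemap,
                truth = list(zone_seconds = zone_seconds,
                             entry_times = entry_times))
    class(out) <- "sim_session"
    out
  })
}

#' Simulate one latency-to-enter trial segment
#'
#' The track starts at barrier removal in the holding corner.  With a
#' planted `entry_s` the animal wanders and then dashes so that the head
#' crosses into the burrow at the planted time (within a frame); with
#' `entry_s = NULL` it wanders for the whole trial without entering.
#'
#' @param entry_s planted burrow entry time (>= 3.5 s), or NULL for a
#'   no-entry trial.
#' @param trial_limit_s trial duration limit (default 60).
#' @param frame_rate_hz frames per second.
#' @param seed RNG seed.
#' @return list with `pose` (a `pose_track`), `zonemap`, and
#'   `planted_entry_s`.
#' @export
simulate_lte_trial <- function(entry_s = NULL, trial_limit_s = 60,
                               frame_rate_hz = 30, seed = 1) {
  zm <- make_zonemap("lte")
  if (!is.null(entry_s)) {
    .assert(entry_s >= 3.5 && entry_s <= trial_limit_s,
            "entry_s must be in [3.5, trial_limit_s]")
  }
  with_seed(seed, {
    dt <- 1 / frame_rate_hz
    dur <- if (is.null(entry_s)) trial_limit_s + 2 else entry_s + 5
    n <- round(dur * frame_rate_hz)
    ## wander in the lower part of the arena (never reaches the burrow)
    pos <- c(41, 6); tgt <- NULL
    head <- matrix(0, n, 2); theta <- numeric(n); th <- pi / 2
    for (i in seq_len(n)) {
      if (is.null(tgt) || sqrt(sum((tgt - pos)^2)) < 0.3) {
        tgt <- c(stats::runif(1, 6, 41), stats::runif(1, 6, 34))
      }
      u <- (tgt - pos) / sqrt(sum((tgt - pos)^2))
      pos <- pos + u * 8 * dt
      tt <- atan2(u[2], u[1])
      th <- th + sign(.angdiff(tt, th)) * min(abs(.angdiff(tt, th)), 0.4)
      head[i, ] <- pos; theta[i] <- th
    }
    if (!is.null(entry_s)) {
      ## choose the dash start so the head crosses the burrow boundary at
      ## the planted time
      t <- (seq_len(n) - 1) * dt
      bdist <- function(p) {
        q <- c(min(max(p[1], 0), 13), min(max(p[2], 40), 47))
        sqrt(sum((p - q)^2))
      }
      g <- vapply(seq_len(n), function(i)
        bdist(head[i, ]) / 15 - (entry_s - t[i]), numeric(1))
      f0 <- which(g >= 0)[1]
      .assert(!is.na(f0), "no feasible dash start for planted entry")
      p <- head[f0, ]
      speed <- bdist(p) / max(entry_s - t[f0], dt)
      q <- c(min(max(p[1], 0), 13), min(max(p[2], 40), 47))
      u <- (q - p) / sqrt(sum((q - p)^2))
      for (i in (f0 + 1):n) {
        ctr <- c(6.5, 43.5)
        v <- ctr - p
        if (sqrt(sum(v^2)) > 1) {
          uu <- if (point_in_polygon(p[1], p[2], zm$zones$burrow)) v / sqrt(sum(v^2)) else u
          p <- p + uu * speed * dt
          theta[i] <- atan2(uu[2], uu[1])
        } else {
          theta[i] <- theta[i - 1]
        }
        head[i, ] <- p
      }
    }
    pose <- .pose_from_head(head, theta, zm, frame_rate_hz)
    list(pose = pose, zonemap = zm,
         planted_entry_s = if (is.null(entry_s)) NA_real_ else entry_s)
  })
}

#' Simulate a 10-trial latency-to-enter block with a planted laser effect
#'
#' Laser trials alternate starting with a light-off trial.  Latent
#' latencies are normal around `base_latency_s` (plus `on_effect_s` on
#' laser trials), truncated to the trial structure; latents above the trial
#' limit become no-entry trials.  Each trial is realized as a track and
#' scored with [score_lte_trial()].
#'
#' @param base_latency_s mean OFF-trial latency.
#' @param on_effect_s planted ON minus OFF effect, seconds.
#' @param sd_s trial-to-trial latency sd.
#' @param n_trials number of trials (default 10, alternating).
#' @param seed RNG seed.
#' @return list with `trials` (trial table with `latency_s` from the
#'   scorer), `planted` (latent latencies).
#' @export
simulate_lte_block <- function(base_latency_s = 20, on_effect_s = 0,
                               sd_s = 4, n_trials = 10, seed = 1) {
  with_seed(seed, {
    laser <- rep(c(FALSE, TRUE), length.out = n_trials)
    latent <- stats::rnorm(n_trials, base_latency_s + on_effect_s * laser, sd_s)
    latent <- pmax(latent, 3.6)
    lat <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      tr <- simulate_lte_trial(
        entry_s = if (latent[i] > 60) NULL else latent[i],
        seed = sample.int(1e6, 1))
      lat[i] <- score_lte_trial(
        compute_kinematics(tr$pose, smoothing_window = 1), tr$zonemap)
    }
    list(trials = data.frame(trial_index = seq_len(n_trials),
                             laser_on = laser, latency_s = lat),
         planted = latent)
  })
}

#' Simulate a seeded cohort of sessions
#'
#' @param configs named list of [sim_config()] objects (one per group).
#' @param n_per_group sessions per group (>= 1).
#' @param seed master seed; session seeds are derived deterministically.
#' @return list with `sessions` (list of `sim_session`) and `index`
#'   (data.frame `session_id`, `group`, `seed`).
#' @export
simulate_cohort <- function(configs, n_per_group = 1, seed = 1) {
  .assert(n_per_group >= 1, "n_per_group must be >= 1")
  .assert(length(names(configs)) == length(configs) &&
            !anyDuplicated(names(configs)),
          "configs must be a uniquely named list (duplicate session identifiers)")
  sessions <- list(); idx <- list()
  for (gi in seq_along(configs)) {
    for (i in seq_len(n_per_group)) {
      cfg <- configs[[gi]]
      cfg$seed <- as.integer((seed * 1000L + gi * 101L + i) %% .Machine$integer.max)
      id <- sprintf("%s_%02d", names(configs)[gi], i)
      sessions[[id]] <- simulate_session(cfg)
      idx[[id]] <- data.frame(session_id = id, group = names(configs)[gi],
                              seed = cfg$seed)
    }
  }
  list(sessions = sessions, index = do.call(rbind, c(idx, make.row.names = FALSE)))
}

## Expected dwell times (s) used to solve state weights for a target
## freezing propensity.
.expected_dwell <- function(cfg, rate) {
  min_f <- c(pause = 26, locomote = 15, sap = 15) / rate
  e_exp <- function(m, mean) m + mean * exp(-m / mean)
  c(pause = e_exp(min_f[["pause"]], cfg$dwell_means_s[["pause"]]),
    locomote = e_exp(min_f[["locomote"]], cfg$dwell_means_s[["locomote"]]),
    sap = e_exp(min_f[["sap"]], cfg$dwell_means_s[["sap"]]),
    freeze = exp(log(cfg$freeze_median_s) + cfg$freeze_sigma^2 / 2))
}

#' Open-field configuration with a target freezing propensity
#'
#' Solves the freeze-state weight of the semi-Markov chain so the expected
#' fraction of session time spent frozen equals `propensity`.
#'
#' @param propensity target freezing time fraction (0-0.65).
#' @param ... passed to [sim_config()].
#' @return a `sim_config`.
#' @export
freezing_config <- function(propensity, ...) {
  cfg <- sim_config(arena = "open_field", ...)
  E <- .expected_dwell(cfg, cfg$frame_rate_hz)
  w_l <- 0.45; w_s <- 0.10
  A <- w_l * E[["locomote"]] + w_s * E[["sap"]]
  denom <- E[["freeze"]] - propensity * (E[["pause"]] + E[["freeze"]])
  .assert(denom > 0, "propensity out of reachable range")
  w_f <- propensity * ((w_l + w_s) * E[["pause"]] + A) / denom
  cfg$state_weights <- c(locomote = w_l, freeze = w_f, sap = w_s)
  cfg
}

#' Robustness of percent-time-freezing across minimum bout durations
#'
#' Simulates `n_sessions` open-field sessions with log-normal freeze bouts
#' (median 2 s, log-sd 0.8) and heterogeneous freezing propensity spanning
#' 10-60% of session time, classifies freezing in each through the full
#' pose pipeline, and correlates percent-time-freezing computed under the
#' 0.33-s and 1-s minimum bout durations across sessions.
#'
#' @param n_sessions number of sessions (default 40).
#' @param duration_s session length (default 600).
#' @param seed master seed.
#' @param min_durs the two minimum bout durations (default `c(0.33, 1)`).
#' @return list with `r`, `percent_freezing` (sessions x durations) and
#'   `propensities`.
#' @export
freeze_robustness_experiment <- function(n_sessions = 40, duration_s = 600,
                                         seed = 1, min_durs = c(0.33, 1)) {
  props <- with_seed(seed, stats::runif(n_sessions, 0.1, 0.6))
  kins <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    cfg <- freezing_config(props[i], duration_s = duration_s,
                           seed = (seed * 1000L + i) %% .Machine$integer.max)
    s <- simulate_session(cfg)
    tr <- interpolate_low_confidence(s$pose)
    kins[[i]] <- compute_kinematics(tr)
  }
  rb <- bout_robustness(kins, min_durs = min_durs)
  list(r = rb$r, percent_freezing = rb$percent_freezing, propensities = props)
}

#' Distance-tuning recovery across a simulated photometry cohort
#'
#' Simulates corridor sessions with the requested transient-rate tuning,
#' runs the full pose + photometry pipeline, and reports the per-session
#' spatial-tuning correlations during approach and escape.
#'
#' @param n_sessions sessions to simulate.
#' @param tuning_sign -1 (rate high far from the rat), +1 (high near the
#'   rat) or 0.
#' @param tuning_states optional states the modulation is restricted to.
#' @param duration_s session length (default 600).
#' @param seed master seed.
#' @return data.frame (`session`, `approach_r`, `escape_r`).
#' @export
tuning_recovery_experiment <- function(n_sessions = 20, tuning_sign = -1,
                                       tuning_states = NULL,
                                       duration_s = 600, seed = 1) {
  out <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    cfg <- sim_config(arena = "corridor", duration_s = duration_s,
                      seed = (seed * 1000L + i) %% .Machine$integer.max,
                      tuning_sign = tuning_sign,
                      tuning_states = tuning_states)
    s <- simulate_session(cfg)
    tr <- interpolate_low_confidence(s$pose)
    kin <- compute_kinematics(tr, threat_point = s$zonemap$threat_point)
    bouts <- classify_session(kin)
    ph <- process_photometry(s$photometry, kin$timestamp_s)
    tun <- spatial_bin_dff(ph$frames, kin, bouts, s$zonemap)
    out[[i]] <- data.frame(session = i,
                           approach_r = tun$approach$r,
                           escape_r = tun$escape$r,
                           approach_r_sample = tun$approach$r_sample,
                           escape_r_sample = tun$escape$r_sample)
  }
  do.call(rbind, out)
}

#' Write the files of a simulated session to a directory
#'
#' Pose and photometry as CSV; schedule, zone map and ground truth as JSON.
#'
#' @param session a `sim_session`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pose = file.path(dir, "pose.csv"))
  write_pose_table(session$pose, paths[["pose"]])
  if (!is.null(session$photometry)) {
    paths[["photometry"]] <- file.path(dir, "photometry.csv")
    write_photometry(session$photometry, paths[["photometry"]])
  }
  if (!is.null(session$schedule)) {
    paths[["schedule"]] <- file.path(dir, "schedule.json")
    jsonlite::write_json(as.data.frame(session$schedule), paths[["schedule"]],
                         digits = NA, dataframe = "columns")
  }
  paths[["zonemap"]] <- file.path(dir, "zonemap.json")
  write_zonemap(session$zonemap, paths[["zonemap"]])
  if (!is.null(session$truth)) {
    paths[["truth"]] <- file.path(dir, "ground_truth.json")
    tr <- session$truth
    tr$latent_rate <- NULL; tr$transient_trace <- NULL  # kept in-memory only
    jsonlite::write_json(tr, paths[["truth"]], digits = NA, auto_unbox = TRUE,
                         dataframe = "columns", null = "null")
  }
  invisible(paths)
}

#' Read an epoch schedule written by [write_session()]
#'
#' @param path JSON path.
#' @return an `epoch_schedule` data.frame.
#' @export
read_schedule <- function(path) {
  df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(df) <- c("epoch_schedule", "data.frame")
  df
}
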