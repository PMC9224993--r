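## Zone-based assay scoring: occupancy, entries, threat distance, trial
## latencies, burrow-preference screening, place-test preference, and
## per-epoch metric contrasts.

## Head-centroid positions from a kinematics series (preferred) or track.
.positions <- function(kin) {
  .assert(all(c("head_x", "head_y", "timestamp_s") %in% names(kin)),
          "need a kinematics_series with head positions")
  kin
}

#' Time spent in each zone
#'
#' Occupancy is the sum of frame durations whose head-centroid position
#' falls inside the zone polygon (boundary points count as inside).
#'
#' @param kin a `kinematics_series`.
#' @param zonemap a [make_zonemap()] object.
#' @param zones zone names (default: all zones in the map).
#' @param window optional c(start_s, end_s) restricting the analysis.
#' @return data.frame (`zone`, `seconds`, `fraction`); fractions are of the
#'   analyzed time.
#' @export
zone_occupancy <- function(kin, zonemap, zones = names(zonemap$zones),
                           window = NULL) {
  kin <- .positions(kin)
  sel <- rep(TRUE, nrow(kin))
  if (!is.null(window)) {
    sel <- kin$timestamp_s >= window[1] & kin$timestamp_s < window[2]
  }
  x <- kin$head_x[sel]; y <- kin$head_y[sel]
  dur <- .frame_durations(kin$timestamp_s)[sel]
  outside <- !point_in_polygon(x, y, zonemap$bounds)
  .assert(mean(outside) <= 0.05,
          sprintf("%.1f%% of positions outside the arena; check calibration",
                  100 * mean(outside)))
  total <- sum(dur)
  secs <- vapply(zones, function(z)
    sum(dur[in_zone(x, y, zonemap, z)]), numeric(1))
  data.frame(zone = zones, seconds = secs, fraction = secs / total,
             row.names = NULL)
}

#' Count sustained entries into a zone
#'
#' An entry is an outside-to-inside transition sustained for at least
#' `min_entry_dur_s` (debounce against boundary grazing).
#'
#' @inheritParams zone_occupancy
#' @param zone zone name.
#' @param min_entry_dur_s minimum sustained presence (default 0.2 s).
#' @return list with `count` and `entry_times` (seconds).
#' @export
count_entries <- function(kin, zonemap, zone, min_entry_dur_s = 0.2) {
  kin <- .positions(kin)
  inside <- in_zone(kin$head_x, kin$head_y, zonemap, zone)
  runs <- logical_runs(inside)
  if (nrow(runs) == 0) return(list(count = 0L, entry_times = numeric(0)))
  t <- kin$timestamp_s
  dur <- .frame_durations(t)
  len <- vapply(seq_len(nrow(runs)), function(i)
    sum(dur[runs$start[i]:runs$end[i]]), numeric(1))
  keep <- len >= min_entry_dur_s - 1e-9
  list(count = sum(keep), entry_times = t[runs$start[keep]])
}

#' Distance to the threat reference point
#'
#' Per-frame Euclidean distance from the head centroid to the rat-wall
#' midpoint (or the zone map's threat point).
#'
#' @inheritParams zone_occupancy
#' @param window optional c(start_s, end_s).
#' @return list with `distance_cm` (per-frame series) and `mean_cm`.
#' @export
threat_distance <- function(kin, zonemap, window = NULL) {
  kin <- .positions(kin)
  tp <- zonemap$threat_point
  .assert(!is.null(tp), "zone map defines no threat reference point")
  d <- sqrt((kin$head_x - tp[1])^2 + (kin$head_y - tp[2])^2)
  sel <- rep(TRUE, nrow(kin))
  if (!is.null(window)) {
    sel <- kin$timestamp_s >= window[1] & kin$timestamp_s < window[2]
  }
  list(distance_cm = d, mean_cm = mean(d[sel]))
}

#' Latency to enter the burrow in one trial
#'
#' The trial segment starts at barrier removal.  Latency is the time of
#' first head entry into the burrow polygon; trials without entry before
#' `trial_limit_s` score `trial_limit_s + 1` (61 s under the default
#' 60-s limit).
#'
#' @param kin trial-segment `kinematics_series` (time 0 = barrier removal).
#' @param zonemap latency-to-enter zone map (must define `burrow`).
#' @param trial_limit_s trial duration limit (default 60).
#' @return latency in seconds.
#' @export
score_lte_trial <- function(kin, zonemap, trial_limit_s = 60) {
  kin <- .positions(kin)
  .assert("burrow" %in% names(zonemap$zones), "zone map defines no burrow")
  if (max(kin$timestamp_s) < trial_limit_s) {
    inside_any <- any(in_zone(kin$head_x, kin$head_y, zonemap, "burrow"))
    .assert(inside_any,
            "trial segment shorter than the trial limit with no burrow entry")
  }
  inside <- in_zone(kin$head_x, kin$head_y, zonemap, "burrow")
  hit <- which(inside & kin$timestamp_s <= trial_limit_s)
  if (length(hit) == 0) return(trial_limit_s + 1)
  max(kin$timestamp_s[hit[1]], .frame_durations(kin$timestamp_s)[1])
}

#' ON minus OFF latency contrast over a 10-trial block
#'
#' @param trials data.frame with columns `trial_index`, `laser_on`
#'   (logical) and `latency_s`; 5 trials per condition.
#' @return mean ON latency minus mean OFF latency, seconds.
#' @export
lte_contrast <- function(trials) {
  .assert(all(c("laser_on", "latency_s") %in% names(trials)),
          "trials need laser_on and latency_s columns")
  n_on <- sum(trials$laser_on); n_off <- sum(!trials$laser_on)
  .assert(n_on == n_off && n_on > 0,
          sprintf("unbalanced trial counts (%d ON vs %d OFF)", n_on, n_off))
  mean(trials$latency_s[trials$laser_on]) -
    mean(trials$latency_s[!trials$laser_on])
}

#' Burrow-preference screening from a habituation session
#'
#' Passes when the burrow occupancy strictly exceeds the occupancy of each
#' of the other three corner zones.
#'
#' @inheritParams zone_occupancy
#' @param corner_zones the three non-burrow corner zone names.
#' @return list with `pass` (logical) and `seconds` (named occupancies).
#' @export
burrow_preference <- function(kin, zonemap,
                              corner_zones = c("corner_ne", "corner_sw",
                                               "corner_se")) {
  occ <- zone_occupancy(kin, zonemap, zones = c("burrow", corner_zones))
  secs <- stats::setNames(occ$seconds, occ$zone)
  list(pass = all(secs["burrow"] > secs[corner_zones]), seconds = secs)
}

#' Real-time place-test preference
#'
#' Time in the stimulated chamber during test minus time in the same
#' chamber during pre-exposure, seconds.
#'
#' @param pre_kin,test_kin `kinematics_series` for the two sessions.
#' @param zonemap place-test zone map.
#' @param stim_zone stimulated chamber name (default `"stim_chamber"`).
#' @return scalar seconds (negative = avoidance).
#' @export
rtpt_preference <- function(pre_kin, test_kin, zonemap,
                            stim_zone = "stim_chamber") {
  .assert(stim_zone %in% names(zonemap$zones),
          sprintf("zone '%s' not in zone map", stim_zone))
  t_test <- zone_occupancy(test_kin, zonemap, zones = stim_zone)$seconds
  t_pre <- zone_occupancy(pre_kin, zonemap, zones = stim_zone)$seconds
  t_test - t_pre
}

## All metrics computable per condition.  Counts are reported per condition
## (not rates).
.epoch_metric_names <- c("mean_speed_cms", "pct_freezing", "distance_cm",
                         "corner_entries", "center_time_s", "corner_time_s",
                         "open_arm_pct", "threat_zone_time_s",
                         "threat_distance_cm", "sap_count", "approach_count",
                         "escape_count", "escape_velocity_cms")

#' Per-condition behavioral metrics and ON minus OFF contrasts
#'
#' Computes each requested metric separately within the laser-ON and
#' laser-OFF epochs of a schedule and reports the ON minus OFF contrast.
#' Bout counts are assigned to the condition containing the bout onset;
#' bout-time metrics use the bout time intersected with the epochs.
#'
#' @param kin a `kinematics_series`.
#' @param bouts a bout table (e.g. from [classify_session()]).
#' @param schedule an `epoch_schedule`.
#' @param zonemap the arena zone map.
#' @param metrics metric names (subset of the default set).
#' @param n_epochs optional: keep only the first `n_epochs` epochs (the
#'   elevated plus maze protocol analyzes four of its five epochs).
#' @return data.frame (`metric`, `on`, `off`, `contrast`).
#' @export
epoch_metrics <- function(kin, bouts, schedule, zonemap,
                          metrics = .epoch_metric_names, n_epochs = NULL) {
  .assert(all(metrics %in% .epoch_metric_names),
          "unknown metric requested")
  if (!is.null(n_epochs)) schedule <- schedule[seq_len(n_epochs), ]
  t <- kin$timestamp_s
  dur <- .frame_durations(t)
  one_condition <- function(cond) {
    ep <- schedule[schedule$condition == cond, , drop = FALSE]
    .assert(nrow(ep) > 0, sprintf("schedule has no %s epochs", cond))
    sel <- rep(FALSE, length(t))
    for (i in seq_len(nrow(ep))) {
      sel <- sel | (t >= ep$start_s[i] & t < ep$end_s[i])
    }
    total <- sum(dur[sel])
    in_ep <- function(times) {
      out <- rep(FALSE, length(times))
      for (i in seq_len(nrow(ep))) {
        out <- out | (times >= ep$start_s[i] & times < ep$end_s[i])
      }
      out
    }
    bout_time <- function(lab) {
      b <- bouts[bouts$label == lab, , drop = FALSE]
      if (nrow(b) == 0) return(0)
      sum(vapply(seq_len(nrow(b)), function(i)
        sum(vapply(seq_len(nrow(ep)), function(j)
          max(0, min(b$end_s[i], ep$end_s[j]) -
                max(b$start_s[i], ep$start_s[j])), numeric(1))),
        numeric(1)))
    }
    bout_count <- function(lab) {
      b <- bouts[bouts$label == lab, , drop = FALSE]
      sum(in_ep(b$start_s))
    }
    vals <- c()
    for (m in metrics) {
      vals[m] <- switch(m,
        mean_speed_cms = mean(kin$head_speed_cms[sel]),
        pct_freezing = 100 * bout_time("freeze") / total,
        distance_cm = sum(kin$head_speed_cms[sel] * dur[sel]),
        corner_entries = {
          cz <- grep("^corner_", names(zonemap$zones), value = TRUE)
          sum(vapply(cz, function(z)
            sum(in_ep(count_entries(kin, zonemap, z)$entry_times)),
            numeric(1)))
        },
        center_time_s = sum(dur[sel & in_zone(kin$head_x, kin$head_y,
                                              zonemap, "center")]),
        corner_time_s = {
          cz <- grep("^corner_", names(zonemap$zones), value = TRUE)
          sum(vapply(cz, function(z)
            sum(dur[sel & in_zone(kin$head_x, kin$head_y, zonemap, z)]),
            numeric(1)))
        },
        open_arm_pct = {
          oa <- in_zone(kin$head_x, kin$head_y, zonemap, "open_arm_left") |
            in_zone(kin$head_x, kin$head_y, zonemap, "open_arm_right")
          100 * sum(dur[sel & oa]) / total
        },
        threat_zone_time_s = sum(dur[sel & in_zone(kin$head_x, kin$head_y,
                                                   zonemap, "threat_zone")]),
        threat_distance_cm = {
          tp <- zonemap$threat_point
          mean(sqrt((kin$head_x[sel] - tp[1])^2 +
                      (kin$head_y[sel] - tp[2])^2))
        },
        sap_count = bout_count("sap"),
        approach_count = bout_count("approach"),
        escape_count = bout_count("escape"),
        escape_velocity_cms = {
          b <- bouts[bouts$label == "escape", , drop = FALSE]
          b <- b[in_ep(b$start_s), , drop = FALSE]
          if (nrow(b) == 0) NA_real_ else mean(b$mean_speed_cms)
        })
    }
    vals
  }
  on <- one_condition("ON")
  off <- one_condition("OFF")
  data.frame(metric = metrics, on = as.numeric(on), off = as.numeric(off),
             contrast = as.numeric(on - off), row.names = NULL)
}
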