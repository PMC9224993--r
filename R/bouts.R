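## Kinematic behavior definitions and bout post-processing.
##
## Freezing: head and tailbase speeds both below 0.25 cm/s for at least
## 0.33 s.  Stretch-attend posture (SAP): nose-tailbase distance above 1.2
## body lengths while the tailbase moves below 1 cm/s.  Approach / escape:
## signed velocity toward the threat point above +3 / below -3 cm/s.

#' Classifier thresholds
#'
#' @param freeze_speed_max_cms speed ceiling for freezing (default 0.25).
#' @param freeze_min_dur_s minimum freeze bout duration (default 0.33).
#' @param sap_stretch_factor nose-tail distance threshold in body lengths
#'   (default 1.2).
#' @param sap_tail_speed_max_cms tailbase speed ceiling during SAP (default 1).
#' @param run_speed_min_cms signed-velocity threshold for approach/escape
#'   (default 3).
#' @return list of class `classifier_params`.
#' @export
classifier_params <- function(freeze_speed_max_cms = 0.25,
                              freeze_min_dur_s = 0.33,
                              sap_stretch_factor = 1.2,
                              sap_tail_speed_max_cms = 1,
                              run_speed_min_cms = 3) {
  p <- list(freeze_speed_max_cms = freeze_speed_max_cms,
            freeze_min_dur_s = freeze_min_dur_s,
            sap_stretch_factor = sap_stretch_factor,
            sap_tail_speed_max_cms = sap_tail_speed_max_cms,
            run_speed_min_cms = run_speed_min_cms)
  .assert(all(unlist(p) > 0), "all classifier parameters must be positive")
  class(p) <- "classifier_params"
  p
}

## Assemble a bout table from frame-level condition runs.  end_s is
## exclusive: the timestamp of the first frame after the bout (last frame +
## one frame duration at the track edge).
.bouts_from_runs <- function(kin, runs, label, speed) {
  t <- kin$timestamp_s
  dur <- .frame_durations(t)
  if (nrow(runs) == 0) {
    return(data.frame(label = character(), start_s = numeric(),
                      end_s = numeric(), duration_s = numeric(),
                      mean_speed_cms = numeric(), peak_speed_cms = numeric()))
  }
  start_s <- t[runs$start]
  end_s <- t[runs$end] + dur[runs$end]
  data.frame(
    label = label, start_s = start_s, end_s = end_s,
    duration_s = end_s - start_s,
    mean_speed_cms = vapply(seq_len(nrow(runs)), function(i)
      mean(speed[runs$start[i]:runs$end[i]]), numeric(1)),
    peak_speed_cms = vapply(seq_len(nrow(runs)), function(i)
      max(speed[runs$start[i]:runs$end[i]]), numeric(1))
  )
}

.empty_bouts <- function() {
  data.frame(label = character(), start_s = numeric(), end_s = numeric(),
             duration_s = numeric(), mean_speed_cms = numeric(),
             peak_speed_cms = numeric())
}

#' Detect freezing bouts
#'
#' Maximal runs of frames where both the head and tailbase speeds are below
#' `freeze_speed_max_cms`, kept when they last at least `freeze_min_dur_s`.
#'
#' @param kin a `kinematics_series`.
#' @param params a [classifier_params()] list.
#' @return bout table (label, start_s, end_s, duration_s, mean/peak head
#'   speed) with attribute `percent_time_freezing` (% of analyzed time).
#' @export
detect_freezing <- function(kin, params = classifier_params()) {
  .assert(nrow(kin) > 0, "empty kinematics series")
  cond <- kin$head_speed_cms < params$freeze_speed_max_cms &
    kin$tailbase_speed_cms < params$freeze_speed_max_cms
  b <- .bouts_from_runs(kin, logical_runs(cond), "freeze", kin$head_speed_cms)
  b <- b[b$duration_s >= params$freeze_min_dur_s - 1e-9, , drop = FALSE]
  rownames(b) <- NULL
  total <- kin$timestamp_s[nrow(kin)] - kin$timestamp_s[1] +
    .frame_durations(kin$timestamp_s)[nrow(kin)]
  attr(b, "percent_time_freezing") <- 100 * sum(b$duration_s) / total
  b
}

#' Detect stretch-attend postures
#'
#' Maximal runs where the nose-tailbase distance exceeds
#' `sap_stretch_factor` body lengths while the tailbase speed stays below
#' `sap_tail_speed_max_cms`.
#'
#' @inheritParams detect_freezing
#' @return bout table; SAP count is `nrow()` of the result.
#' @export
detect_sap <- function(kin, params = classifier_params()) {
  bl <- attr(kin, "body_length_cm")
  .assert(is.numeric(bl) && bl > 0, "body length zero or undefined")
  cond <- kin$nose_tail_distance_cm > params$sap_stretch_factor * bl &
    kin$tailbase_speed_cms < params$sap_tail_speed_max_cms
  b <- .bouts_from_runs(kin, logical_runs(cond), "sap", kin$tailbase_speed_cms)
  rownames(b) <- NULL
  b
}

#' Detect approach and escape runs
#'
#' Approach: maximal runs with signed velocity toward the threat above
#' `run_speed_min_cms`; escape: below `-run_speed_min_cms`.  Mean and peak
#' tailbase speeds are recorded per bout; the escape-velocity metric is the
#' mean tailbase speed during escape bouts.
#'
#' @inheritParams detect_freezing
#' @return bout table with labels `approach` and `escape`.
#' @export
detect_runs <- function(kin, params = classifier_params()) {
  v <- kin$signed_velocity_to_threat_cms
  .assert(!all(is.na(v)),
          "signed velocity to threat unavailable (threat point undefined)")
  ap <- .bouts_from_runs(kin, logical_runs(v > params$run_speed_min_cms),
                         "approach", kin$tailbase_speed_cms)
  es <- .bouts_from_runs(kin, logical_runs(v < -params$run_speed_min_cms),
                         "escape", kin$tailbase_speed_cms)
  out <- rbind(ap, es)
  rownames(out) <- NULL
  out
}

#' Merge nearby bouts and drop short ones
#'
#' Same-label bouts separated by less than `merge_gap_s` are merged, then
#' bouts shorter than `min_dur_s` are dropped.  Idempotent.
#'
#' @param bouts a bout table.
#' @param merge_gap_s gap below which same-label bouts merge (default 0).
#' @param min_dur_s minimum retained duration (default 0).
#' @return a bout table.
#' @export
postprocess_bouts <- function(bouts, merge_gap_s = 0, min_dur_s = 0) {
  .assert(merge_gap_s >= 0 && min_dur_s >= 0,
          "merge_gap_s and min_dur_s must be non-negative")
  if (nrow(bouts) == 0) return(bouts)
  out <- do.call(rbind, lapply(split(bouts, bouts$label), function(b) {
    b <- b[order(b$start_s), , drop = FALSE]
    if (merge_gap_s > 0 && nrow(b) > 1) {
      grp <- cumsum(c(1, as.integer(
        b$start_s[-1] - b$end_s[-nrow(b)] >= merge_gap_s)))
      b <- do.call(rbind, lapply(split(b, grp), function(g) {
        data.frame(label = g$label[1], start_s = min(g$start_s),
                   end_s = max(g$end_s),
                   duration_s = max(g$end_s) - min(g$start_s),
                   mean_speed_cms = sum(g$mean_speed_cms * g$duration_s) /
                     sum(g$duration_s),
                   peak_speed_cms = max(g$peak_speed_cms))
      }))
    }
    b
  }))
  out <- out[out$duration_s >= min_dur_s, , drop = FALSE]
  out <- out[order(out$label, out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent time freezing under a given minimum bout duration
#'
#' @param kin a `kinematics_series`.
#' @param params classifier thresholds.
#' @param min_dur_s minimum freeze bout duration to count.
#' @return percent of session time spent freezing.
#' @export
percent_time_freezing <- function(kin, params = classifier_params(),
                                  min_dur_s = params$freeze_min_dur_s) {
  p <- params
  p$freeze_min_dur_s <- min_dur_s
  b <- detect_freezing(kin, p)
  attr(b, "percent_time_freezing")
}

#' Robustness of percent-time-freezing to the minimum bout duration
#'
#' Computes percent time freezing per session under each minimum bout
#' duration and returns the Pearson correlation between the first two
#' resulting vectors across sessions.
#'
#' @param kins list of `kinematics_series`, one per session (>= 3).
#' @param params classifier thresholds.
#' @param min_durs numeric vector of minimum bout durations, seconds
#'   (default `c(0.33, 1)`).
#' @return list with `r` (Pearson correlation, NA when degenerate),
#'   `percent_freezing` (sessions x durations matrix) and `diagnostic`.
#' @export
bout_robustness <- function(kins, params = classifier_params(),
                            min_durs = c(0.33, 1)) {
  .assert(length(kins) >= 3, "need at least 3 sessions for a stable correlation")
  m <- vapply(min_durs, function(d)
    vapply(kins, percent_time_freezing, numeric(1), params = params,
           min_dur_s = d),
    numeric(length(kins)))
  colnames(m) <- paste0("min_", min_durs, "s")
  if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) {
    return(list(r = NA_real_, percent_freezing = m,
                diagnostic = "degenerate: a percent-freezing vector is constant"))
  }
  list(r = stats::cor(m[, 1], m[, 2]), percent_freezing = m, diagnostic = "ok")
}

#' Classify all behaviors for one session
#'
#' Runs the freeze, stretch-attend and (when a threat point is defined)
#' approach/escape detectors, then applies bout post-processing.  Approach
#' and escape bouts shorter than `run_min_dur_s` are dropped: sub-150-ms
#' supra-threshold blips are tracking-noise artifacts of interpolated pose
#' estimates, not locomotor runs.
#'
#' @param kin a `kinematics_series`.
#' @param params classifier thresholds.
#' @param run_min_dur_s debounce for approach/escape bouts (default 0.15).
#' @param merge_gap_s same-label merge gap passed to [postprocess_bouts()].
#' @return bout table with labels among freeze, sap, approach, escape, and
#'   attribute `percent_time_freezing`.
#' @export
classify_session <- function(kin, params = classifier_params(),
                             run_min_dur_s = 0.15, merge_gap_s = 0) {
  fr <- detect_freezing(kin, params)
  pct <- attr(fr, "percent_time_freezing")
  sap <- detect_sap(kin, params)
  out <- rbind(fr, sap)
  if (!all(is.na(kin$signed_velocity_to_threat_cms))) {
    runs <- detect_runs(kin, params)
    runs <- postprocess_bouts(runs, merge_gap_s = merge_gap_s,
                              min_dur_s = run_min_dur_s)
    out <- rbind(out, runs)
  }
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "percent_time_freezing") <- pct
  out
}
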