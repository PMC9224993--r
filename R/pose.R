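## Pose-table input, cleaning, and kinematic series.
##
## A pose track holds per-frame x/y coordinates and tracking likelihoods for
## the four tracked bodyparts (nose, both ears, tailbase) plus timestamps.
## Internally coordinates are always cm with origin at the arena lower-left.

BODYPARTS <- c("nose", "ear_left", "ear_right", "tailbase")

#' Construct a pose track
#'
#' @param df data.frame with columns `frame`, `timestamp_s` and, for each
#'   bodypart in `nose`, `ear_left`, `ear_right`, `tailbase`, columns
#'   `<bp>_x`, `<bp>_y`, `<bp>_likelihood`.
#' @param cm_per_px calibration scalar applied to coordinates (1 = already cm).
#' @return data.frame of class `pose_track`.
#' @export
pose_track <- function(df, cm_per_px = 1) {
  need <- c("frame", "timestamp_s",
            as.vector(t(outer(BODYPARTS, c("_x", "_y", "_likelihood"), paste0))))
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0,
          paste0("pose table is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  .assert(nrow(df) > 0, "pose table is empty")
  for (col in need) {
    .assert(is.numeric(df[[col]]),
            sprintf("pose column '%s' is not numeric", col))
  }
  lk <- grep("_likelihood$", need, value = TRUE)
  for (col in lk) {
    .assert(all(df[[col]] >= 0 & df[[col]] <= 1, na.rm = TRUE),
            sprintf("likelihood column '%s' outside [0, 1]", col))
  }
  df <- df[, need]
  if (cm_per_px != 1) {
    xy <- grep("_(x|y)$", need, value = TRUE)
    df[xy] <- df[xy] * cm_per_px
  }
  ## reject rows that break timestamp monotonicity
  keep <- c(TRUE, diff(df$timestamp_s) > 0)
  while (!all(keep)) {
    df <- df[keep, , drop = FALSE]
    keep <- c(TRUE, diff(df$timestamp_s) > 0)
  }
  .assert(nrow(df) > 0, "no rows with strictly increasing timestamps")
  rownames(df) <- NULL
  class(df) <- c("pose_track", "data.frame")
  df
}

#' Read a pose table from CSV
#'
#' Expects the column layout written by [write_pose_table()]: `frame`,
#' `timestamp_s`, then `<bodypart>_x`, `<bodypart>_y`,
#' `<bodypart>_likelihood` for nose, ear_left, ear_right and tailbase.
#' Rows with non-monotone timestamps are dropped.
#'
#' @param path CSV file path.
#' @param cm_per_px coordinate calibration (cm per pixel); 1 when the file is
#'   already in cm.  If `NULL` and `arena` is given, the scale is derived
#'   from the known arena width and the observed x-range.
#' @param arena optional arena name used to derive calibration.
#' @return a `pose_track`.
#' @export
read_pose_table <- function(path, cm_per_px = 1, arena = NULL) {
  .assert(file.exists(path), sprintf("pose file not found: %s", path))
  df <- utils::read.csv(path)
  .assert(nrow(df) > 0, "pose file is empty")
  if (is.null(cm_per_px)) {
    .assert(!is.null(arena), "need either cm_per_px or arena for calibration")
    w <- arena_dims(arena)[1]
    rng <- range(df$nose_x, df$tailbase_x, na.rm = TRUE)
    cm_per_px <- w / diff(rng)
  }
  pose_track(df, cm_per_px = cm_per_px)
}

#' Write a pose table to CSV
#'
#' @param track a `pose_track`.
#' @param path output path.
#' @export
write_pose_table <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Replace low-confidence coordinates by linear interpolation
#'
#' Coordinates whose tracking likelihood falls below `likelihood_min` are
#' replaced by linear interpolation between the nearest confident frames
#' (nearest confident value at the track edges).  Filled frames are flagged
#' in a `<bodypart>_filled` column.
#'
#' @param track a `pose_track`.
#' @param likelihood_min confidence threshold in `[0, 1]` (default 0.9).
#' @return a `pose_track` with filled coordinates and `_filled` flags.
#' @export
interpolate_low_confidence <- function(track, likelihood_min = 0.9) {
  .assert(likelihood_min >= 0 && likelihood_min <= 1,
          "likelihood_min must be in [0, 1]")
  out <- track
  idx <- seq_len(nrow(track))
  for (bp in BODYPARTS) {
    lk <- track[[paste0(bp, "_likelihood")]]
    good <- lk >= likelihood_min
    .assert(any(good),
            sprintf("bodypart '%s' has no frames at or above likelihood %g",
                    bp, likelihood_min))
    out[[paste0(bp, "_filled")]] <- !good
    if (all(good)) next
    for (ax in c("_x", "_y")) {
      col <- paste0(bp, ax)
      v <- track[[col]]
      out[[col]] <- stats::approx(idx[good], v[good], xout = idx,
                                  rule = 2)$y
    }
  }
  class(out) <- c("pose_track", "data.frame")
  out
}

#' Derive speed and posture series from a pose track
#'
#' The head point is the centroid of the nose and both ears.  Positions are
#' smoothed with a centered boxcar over `smoothing_window` frames before
#' differentiation; speeds are forward differences of the smoothed positions
#' (the last value is edge-replicated so all series share the track length).
#' Body length is the session median of the nose-tailbase distance.  When a
#' threat point is supplied, the signed velocity toward the threat is
#' `-d(distance to threat)/dt`, positive while approaching.
#'
#' @param track a `pose_track` (cm).
#' @param smoothing_window odd integer >= 1, frames (default 5, ~0.17 s at
#'   30 frames/s).
#' @param threat_point optional c(x, y) of the threat reference point, cm.
#' @return data.frame of class `kinematics_series` with columns
#'   `timestamp_s`, `head_x`, `head_y`, `head_speed_cms`,
#'   `tailbase_speed_cms`, `nose_tail_distance_cm`,
#'   `signed_velocity_to_threat_cms` (NA when no threat point) and
#'   attributes `body_length_cm` and `frame_rate_hz`.
#' @export
compute_kinematics <- function(track, smoothing_window = 5, threat_point = NULL) {
  w <- as.integer(smoothing_window)
  .assert(w >= 1 && w %% 2L == 1L, "smoothing_window must be odd and >= 1")
  n <- nrow(track)
  .assert(n > w, "track shorter than smoothing window")
  t <- track$timestamp_s

  sm <- lapply(BODYPARTS, function(bp) {
    list(x = .boxcar(track[[paste0(bp, "_x")]], w),
         y = .boxcar(track[[paste0(bp, "_y")]], w))
  })
  names(sm) <- BODYPARTS
  head_x <- (sm$nose$x + sm$ear_left$x + sm$ear_right$x) / 3
  head_y <- (sm$nose$y + sm$ear_left$y + sm$ear_right$y) / 3

  fwd_speed <- function(x, y) {
    dt <- diff(t)
    sp <- sqrt(diff(x)^2 + diff(y)^2) / dt
    c(sp, sp[length(sp)])
  }
  head_speed <- fwd_speed(head_x, head_y)
  tail_speed <- fwd_speed(sm$tailbase$x, sm$tailbase$y)
  ntd <- sqrt((sm$nose$x - sm$tailbase$x)^2 + (sm$nose$y - sm$tailbase$y)^2)

  signed_v <- rep(NA_real_, n)
  if (!is.null(threat_point)) {
    d <- sqrt((head_x - threat_point[1])^2 + (head_y - threat_point[2])^2)
    dv <- -diff(d) / diff(t)
    signed_v <- c(dv, dv[length(dv)])
  }

  out <- data.frame(
    timestamp_s = t, head_x = head_x, head_y = head_y,
    head_speed_cms = head_speed, tailbase_speed_cms = tail_speed,
    nose_tail_distance_cm = ntd,
    signed_velocity_to_threat_cms = signed_v
  )
  attr(out, "body_length_cm") <- stats::median(ntd)
  attr(out, "frame_rate_hz") <- 1 / stats::median(diff(t))
  attr(out, "smoothing_window") <- w
  class(out) <- c("kinematics_series", "data.frame")
  out
}
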