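## Peri-event averaging, arm-entry responses, spatial tuning of the
## corrected calcium signal, zone-mean comparisons, and the speed control.

#' Peri-event average of the frame-aligned signal
#'
#' Extracts a window of `window_s` seconds before and after each event
#' onset; events too close to the recording edges are dropped.
#'
#' @param zdff_frames a `zdff_frames` data.frame ([align_to_frames()]).
#' @param event_times event onset times, seconds.
#' @param window_s half-window (default 5).
#' @return list of class `peri_event`: `tensor` (events x offsets matrix),
#'   `offsets_s`, `mean_trace`, `n_events`, `dropped`.
#' @export
peri_event_average <- function(zdff_frames, event_times, window_s = 5) {
  t <- zdff_frames$timestamp_s
  dt <- stats::median(diff(t))
  k <- round(window_s / dt)
  offsets <- (-k:k) * dt
  idx <- vapply(event_times, function(e) which.min(abs(t - e)), integer(1))
  valid <- idx - k >= 1 & idx + k <= length(t) &
    abs(t[idx] - event_times) <= dt
  .assert(any(valid), "no events with a full window inside the recording")
  rows <- lapply(idx[valid], function(i) zdff_frames$zdff[(i - k):(i + k)])
  tensor <- do.call(rbind, rows)
  colnames(tensor) <- sprintf("%.3f", offsets)
  out <- list(tensor = tensor, offsets_s = offsets,
              mean_trace = colMeans(tensor, na.rm = TRUE),
              n_events = sum(valid), dropped = sum(!valid))
  class(out) <- "peri_event"
  out
}

#' Mean signal in the window after arm entries
#'
#' Averages the aligned signal over `(entry, entry + post_window_s]` per
#' entry, then per arm type, and reports the open minus closed contrast.
#'
#' @param zdff_frames a `zdff_frames`.
#' @param entries data.frame with columns `time_s` and `arm` (values
#'   `"open"` / `"closed"`).
#' @param post_window_s window length after entry (default 1).
#' @return list with `per_entry` (data.frame), `open_mean`, `closed_mean`,
#'   `contrast` (open minus closed).
#' @export
arm_entry_response <- function(zdff_frames, entries, post_window_s = 1) {
  .assert(all(c("time_s", "arm") %in% names(entries)),
          "entries need time_s and arm columns")
  .assert(all(c("open", "closed") %in% entries$arm),
          "need entries of both arm types")
  t <- zdff_frames$timestamp_s
  vals <- vapply(seq_len(nrow(entries)), function(i) {
    e <- entries$time_s[i]
    if (e + post_window_s > t[length(t)]) return(NA_real_)
    sel <- t > e & t <= e + post_window_s
    mean(zdff_frames$zdff[sel], na.rm = TRUE)
  }, numeric(1))
  per <- data.frame(time_s = entries$time_s, arm = entries$arm,
                    mean_zdff = vals)
  per <- per[!is.na(per$mean_zdff), , drop = FALSE]
  om <- mean(per$mean_zdff[per$arm == "open"])
  cm <- mean(per$mean_zdff[per$arm == "closed"])
  list(per_entry = per, open_mean = om, closed_mean = cm,
       contrast = om - cm)
}

#' Spatial tuning of the signal along the corridor
#'
#' Restricts frames to approach (or escape) bouts, bins them by distance
#' from the safe wall into `n_bins` equal-width bins, and correlates the
#' per-bin mean signal with the bin-center distance (Pearson).  Empty bins
#' are reported and excluded pairwise from the correlation.  A sample-level
#' correlation over the masked frames is also reported.
#'
#' @param zdff_frames a `zdff_frames`.
#' @param kin a `kinematics_series` on the same frame clock.
#' @param bouts bout table with `approach` / `escape` labels.
#' @param zonemap corridor zone map (defines the safe wall).
#' @param labels run types to analyze.
#' @param n_bins number of spatial bins (default 10).
#' @return named list (per label) of class `spatial_tuning`: data.frame
#'   `bins` (`bin`, `center_cm`, `mean_zdff`, `sem`, `n`), `r`, `p`,
#'   `r_sample`, `n_samples`.
#' @export
spatial_bin_dff <- function(zdff_frames, kin, bouts, zonemap,
                            labels = c("approach", "escape"), n_bins = 10) {
  .assert(!is.null(zonemap$safe_wall_x), "zone map defines no safe wall")
  L <- max(zonemap$bounds$x) - zonemap$safe_wall_x
  dist_safe <- kin$head_x - zonemap$safe_wall_x
  edges <- seq(0, L, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  t <- kin$timestamp_s
  out <- list()
  for (lab in labels) {
    b <- bouts[bouts$label == lab, , drop = FALSE]
    mask <- rep(FALSE, length(t))
    for (i in seq_len(nrow(b))) {
      mask <- mask | (t >= b$start_s[i] & t < b$end_s[i])
    }
    mask <- mask & !is.na(zdff_frames$zdff)
    d <- dist_safe[mask]
    z <- zdff_frames$zdff[mask]
    bin <- pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1L),
                n_bins)
    stats_df <- data.frame(
      bin = seq_len(n_bins), center_cm = centers,
      mean_zdff = vapply(seq_len(n_bins), function(k)
        if (any(bin == k)) mean(z[bin == k]) else NA_real_, numeric(1)),
      sem = vapply(seq_len(n_bins), function(k)
        if (sum(bin == k) > 1) stats::sd(z[bin == k]) / sqrt(sum(bin == k))
        else NA_real_, numeric(1)),
      n = vapply(seq_len(n_bins), function(k) sum(bin == k), numeric(1)))
    ok <- !is.na(stats_df$mean_zdff)
    r <- p <- NA_real_
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(stats_df$center_cm[ok], stats_df$mean_zdff[ok])
      r <- unname(ct$estimate); p <- ct$p.value
    }
    r_sample <- if (length(z) >= 3 && stats::sd(z) > 0)
      stats::cor(d, z) else NA_real_
    res <- list(bins = stats_df, r = r, p = p, r_sample = r_sample,
                n_samples = length(z), empty_bins = which(!ok))
    class(res) <- "spatial_tuning"
    out[[lab]] <- res
  }
  out
}

#' Mean signal in the safe third versus the threat two-thirds
#'
#' The safe zone is the third of the corridor nearest the safe wall; the
#' threat zone is the remaining two-thirds.  The two zones partition the
#' corridor, so the occupancy-weighted combination of the zone means equals
#' the whole-corridor mean.
#'
#' @inheritParams spatial_bin_dff
#' @return list with `safe_mean`, `threat_mean`, `contrast`
#'   (threat minus safe), `safe_n`, `threat_n`.
#' @export
zone_mean_dff <- function(zdff_frames, kin, zonemap) {
  .assert(!is.null(zonemap$safe_wall_x), "zone map defines no safe wall")
  L <- max(zonemap$bounds$x) - zonemap$safe_wall_x
  d <- kin$head_x - zonemap$safe_wall_x
  z <- zdff_frames$zdff
  ok <- !is.na(z)
  safe <- ok & d <= L / 3
  threat <- ok & d > L / 3
  .assert(any(safe) && any(threat),
          "animal never sampled in one of the zones")
  list(safe_mean = mean(z[safe]), threat_mean = mean(z[threat]),
       contrast = mean(z[threat]) - mean(z[safe]),
       safe_n = sum(safe), threat_n = sum(threat))
}

#' Speed versus signal control correlation
#'
#' @param zdff_frames a `zdff_frames`.
#' @param speed per-frame speed series (cm/s).
#' @return list with Pearson `r` and `p`.
#' @export
speed_dff_control <- function(zdff_frames, speed) {
  ok <- !is.na(zdff_frames$zdff) & !is.na(speed)
  .assert(stats::sd(speed[ok]) > 0, "constant speed series")
  ct <- stats::cor.test(speed[ok], zdff_frames$zdff[ok])
  list(r = unname(ct$estimate), p = ct$p.value)
}
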