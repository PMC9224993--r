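## Fiber photometry processing: de-interleave the alternating two-channel
## stream, remove bleaching and motion artifacts with the isosbestic
## reference channel, z-score, and align to behavior video frames.
##
## The recording interleaves a calcium-dependent 470-nm channel with a
## calcium-independent 405-nm reference at a nominal 20 Hz total rate.
## Bleaching and motion artifacts are common to both channels, so a linear
## fit of the reference onto the signal captures them; the fractional
## residual is the corrected dF/F.

#' Construct / read / write a photometry recording
#'
#' @param df data.frame with columns `timestamp_s`, `channel` (470 or 405)
#'   and `value`.
#' @return data.frame of class `photometry_recording`.
#' @export
photometry_recording <- function(df) {
  need <- c("timestamp_s", "channel", "value")
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0,
          paste0("photometry table missing column(s): ",
                 paste(miss, collapse = ", ")))
  .assert(all(df$channel %in% c(405L, 470L)),
          "channel must be 405 or 470")
  .assert(all(diff(df$timestamp_s) > 0),
          "photometry timestamps must be strictly increasing")
  df <- df[, need]
  class(df) <- c("photometry_recording", "data.frame")
  df
}

#' @rdname photometry_recording
#' @param path CSV file path.
#' @export
read_photometry <- function(path) {
  .assert(file.exists(path), sprintf("photometry file not found: %s", path))
  photometry_recording(utils::read.csv(path))
}

#' @rdname photometry_recording
#' @param rec a `photometry_recording`.
#' @export
write_photometry <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' Split the interleaved stream into signal and reference series
#'
#' Channel tags must strictly alternate.  Each signal sample is paired with
#' the nearest reference sample in time (its multiplexing partner), so both
#' series share the signal clock.  Averaging the two surrounding reference
#' samples instead would leak shared reference noise into consecutive
#' corrected samples and color the residual.
#'
#' @param rec a `photometry_recording`.
#' @return list with `signal` and `reference` data.frames (`timestamp_s`,
#'   `value`), both on the signal-channel clock, plus `raw_reference`.
#' @export
deinterleave <- function(rec) {
  ch <- rec$channel
  .assert(all(ch[-1] != ch[-length(ch)]),
          "two consecutive samples share a channel tag; stream is not alternating")
  sig <- rec[rec$channel == 470L, c("timestamp_s", "value")]
  ref <- rec[rec$channel == 405L, c("timestamp_s", "value")]
  .assert(nrow(sig) > 1 && nrow(ref) > 1, "need both channels present")
  idx <- findInterval(sig$timestamp_s, ref$timestamp_s)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, nrow(ref))
  ## ties (exactly equidistant neighbors) resolve to the following sample;
  ## the tolerance keeps the resolution stable under floating-point jitter
  nearest <- ifelse(abs(ref$timestamp_s[hi] - sig$timestamp_s) <=
                      abs(ref$timestamp_s[lo] - sig$timestamp_s) + 1e-9,
                    hi, lo)
  rownames(sig) <- rownames(ref) <- NULL
  list(signal = sig,
       reference = data.frame(timestamp_s = sig$timestamp_s,
                              value = ref$value[nearest]),
       raw_reference = ref)
}

#' Reference-correct the calcium signal into dF/F
#'
#' Fits `signal ~ slope * reference + intercept` by least squares (or a
#' Theil-Sen fit over subsampled pairs for artifact-heavy sessions) and
#' returns the fractional residual `dff = (signal - fitted) / fitted`.
#' Because bleaching and motion artifacts are shared across channels, the
#' fitted series tracks them and the residual isolates calcium transients.
#'
#' @param signal,reference aligned equal-length data.frames from
#'   [deinterleave()].
#' @param method `"ols"` (default) or `"theil_sen"`.
#' @param n_pairs number of random pairs for the Theil-Sen slope.
#' @param seed RNG seed used only by the Theil-Sen subsampling.
#' @return data.frame of class `dff_series` (`timestamp_s`, `dff`) with
#'   attribute `fit_params` (slope, intercept, method).
#' @export
correct_reference <- function(signal, reference, method = c("ols", "theil_sen"),
                              n_pairs = 20000, seed = 1) {
  method <- match.arg(method)
  .assert(nrow(signal) == nrow(reference), "series lengths differ")
  .assert(nrow(signal) >= 100, "need at least 100 aligned samples")
  x <- reference$value
  y <- signal$value
  .assert(stats::var(x) > 0, "zero-variance reference channel")
  if (method == "ols") {
    slope <- stats::cov(x, y) / stats::var(x)
    intercept <- mean(y) - slope * mean(x)
  } else {
    n <- length(x)
    slopes <- with_seed(seed, {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      keep <- x[i] != x[j]
      (y[i] - y[j])[keep] / (x[i] - x[j])[keep]
    })
    slope <- stats::median(slopes)
    intercept <- stats::median(y - slope * x)
  }
  fitted <- slope * x + intercept
  .assert(all(fitted > 0), "fitted reference has non-positive values")
  out <- data.frame(timestamp_s = signal$timestamp_s,
                    dff = (y - fitted) / fitted)
  attr(out, "fit_params") <- c(slope = slope, intercept = intercept)
  attr(out, "method") <- method
  class(out) <- c("dff_series", "data.frame")
  out
}

#' z-score a dF/F series
#'
#' The mean and standard deviation are estimated over `window` (whole
#' series by default) and applied to the whole series.
#'
#' @param dff a `dff_series`.
#' @param window optional c(start_s, end_s) normalization window.
#' @return the input with an added `zdff` column and attribute
#'   `zscore_window`.
#' @export
zscore_dff <- function(dff, window = NULL) {
  sel <- rep(TRUE, nrow(dff))
  if (!is.null(window)) {
    .assert(length(window) == 2 && window[1] < window[2],
            "window must be c(start_s, end_s)")
    sel <- dff$timestamp_s >= window[1] & dff$timestamp_s <= window[2]
    .assert(any(sel), "normalization window outside recording")
  }
  m <- mean(dff$dff[sel])
  s <- stats::sd(dff$dff[sel])
  .assert(is.finite(s) && s > 0, "zero variance in normalization window")
  out <- dff
  out$zdff <- (dff$dff - m) / s
  attr(out, "zscore_window") <- if (is.null(window)) "session" else window
  attr(out, "fit_params") <- attr(dff, "fit_params")
  class(out) <- c("dff_series", "data.frame")
  out
}

#' Assign each behavior frame the nearest photometry sample
#'
#' Frames farther than one photometry sample period from any sample are
#' flagged missing (NA).
#'
#' @param zdff a `dff_series` with a `zdff` column.
#' @param frame_timestamps behavior frame times, seconds.
#' @return data.frame (`frame`, `timestamp_s`, `zdff`, `sample_index`) of
#'   class `zdff_frames`; `zdff` is NA outside photometry coverage.
#' @export
align_to_frames <- function(zdff, frame_timestamps) {
  ts <- zdff$timestamp_s
  .assert(max(frame_timestamps) >= ts[1] && min(frame_timestamps) <= ts[length(ts)],
          "no temporal overlap between frames and photometry")
  period <- stats::median(diff(ts))
  idx <- findInterval(frame_timestamps, ts)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(ts))
  d_lo <- abs(frame_timestamps - ts[lo])
  d_hi <- abs(frame_timestamps - ts[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  z <- zdff$zdff[nearest]
  z[dist > period] <- NA_real_
  out <- data.frame(frame = seq_along(frame_timestamps),
                    timestamp_s = frame_timestamps,
                    zdff = z, sample_index = nearest)
  out$sample_index[dist > period] <- NA_integer_
  class(out) <- c("zdff_frames", "data.frame")
  out
}

#' Full photometry pipeline for one session
#'
#' De-interleave, reference-correct, z-score, and align to video frames.
#'
#' @param rec a `photometry_recording`.
#' @param frame_timestamps behavior frame times (optional).
#' @inheritParams correct_reference
#' @param zscore_window optional c(start_s, end_s).
#' @return list with `dff` (the z-scored `dff_series`) and, when frame
#'   times are given, `frames` (a `zdff_frames`).
#' @export
process_photometry <- function(rec, frame_timestamps = NULL,
                               method = "ols", zscore_window = NULL) {
  de <- deinterleave(rec)
  dff <- correct_reference(de$signal, de$reference, method = method)
  z <- zscore_dff(dff, window = zscore_window)
  out <- list(dff = z)
  if (!is.null(frame_timestamps)) {
    out$frames <- align_to_frames(z, frame_timestamps)
  }
  out
}
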