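## Small internal helpers shared across modules.

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Maximal runs of TRUE in a logical vector
#'
#' @param x logical vector (NA treated as FALSE).
#' @return data.frame with integer columns `start`, `end` (inclusive frame
#'   indices), one row per maximal run.
#' @keywords internal
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

## Evaluate an expression with a temporary RNG seed, restoring the caller's
## RNG state afterwards.  Keeps session generation reproducible without
## clobbering the global stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Signed smallest angular difference a - b in (-pi, pi].
.angdiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

## Centered boxcar smoother with edge replication; w must be odd, >= 1.
.boxcar <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[(h + 1L):(h + length(x))]
}

## Per-frame durations: forward differences of timestamps, last replicated.
.frame_durations <- function(t) {
  n <- length(t)
  if (n == 1L) return(1)
  d <- diff(t)
  c(d, d[n - 1L])
}

## Intersection length of interval [a0,a1) with a set of intervals.
.interval_overlap <- function(a0, a1, s0, s1) {
  sum(pmax(0, pmin(a1, s1) - pmax(a0, s0)))
}
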