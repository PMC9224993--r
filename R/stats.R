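## Statistical procedures used with the assays, and histology
## count-fraction arithmetic.
##
## Group comparisons are two-tailed Student t-tests on per-animal contrast
## scores (ON minus OFF, or CNO minus saline); unpaired tests use the
## pooled-variance form (df = n1 + n2 - 2), matching the degrees of freedom
## reported with these assays.  Normality screening uses the Lilliefors
## test with a Monte-Carlo null; multiple comparisons are adjusted by the
## Benjamini-Hochberg false discovery rate.

#' Two-tailed Student t-test on per-animal contrast scores
#'
#' Unpaired tests use classical pooled variance; paired tests require both
#' groups in matching order.
#'
#' @param a,b numeric vectors of per-animal values.
#' @param paired logical.
#' @return list with `t`, `df`, `p`.
#' @export
group_ttest <- function(a, b, paired = FALSE) {
  .assert(length(a) >= 2 && length(b) >= 2, "need n >= 2 per group")
  if (paired) {
    .assert(length(a) == length(b), "paired groups must match in length")
    .assert(stats::sd(a - b) > 0, "zero variance of paired differences")
    res <- stats::t.test(a, b, paired = TRUE)
  } else {
    pooled <- ((length(a) - 1) * stats::var(a) +
                 (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    .assert(pooled > 0, "zero pooled variance")
    res <- stats::t.test(a, b, var.equal = TRUE)
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list with `r` and `p` (t-transform, df = n - 2).
#' @export
pearson_r <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 3, "need n >= 3 pairs")
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0, "constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' Simulates `n_mc` standard-normal samples of size `n` and computes the
#' Kolmogorov-Smirnov statistic against a normal with estimated mean and
#' sd for each.  Cached per (n, n_mc, seed) within a session.
#'
#' @param n sample size.
#' @param n_mc Monte-Carlo replicates (default 10000).
#' @param seed RNG seed for the null.
#' @return sorted numeric vector of null D statistics.
#' @export
lilliefors_null <- function(n, n_mc = 10000, seed = 1) {
  key <- sprintf("n%d_m%d_s%d", n, n_mc, seed)
  if (!is.null(.lillie_cache[[key]])) return(.lillie_cache[[key]])
  d <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) .lillie_d(stats::rnorm(n)), numeric(1))
  })
  d <- sort(d)
  .lillie_cache[[key]] <- d
  d
}

.lillie_cache <- new.env(parent = emptyenv())

## KS statistic of x against Normal(mean(x), sd(x)).
.lillie_d <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with
#' estimated mean and sd; the p-value comes from a seeded Monte-Carlo null
#' of the same sample size, making it exact up to simulation error at any
#' n.
#'
#' @param x numeric sample (n >= 4, non-constant).
#' @param n_mc Monte-Carlo replicates.
#' @param seed RNG seed for the null.
#' @param null optional precomputed [lilliefors_null()] vector.
#' @return list with `D` and `p`.
#' @export
lilliefors_test <- function(x, n_mc = 10000, seed = 1, null = NULL) {
  .assert(length(x) >= 4, "need n >= 4")
  .assert(stats::sd(x) > 0, "constant sample")
  D <- .lillie_d(x)
  if (is.null(null)) null <- lilliefors_null(length(x), n_mc, seed)
  p <- (1 + sum(null >= D)) / (length(null) + 1)
  list(D = D, p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values (same order as input).
#' @export
fdr_adjust <- function(p_values) {
  .assert(all(p_values >= 0 & p_values <= 1), "p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Marker-overlap fractions from histology count tables
#'
#' Computes, per region, the fraction of denominator-marker cells that are
#' also positive for the other marker.  `pooled` sums counts over animals
#' before dividing; `per_animal_mean` averages per-animal fractions.
#' Regions can be combined (the lateral and ventrolateral columns are
#' pooled into `l/vlPAG` by default: overlap cells counted in both columns
#' divided by denominator cells counted in both columns).
#'
#' @param counts data.frame with columns `animal`, `region`, `marker_a`,
#'   `marker_b`, `overlap` (non-negative integers,
#'   `overlap <= min(marker_a, marker_b)`).
#' @param pooling `"pooled"` or `"per_animal_mean"`.
#' @param denominator `"marker_a"` or `"marker_b"`.
#' @param combine named list mapping a combined-region name to the regions
#'   it pools (default `list("l/vlPAG" = c("lPAG", "vlPAG"))`, applied when
#'   those regions are present).
#' @return data.frame (`region`, `fraction`, `n_animals`).
#' @export
overlap_fractions <- function(counts,
                              pooling = c("pooled", "per_animal_mean"),
                              denominator = c("marker_a", "marker_b"),
                              combine = list("l/vlPAG" = c("lPAG", "vlPAG"))) {
  pooling <- match.arg(pooling)
  denominator <- match.arg(denominator)
  need <- c("animal", "region", "marker_a", "marker_b", "overlap")
  .assert(all(need %in% names(counts)), "count table missing columns")
  .assert(all(counts$overlap <= pmin(counts$marker_a, counts$marker_b)),
          "overlap exceeds a marker count")
  .assert(all(counts[, c("marker_a", "marker_b", "overlap")] >= 0),
          "negative counts")
  for (nm in names(combine)) {
    sub <- counts[counts$region %in% combine[[nm]], , drop = FALSE]
    if (nrow(sub) > 0) {
      agg <- stats::aggregate(sub[, c("marker_a", "marker_b", "overlap")],
                              by = list(animal = sub$animal), FUN = sum)
      agg$region <- nm
      counts <- rbind(counts, agg[, need])
    }
  }
  res <- lapply(split(counts, counts$region), function(g) {
    den <- g[[denominator]]
    if (pooling == "pooled") {
      .assert(sum(den) > 0, sprintf("zero total denominator in region %s",
                                    g$region[1]))
      frac <- sum(g$overlap) / sum(den)
      n <- length(unique(g$animal))
    } else {
      keep <- den > 0
      if (!all(keep)) {
        warning(sprintf("region %s: %d animal(s) with zero denominator excluded",
                        g$region[1], sum(!keep)))
      }
      .assert(any(keep), sprintf("no usable animals in region %s", g$region[1]))
      frac <- mean(g$overlap[keep] / den[keep])
      n <- sum(keep)
    }
    data.frame(region = g$region[1], fraction = frac, n_animals = n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cohort screening fraction
#'
#' @param pass_count animals passing the screen.
#' @param total animals screened.
#' @return percentage, reported to one decimal.
#' @export
cohort_screen_fraction <- function(pass_count, total) {
  .assert(total > 0, "total must be positive")
  .assert(pass_count >= 0 && pass_count <= total,
          "pass_count must be between 0 and total")
  round(100 * pass_count / total, 1)
}
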