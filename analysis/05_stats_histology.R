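#!/usr/bin/env Rscript

# Stage 5: statistical summary and histology count-fraction arithmetic.
# The per-animal count table is synthetic (no per-animal counts are
# published); its pooled totals reproduce the published l/vlPAG counts
# (302 double-labeled of 3115 glutamatergic cells; 302 of 317 marker+
# cells), so the pooled fractions below are the published arithmetic while
# the per-animal means illustrate the alternative pooling.

suppressPackageStartupMessages(library(defensetrack))

## synthetic per-animal split of the published pooled counts (n = 4)
counts <- data.frame(
  animal = rep(1:4, each = 2),
  region = rep(c("lPAG", "vlPAG"), 4),
  marker_a = c(420, 390, 380, 370, 400, 395, 385, 375),  # vGlut2+
  marker_b = c(41, 39, 38, 37, 42, 40, 41, 39),          # GFP+
  overlap = c(39, 37, 36, 35, 40, 38, 40, 37))
stopifnot(sum(counts$marker_a) == 3115, sum(counts$marker_b) == 317,
          sum(counts$overlap) == 302)

pooled <- overlap_fractions(counts, "pooled", denominator = "marker_a")
per_an <- overlap_fractions(counts, "per_animal_mean", denominator = "marker_a")
pooled_b <- overlap_fractions(counts, "pooled", denominator = "marker_b")
cat("== marker overlap fractions (l/vlPAG pooled columns) ==\n")
cat(sprintf("  marker+ of glutamatergic cells: pooled %.1f%%, per-animal mean %.1f%%\n",
            100 * pooled$fraction[pooled$region == "l/vlPAG"],
            100 * per_an$fraction[per_an$region == "l/vlPAG"]))
cat(sprintf("  glutamatergic of marker+ cells: pooled %.1f%%\n",
            100 * pooled_b$fraction[pooled_b$region == "l/vlPAG"]))
write.csv(rbind(cbind(pooling = "pooled", pooled),
                cbind(pooling = "per_animal_mean", per_an)),
          "results/histology_fractions.csv", row.names = FALSE)

cat(sprintf("  burrow screening of the published cohort: %.1f%% (63 of 69)\n",
            cohort_screen_fraction(63, 69)))

## multiple-comparison adjustment across the stage-3 assay tests
if (file.exists("results/openfield_tests.csv")) {
  tests <- read.csv("results/openfield_tests.csv")
  norm <- vapply(unique(tests$metric), function(m) {
    v <- read.csv("results/openfield_scores.csv")
    x <- v$contrast[v$metric == m]
    lilliefors_test(x, n_mc = 2000, seed = 42)$p
  }, numeric(1))
  tests$normality_p <- norm[tests$metric]
  write.csv(tests, "results/stats_summary.csv", row.names = FALSE)
  cat("== open-field contrasts: FDR-adjusted group tests ==\n")
  for (i in seq_len(nrow(tests))) {
    cat(sprintf("  %-16s p = %.4g  p_adj = %.4g  (Lilliefors p = %.3f)\n",
                tests$metric[i], tests$p[i], tests$p_adj[i],
                tests$normality_p[i]))
  }
}
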