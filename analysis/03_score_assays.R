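#!/usr/bin/env Rscript

# Stage 3: assay scoring.  Open-field sessions are scored per laser
# condition (ON minus OFF contrasts of speed, freezing, center/corner
# occupancy and corner entries) and the stimulated group is compared with
# controls by unpaired pooled-variance t-tests.  A latency-to-enter cohort
# with a planted laser effect is screened for burrow preference and scored
# trial by trial with the 61-s no-entry convention.

suppressPackageStartupMessages(library(defensetrack))

index <- read.csv("results/session_index.csv")
of_ids <- index$session_id[index$group %in% c("control", "stim")]

rows <- list()
for (id in of_ids) {
  dir <- file.path("results/sessions", id)
  track <- interpolate_low_confidence(read_pose_table(file.path(dir, "pose.csv")))
  zm <- read_zonemap(file.path(dir, "zonemap.json"))
  kin <- compute_kinematics(track)
  bouts <- read.csv(file.path(dir, "bouts.csv"))
  sched <- read_schedule(file.path(dir, "schedule.json"))
  em <- epoch_metrics(kin, bouts, sched, zm,
                      metrics = c("mean_speed_cms", "pct_freezing",
                                  "center_time_s", "corner_time_s",
                                  "corner_entries"))
  em$session_id <- id
  em$group <- index$group[index$session_id == id]
  rows[[id]] <- em
}
scores <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(scores, "results/openfield_scores.csv", row.names = FALSE)

cat("== open field: ON minus OFF contrasts, stim vs control ==\n")
tests <- list()
for (m in unique(scores$metric)) {
  a <- scores$contrast[scores$metric == m & scores$group == "stim"]
  b <- scores$contrast[scores$metric == m & scores$group == "control"]
  tt <- group_ttest(a, b)
  tests[[m]] <- data.frame(metric = m, stim_mean = mean(a),
                           control_mean = mean(b), t = tt$t, df = tt$df,
                           p = tt$p)
  cat(sprintf("  %-16s stim %7.2f  ctl %7.2f  t(%d) = %6.2f  p = %.4g\n",
              m, mean(a), mean(b), tt$df, tt$t, tt$p))
}
tt_df <- do.call(rbind, c(tests, make.row.names = FALSE))
tt_df$p_adj <- fdr_adjust(tt_df$p)
write.csv(tt_df, "results/openfield_tests.csv", row.names = FALSE)

## latency-to-enter: burrow-preference screening, then a 10-trial block per
## animal with a planted -8 s laser effect in the "stimulated" group
cat("== latency-to-enter ==\n")
zm <- make_zonemap("lte")
screen <- vapply(1:16, function(i) {
  iti <- if (i <= 14) {
    data.frame(zone = c("burrow", "corner_sw", "corner_ne", "corner_se"),
               dwell_s = c(22, 7, 6, 5))
  } else {
    data.frame(zone = c("burrow", "corner_sw", "corner_ne", "corner_se"),
               dwell_s = c(6, 18, 8, 8))
  }
  s <- simulate_itinerary_track(zm, iti, seed = 700 + i)
  burrow_preference(compute_kinematics(s$pose, smoothing_window = 1),
                    zm)$pass
}, logical(1))
cat(sprintf("  burrow screening: %d of %d mice retained (%.1f%%)\n",
            sum(screen), length(screen),
            cohort_screen_fraction(sum(screen), length(screen))))

lte <- lapply(1:12, function(i) {
  eff <- if (i <= 6) -8 else 0
  bl <- simulate_lte_block(base_latency_s = 24, on_effect_s = eff, sd_s = 3,
                           seed = 800 + i)
  data.frame(animal = i, group = if (eff < 0) "stim" else "control",
             contrast_s = lte_contrast(bl$trials))
})
lte <- do.call(rbind, lte)
write.csv(lte, "results/lte_contrasts.csv", row.names = FALSE)
tt <- group_ttest(lte$contrast_s[lte$group == "stim"],
                  lte$contrast_s[lte$group == "control"])
cat(sprintf("  ON-OFF latency contrast: stim %5.2f s vs ctl %5.2f s, t(%d) = %.2f, p = %.4g\n",
            mean(lte$contrast_s[lte$group == "stim"]),
            mean(lte$contrast_s[lte$group == "control"]),
            tt$df, tt$t, tt$p))
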