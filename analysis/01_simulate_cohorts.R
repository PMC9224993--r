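#!/usr/bin/env Rscript

# Stage 1: generate the simulated cohorts every downstream stage analyzes.
#
# Two cohorts: (a) an open-field optogenetics cohort in which the
# "stimulated" group freezes much more during laser-ON epochs (a
# pan-neuronal-activation-like phenotype) while controls are unaffected,
# and (b) a corridor photometry cohort with avoidance-like (rate high far
# from the rat) and threat-activated, escape-gated tuning.  Session inputs
# are written as the CSV/JSON bundle the package's readers consume.

suppressPackageStartupMessages(library(defensetrack))

out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## (a) open-field ON/OFF cohort: 8-min sessions, 2-min alternating epochs
of_cfg <- function(effects = NULL) {
  sim_config(arena = "open_field", duration_s = 480, photometry = FALSE,
             epoch_effects = effects)
}
opto <- simulate_cohort(
  list(control = of_cfg(),
       stim = of_cfg(effects = list(freeze = 8))),
  n_per_group = 6, seed = 101)

## (b) corridor photometry cohort: 10-min exposures
phot <- simulate_cohort(
  list(avoidance_tuned = sim_config(arena = "corridor", duration_s = 600,
                                    tuning_sign = -1),
       escape_gated = sim_config(arena = "corridor", duration_s = 600,
                                 tuning_sign = 1,
                                 tuning_states = "escape")),
  n_per_group = 6, seed = 202)

index <- rbind(opto$index, phot$index)
truth_rows <- list()
for (id in names(c(opto$sessions, phot$sessions))) {
  s <- c(opto$sessions, phot$sessions)[[id]]
  write_session(s, file.path(out_dir, id))
  iv <- s$truth$state_intervals
  truth_rows[[id]] <- data.frame(
    session_id = id,
    pct_freezing_truth = 100 * sum(iv$end_s[iv$label == "freeze"] -
                                     iv$start_s[iv$label == "freeze"]) /
      s$config$duration_s)
}
write.csv(index, "results/session_index.csv", row.names = FALSE)
write.csv(do.call(rbind, c(truth_rows, make.row.names = FALSE)),
          "results/session_truth.csv", row.names = FALSE)

cat(sprintf("wrote %d sessions to %s\n", nrow(index), out_dir))
cat("groups:\n")
print(table(index$group))
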