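## Session orchestration: one configuration drives simulate -> kinematics
## -> classify -> score -> photometry -> event analysis, with file outputs
## and a provenance manifest.

.config_defaults <- list(
  arena = "open_field", duration_s = 600, seed = 1,
  smoothing_window = 5, likelihood_min = 0.9,
  run_min_dur_s = 0.15, merge_gap_s = 0,
  tuning_sign = 0, photometry = TRUE, n_epochs = NULL
)

.load_config <- function(config) {
  if (is.character(config)) {
    .assert(file.exists(config), sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML path")
  unknown <- setdiff(names(config), names(.config_defaults))
  .assert(length(unknown) == 0,
          paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(.config_defaults, config)
  .assert(cfg$arena %in% c("open_field", "epm", "lte", "corridor", "rtpt"),
          sprintf("unknown assay name '%s' in field 'arena'", cfg$arena))
  cfg
}

#' Run the full pipeline on one simulated session
#'
#' Simulates a session, writes its input files, re-reads them (exercising
#' the file interfaces), cleans and differentiates the pose, classifies
#' behavior, scores the assay per laser condition, processes photometry
#' where recorded, and writes a session summary plus a manifest with
#' digests of every output.
#'
#' @param config a named list or a YAML file path with any of: `arena`,
#'   `duration_s`, `seed`, `smoothing_window`, `likelihood_min`,
#'   `run_min_dur_s`, `merge_gap_s`, `tuning_sign`, `photometry`,
#'   `n_epochs`.
#' @param out_dir output directory.
#' @return the manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_session <- function(config, out_dir) {
  cfg <- .load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim_cfg <- sim_config(arena = cfg$arena, duration_s = cfg$duration_s,
                        seed = cfg$seed, photometry = isTRUE(cfg$photometry),
                        tuning_sign = cfg$tuning_sign,
                        epoch_s = min(120, cfg$duration_s / 4))
  session <- simulate_session(sim_cfg)
  in_paths <- write_session(session, file.path(out_dir, "inputs"))

  track <- read_pose_table(in_paths[["pose"]])
  track <- interpolate_low_confidence(track, cfg$likelihood_min)
  zm <- read_zonemap(in_paths[["zonemap"]])
  kin <- compute_kinematics(track, cfg$smoothing_window,
                            threat_point = zm$threat_point)
  bouts <- classify_session(kin, run_min_dur_s = cfg$run_min_dur_s,
                            merge_gap_s = cfg$merge_gap_s)
  out_paths <- c(bouts = file.path(out_dir, "bouts.csv"))
  utils::write.csv(bouts, out_paths[["bouts"]], row.names = FALSE)

  schedule <- read_schedule(in_paths[["schedule"]])
  metrics_avail <- c("mean_speed_cms", "pct_freezing", "distance_cm",
    if (cfg$arena %in% c("open_field", "lte")) c("corner_entries", "corner_time_s"),
    if (cfg$arena == "open_field") "center_time_s",
    if (cfg$arena == "epm") "open_arm_pct",
    if (cfg$arena == "corridor") c("threat_zone_time_s", "threat_distance_cm",
                                   "sap_count", "approach_count",
                                   "escape_count", "escape_velocity_cms"))
  summary <- epoch_metrics(kin, bouts, schedule, zm, metrics = metrics_avail,
                           n_epochs = cfg$n_epochs)
  out_paths[["summary"]] <- file.path(out_dir, "session_summary.csv")
  utils::write.csv(summary, out_paths[["summary"]], row.names = FALSE)

  if (!is.null(session$photometry)) {
    rec <- read_photometry(in_paths[["photometry"]])
    ph <- process_photometry(rec, kin$timestamp_s)
    out_paths[["dff"]] <- file.path(out_dir, "dff.csv")
    utils::write.csv(ph$frames, out_paths[["dff"]], row.names = FALSE)
    if (cfg$arena == "corridor") {
      tun <- spatial_bin_dff(ph$frames, kin, bouts, zm)
      tc <- do.call(rbind, lapply(names(tun), function(lab) {
        cbind(run_type = lab, tun[[lab]]$bins,
              r = tun[[lab]]$r, p = tun[[lab]]$p)
      }))
      out_paths[["tuning"]] <- file.path(out_dir, "tuning_curve.csv")
      utils::write.csv(tc, out_paths[["tuning"]], row.names = FALSE)
    }
  }

  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(cfg, cfg_path)
  all_paths <- c(in_paths, out_paths)
  manifest <- list(
    config = cfg,
    config_digest = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("defensetrack")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(nm = names(all_paths)), function(k)
      list(path = unname(all_paths[[k]]),
           md5 = unname(tools::md5sum(all_paths[[k]]))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the named replication checks
#'
#' Recomputes headline quantities from scratch: `t1` the burrow-preference
#' screening percentage from the published cohort counts, `t2` the
#' percent-freezing correlation across minimum bout durations on a
#' simulated cohort, `t3` the no-entry trial latency convention.
#'
#' @param checks character vector among `"t1"`, `"t2"`, `"t3"` (empty
#'   vector allowed).
#' @param seed seed for the simulated checks.
#' @param n_sessions cohort size for `t2`.
#' @return data.frame (`check`, `value`, `expected`, `cmp`, `pass`).
#' @export
run_replication_suite <- function(checks = c("t1", "t2", "t3"), seed = 1,
                                  n_sessions = 40) {
  .assert(all(checks %in% c("t1", "t2", "t3")),
          "unknown check id (known: t1, t2, t3)")
  if (length(checks) == 0) {
    return(data.frame(check = character(), value = numeric(),
                      expected = numeric(), cmp = character(),
                      pass = logical()))
  }
  rows <- lapply(checks, function(ck) {
    if (ck == "t1") {
      v <- cohort_screen_fraction(63, 69)
      data.frame(check = ck, value = v, expected = 91.3, cmp = "eq",
                 pass = abs(v - 91.3) < 0.05)
    } else if (ck == "t2") {
      v <- freeze_robustness_experiment(n_sessions = n_sessions,
                                        seed = seed)$r
      data.frame(check = ck, value = v, expected = 0.95, cmp = "ge",
                 pass = v > 0.95)
    } else {
      tr <- simulate_lte_trial(entry_s = NULL, seed = seed)
      v <- score_lte_trial(compute_kinematics(tr$pose, smoothing_window = 1),
                           tr$zonemap)
      data.frame(check = ck, value = v, expected = 61, cmp = "eq",
                 pass = v == 61)
    }
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
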