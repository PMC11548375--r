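## Cohort-level parameter-recovery benchmark: simulate seeded recordings,
## run the full optical + quality + vitals pipeline, and score extracted HR
## and RR against the simulator's ground truth. Used by the acceptance
## checks and the acceptance report script.

#' Vitals parameter-recovery benchmark on a synthetic cohort
#'
#' For each seed, simulates one recording at the default noise profile,
#' selects the better channel by signal quality, extracts HR and RR
#' (30 s windows, 7.5 s stride, adaptive bands) and computes agreement
#' statistics (ME, RMSE, LoA half-width, Pearson r) between the window
#' estimates and the window-averaged ground-truth traces.
#'
#' @param seeds one simulation seed per recording (default 1:10).
#' @param duration_min recording length in minutes (default 30).
#' @param config_args named list of [sim_config()] overrides applied to
#'   every recording.
#' @param vitals a [vitals_config()].
#' @return list with `per_recording` (data.frame of agreement statistics
#'   per recording and metric) and `mean` (per-metric across-recording
#'   means, the scale the study reports).
#' @export
vitals_recovery_benchmark <- function(seeds = 1:10, duration_min = 30,
                                      config_args = list(),
                                      vitals = vitals_config()) {
  rows <- list()
  for (s in seeds) {
    args <- utils::modifyList(list(seed = s, duration_min = duration_min), config_args)
    cfg <- do.call(sim_config, args)
    sim <- simulate_measurement(cfg)
    sel <- assess_recording(sim$recording)
    v <- extract_vitals(sel$hemodynamics, vitals)
    for (metric in c("hr", "rr")) {
      est_df <- v[[metric]]
      est <- est_df[[2L]]
      truth <- window_truth(sim$truth[[metric]], est_df$time_s, vitals$window)
      a <- vitals_agreement(est, truth)
      a$metric <- metric; a$seed <- s
      a$flagged_frac <- mean(est_df$flagged)
      rows[[length(rows) + 1L]] <- a
    }
  }
  per_recording <- do.call(rbind, rows)
  agg <- function(metric, col) mean(per_recording[[col]][per_recording$metric == metric])
  list(per_recording = per_recording,
       mean = list(
         hr_rmse = agg("hr", "rmse"), hr_r = agg("hr", "pearson_r"),
         hr_loa = agg("hr", "loa"), hr_me = agg("hr", "me"),
         rr_rmse = agg("rr", "rmse"), rr_r = agg("rr", "pearson_r"),
         rr_loa = agg("rr", "loa"), rr_me = agg("rr", "me")))
}
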