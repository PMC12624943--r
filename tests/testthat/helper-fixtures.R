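# Shared fixtures: all built in code, no stored data.

quick_config <- function(...) {
  experiment_config(...)
}

# config for hand-built micro fixtures: every drinking event is a bout
loose_config <- function(...) {
  experiment_config(min_licks_per_bout = 1, ...)
}

quick_registry <- function(n = 4) {
  subject_registry(paste0("rat", seq_len(n)),
                   sprintf("RF%06d", seq_len(n)),
                   body_mass_g = 300)
}

# hand-built bout data frame at offsets (seconds) from experiment start
bout_df <- function(config, t_s, device_id, licks, volume_mL,
                    duration_s = 5, rfid = "RF000001") {
  n <- length(t_s)
  data.frame(datetime = config$experiment_start + t_s,
             device_id = rep_len(device_id, n),
             fluid = fluid_for_device_label(config, rep_len(device_id, n)),
             rfid = rep_len(rfid, n),
             licks = as.integer(rep_len(licks, n)),
             volume_mL = rep_len(volume_mL, n),
             duration_s = rep_len(duration_s, n),
             stringsAsFactors = FALSE)
}

fluid_for_device_label <- function(config, device_id) {
  config$fluids$label[match(device_id, config$fluids$device_id)]
}

hand_session <- function(config, bouts, registry = quick_registry(), licks = NULL) {
  session_log(bouts, config, registry, licks = licks)
}

# a small clean simulated session for structural tests
small_sim <- function(seed = 1, duration_h = 24, n_rats = 2, ...) {
  cfg <- experiment_config(...)
  reg <- quick_registry(n_rats)
  bh <- default_behaviors(reg$subject_id)
  simulate_session(bh, cfg, reg, duration_h = duration_h, seed = seed)
}

# brute-force O(n^2) interval-overlap oracle, half-open [s, s+d)
overlap_count_oracle <- function(start_s, dur_s) {
  n <- length(start_s)
  cnt <- 0L
  if (n < 2) return(cnt)
  e <- start_s + dur_s
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (start_s[i] < e[j] && start_s[j] < e[i] &&
          dur_s[i] > 0 && dur_s[j] > 0) cnt <- cnt + 1L
    }
  }
  cnt
}

expect_metric <- function(mt, metric, subject = NULL, fluid = NULL, day = NULL) {
  r <- mt[mt$metric == metric, ]
  if (!is.null(subject)) r <- r[r$subject_id %in% subject, ]
  if (!is.null(fluid)) r <- r[r$fluid %in% fluid, ]
  if (!is.null(day)) r <- r[!is.na(r$day) & r$day %in% day, ]
  r
}
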