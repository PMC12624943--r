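#' @keywords internal
"_PACKAGE"

# Time convention: all absolute timestamps are POSIXct in UTC; arithmetic is
# done in seconds. Clock-of-day is derived from the epoch value directly
# (UTC has no DST), so a fixed light-cycle anchor is exact.

#' Parse an ISO-8601 timestamp (UTC)
#'
#' @param x character vector, e.g. `"2024-03-01T20:00:00"` or with
#'   fractional seconds `"...T20:00:00.125"`. A space separator is also
#'   accepted.
#' @return POSIXct (UTC); `NA` where unparseable.
#' @export
parse_datetime <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  as.POSIXct(x, format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
}

#' Format a timestamp in the log dialect (ISO-8601, millisecond precision)
#' @param t POSIXct vector.
#' @return character vector like `"2024-03-01T20:00:00.000"`.
#' @export
format_datetime <- function(t) {
  # %OS3 truncates; bias by half a millisecond so the printed value is the
  # rounded one and write->read->write is stable
  format(t + 5e-4, format = "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

#' Define a light cycle
#'
#' @param lights_off time of day at which lights go off: `"HH:MM"` /
#'   `"HH:MM:SS"` string or numeric hours in `[0, 24)`.
#' @param dark_hours length of the dark phase in hours (0 < dark_hours < 24).
#' @return an object of class `light_cycle` with elements `lights_off_h`
#'   and `dark_hours`.
#' @examples
#' lc <- light_cycle("08:00", 12)   # 12:12, lights off at 0800 h
#' to_zeitgeber(parse_datetime("2024-03-01T20:00:00"), lc)  # ZT 0
#' @export
light_cycle <- function(lights_off = "08:00", dark_hours = 12) {
  if (is.character(lights_off)) {
    p <- as.numeric(strsplit(lights_off, ":", fixed = TRUE)[[1]])
    if (any(is.na(p))) stop("light_cycle: cannot parse lights_off '", lights_off, "'")
    lights_off <- p[1] + (if (length(p) >= 2) p[2] / 60 else 0) +
      (if (length(p) >= 3) p[3] / 3600 else 0)
  }
  lights_off <- as.numeric(lights_off) %% 24
  dark_hours <- as.numeric(dark_hours)
  if (!(dark_hours > 0 && dark_hours < 24)) {
    stop("light_cycle: dark_hours must be in (0, 24), got ", dark_hours)
  }
  structure(list(lights_off_h = lights_off, dark_hours = dark_hours),
            class = "light_cycle")
}

clock_hours <- function(t) {
  (as.numeric(t) / 3600) %% 24
}

#' Convert absolute time to Zeitgeber time
#'
#' ZT0 is the lights-on instant (standard chronobiology convention); the
#' dark phase spans `[24 - dark_hours, 24)`, i.e. ZT12-24 for a 12:12
#' cycle. Periodic with 24 h.
#'
#' @param t POSIXct vector (or numeric seconds since the epoch, UTC).
#' @param lc a [light_cycle()].
#' @return numeric ZT hours in `[0, 24)`.
#' @export
to_zeitgeber <- function(t, lc) {
  stopifnot(inherits(lc, "light_cycle"))
  lights_on <- (lc$lights_off_h + lc$dark_hours) %% 24
  (clock_hours(t) - lights_on) %% 24
}

#' Is a time point in the dark phase?
#'
#' Dark is the half-open interval `[lights_off, lights_on)`, i.e.
#' `ZT >= 24 - dark_hours`.
#'
#' @inheritParams to_zeitgeber
#' @return logical vector.
#' @export
is_dark <- function(t, lc) {
  to_zeitgeber(t, lc) >= 24 - lc$dark_hours
}

#' Describe a fluid
#'
#' @param label fluid label used in log files (no commas or quotes).
#' @param ethanol_fraction_vv ethanol volume fraction in `[0, 1]`
#'   (10 percent v/v = 0.10).
#' @param density_g_per_mL density of pure ethanol used for dose
#'   conversion; default 0.789 g/mL (room temperature).
#' @param is_water flag; defaults to `ethanol_fraction_vv == 0`. A water
#'   fluid must have ethanol fraction 0.
#' @return object of class `fluid_spec`.
#' @export
fluid_spec <- function(label, ethanol_fraction_vv = 0,
                       density_g_per_mL = 0.789, is_water = NULL) {
  if (is.null(is_water)) is_water <- ethanol_fraction_vv == 0
  if (ethanol_fraction_vv < 0 || ethanol_fraction_vv > 1) {
    stop("fluid_spec: ethanol_fraction_vv must be in [0, 1]")
  }
  if (is_water && ethanol_fraction_vv != 0) {
    stop("fluid_spec: a water fluid cannot have ethanol_fraction_vv > 0")
  }
  structure(list(label = as.character(label),
                 ethanol_fraction_vv = as.numeric(ethanol_fraction_vv),
                 density_g_per_mL = as.numeric(density_g_per_mL),
                 is_water = isTRUE(is_water)),
            class = "fluid_spec")
}

#' Subject registry (RFID to subject mapping with body mass)
#'
#' @param subject_id character vector of short subject labels.
#' @param rfid character vector of RFID tag codes; must be unique.
#' @param body_mass_g positive body masses in grams.
#' @param notes optional free-text notes.
#' @return a `subject_registry` data frame with one row per subject.
#' @export
subject_registry <- function(subject_id, rfid, body_mass_g, notes = "") {
  subject_id <- as.character(subject_id)
  rfid <- as.character(rfid)
  if (anyDuplicated(rfid)) stop("subject_registry: rfid codes must be unique")
  if (anyDuplicated(subject_id)) stop("subject_registry: subject_id must be unique")
  body_mass_g <- as.numeric(body_mass_g)
  if (any(!is.finite(body_mass_g)) || any(body_mass_g <= 0)) {
    stop("subject_registry: body_mass_g must be positive")
  }
  out <- data.frame(subject_id = subject_id, rfid = rfid,
                    body_mass_g = body_mass_g,
                    notes = rep_len(as.character(notes), length(subject_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("subject_registry", "data.frame")
  out
}

#' Ethanol dose in g per kg body mass
#'
#' `volume_mL * ethanol_fraction_vv * density_g_per_mL / (body_mass_g/1000)`.
#' Water (ethanol fraction 0) gives 0 by construction.
#'
#' @param volume_mL consumed volume in mL (vectorised).
#' @param fluid a [fluid_spec()] (or a one-row slice of a fluid table with
#'   the same fields).
#' @param subject a subject: numeric body mass in grams, or a list/one-row
#'   data frame with a `body_mass_g` field.
#' @return dose in g ethanol per kg body mass.
#' @examples
#' ethanol_dose_g_per_kg(12, fluid_spec("etoh10", 0.10), 300)  # 3.156
#' @export
ethanol_dose_g_per_kg <- function(volume_mL, fluid, subject) {
  mass_g <- if (is.numeric(subject)) subject else subject$body_mass_g
  if (length(mass_g) != 1 || !is.finite(mass_g) || mass_g <= 0) {
    stop("ethanol_dose_g_per_kg: invalid subject: body mass must be a single positive number")
  }
  volume_mL * fluid$ethanol_fraction_vv * fluid$density_g_per_mL / (mass_g / 1000)
}

#' Build the per-device fluid table of an experiment
#'
#' @param ... named arguments `device_id = fluid_spec(...)`.
#' @return data frame with columns `device_id`, `label`,
#'   `ethanol_fraction_vv`, `density_g_per_mL`, `is_water`.
#' @examples
#' device_fluids(E = fluid_spec("etoh10", 0.10), W = fluid_spec("water"))
#' @export
device_fluids <- function(...) {
  specs <- list(...)
  if (length(specs) < 1 || is.null(names(specs)) || any(names(specs) == "")) {
    stop("device_fluids: supply named device_id = fluid_spec(...) arguments")
  }
  stopifnot(all(vapply(specs, inherits, TRUE, "fluid_spec")))
  data.frame(device_id = names(specs),
             label = vapply(specs, `[[`, "", "label"),
             ethanol_fraction_vv = vapply(specs, `[[`, 0, "ethanol_fraction_vv"),
             density_g_per_mL = vapply(specs, `[[`, 0, "density_g_per_mL"),
             is_water = vapply(specs, `[[`, TRUE, "is_water"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Experiment configuration
#'
#' Collects the light cycle, the device-to-fluid mapping, analysis
#' thresholds and the pump calibration into one object. Defaults describe
#' a two-bottle-choice experiment: 10 percent v/v ethanol vs tap water, 12:12
#' light cycle with lights off at 0800 h, bouts defined as drinking events
#' of at least 20 licks.
#'
#' @param light_cycle a [light_cycle()].
#' @param fluids per-device fluid table from [device_fluids()].
#' @param min_licks_per_bout analysis bout threshold (default 20 licks).
#' @param bout_gap_s inter-lick gap that delimits a drinking event
#'   (firmware bout termination; default 10 s).
#' @param lick_bin_edges ascending lick-count edges for bout-range
#'   histograms; an open-ended top bin is added automatically. Default
#'   `c(20, 45, 70, 95, 120, 145, 170, 195)` gives 8 ranges.
#' @param pump_uL_per_step pump calibration constant, microlitre per motor
#'   step (> 0).
#' @param steps_per_lick pump steps issued per detected lick while the tag
#'   is present.
#' @param pump_noise_cv coefficient of variation of the actually delivered
#'   per-step volume (mechanical noise; 0 = ideal pump).
#' @param experiment_start absolute start of the experiment (POSIXct or
#'   ISO-8601 string); day boundaries are 24 h windows from this instant.
#' @param retry_mean_s mean of the exponential retry delay when a rat
#'   finds the spout occupied.
#' @param max_retries retries before a blocked bout attempt is dropped.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(light_cycle = lickometry::light_cycle("08:00", 12),
                              fluids = device_fluids(
                                E = fluid_spec("etoh10", 0.10),
                                W = fluid_spec("water")),
                              min_licks_per_bout = 20,
                              bout_gap_s = 10,
                              lick_bin_edges = c(20, 45, 70, 95, 120, 145, 170, 195),
                              pump_uL_per_step = 1.0,
                              steps_per_lick = 5,
                              pump_noise_cv = 0.15,
                              experiment_start = "2024-03-01T20:00:00",
                              retry_mean_s = 30,
                              max_retries = 3) {
  if (is.character(experiment_start)) experiment_start <- parse_datetime(experiment_start)
  if (!inherits(experiment_start, "POSIXct") || is.na(experiment_start)) {
    stop("experiment_config: experiment_start must be a valid timestamp")
  }
  if (min_licks_per_bout < 1) stop("experiment_config: min_licks_per_bout must be >= 1")
  if (any(diff(lick_bin_edges) <= 0)) {
    stop("experiment_config: lick_bin_edges must be strictly ascending")
  }
  if (pump_uL_per_step <= 0) stop("experiment_config: pump_uL_per_step must be > 0")
  if (bout_gap_s <= 0) stop("experiment_config: bout_gap_s must be > 0")
  if (pump_noise_cv < 0) stop("experiment_config: pump_noise_cv must be >= 0")
  stopifnot(inherits(light_cycle, "light_cycle"), is.data.frame(fluids))
  if (anyDuplicated(fluids$device_id)) {
    stop("experiment_config: device ids must be unique")
  }
  structure(list(light_cycle = light_cycle,
                 fluids = fluids,
                 min_licks_per_bout = as.integer(min_licks_per_bout),
                 bout_gap_s = as.numeric(bout_gap_s),
                 lick_bin_edges = as.numeric(lick_bin_edges),
                 pump_uL_per_step = as.numeric(pump_uL_per_step),
                 steps_per_lick = as.integer(steps_per_lick),
                 pump_noise_cv = as.numeric(pump_noise_cv),
                 experiment_start = experiment_start,
                 retry_mean_s = as.numeric(retry_mean_s),
                 max_retries = as.integer(max_retries)),
            class = "experiment_config")
}

#' Day index of a timestamp within an experiment
#'
#' Days are 24 h windows counted from `experiment_start` (not calendar
#' midnight); day 0 is the first.
#'
#' @param t POSIXct vector.
#' @param config an [experiment_config()].
#' @return integer day indices.
#' @export
day_index <- function(t, config) {
  as.integer(floor((as.numeric(t) - as.numeric(config$experiment_start)) / 86400))
}

#' Session log: ordered bout (and optional lick) records plus metadata
#'
#' The unit of I/O and analysis: the device's timestamped per-bout log
#' together with the experiment configuration and the subject registry.
#' Bouts are stored sorted by start time (ties keep input order).
#'
#' @param bouts data frame with columns `datetime` (POSIXct), `device_id`,
#'   `fluid`, `rfid`, `licks`, `volume_mL`, `duration_s` (`NA` allowed).
#' @param config an [experiment_config()].
#' @param subjects a [subject_registry()].
#' @param licks optional lick-level data frame with columns `datetime`,
#'   `device_id`, `rfid`.
#' @param on_unknown_rfid `"warn"` (keep rows, warn) or `"error"`.
#' @return object of class `session_log`.
#' @export
session_log <- function(bouts, config, subjects, licks = NULL,
                        on_unknown_rfid = c("warn", "error")) {
  on_unknown_rfid <- match.arg(on_unknown_rfid)
  stopifnot(inherits(config, "experiment_config"),
            inherits(subjects, "subject_registry"))
  need <- c("datetime", "device_id", "fluid", "rfid", "licks", "volume_mL", "duration_s")
  miss <- setdiff(need, names(bouts))
  if (length(miss)) stop("session_log: bouts missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(bouts)) {
    if (any(bouts$licks < 0, na.rm = TRUE)) stop("session_log: negative lick counts")
    if (any(bouts$volume_mL < 0, na.rm = TRUE)) stop("session_log: negative volumes")
    unknown <- setdiff(unique(bouts$rfid), subjects$rfid)
    if (length(unknown)) {
      msg <- paste0("unknown RFID(s) not in registry: ", paste(unknown, collapse = ", "))
      if (on_unknown_rfid == "error") stop("session_log: ", msg) else warning("session_log: ", msg)
    }
    bouts <- bouts[order(bouts$datetime), , drop = FALSE]
    rownames(bouts) <- NULL
  }
  if (!is.null(licks) && nrow(licks)) {
    licks <- licks[order(licks$datetime), , drop = FALSE]
    rownames(licks) <- NULL
  }
  structure(list(bouts = bouts, licks = licks, config = config,
                 subjects = subjects),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  nb <- nrow(x$bouts)
  cat("<session_log> ", nb, " bouts, ",
      if (is.null(x$licks)) "no lick stream" else paste0(nrow(x$licks), " licks"),
      ", ", nrow(x$subjects), " subjects, ",
      nrow(x$config$fluids), " devices\n", sep = "")
  if (nb) {
    cat("  span: ", format_datetime(min(x$bouts$datetime)), " .. ",
        format_datetime(max(x$bouts$datetime)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.experiment_config <- function(x, ...) {
  lc <- x$light_cycle
  cat("<experiment_config> lights off at ",
      sprintf("%05.2f h", lc$lights_off_h), ", ", lc$dark_hours, " h dark; ",
      nrow(x$fluids), " device(s); bout >= ", x$min_licks_per_bout,
      " licks, gap ", x$bout_gap_s, " s; pump ", x$pump_uL_per_step,
      " uL/step x ", x$steps_per_lick, " steps/lick\n", sep = "")
  invisible(x)
}

# map device_id -> fluid label / spec row
fluid_for_device <- function(config, device_id) {
  i <- match(device_id, config$fluids$device_id)
  if (anyNA(i)) stop("unknown device_id: ",
                     paste(unique(device_id[is.na(i)]), collapse = ", "))
  config$fluids[i, , drop = FALSE]
}

subject_for_rfid <- function(subjects, rfid) {
  subjects$subject_id[match(rfid, subjects$rfid)]
}
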