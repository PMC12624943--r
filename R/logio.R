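# Log dialects (normative for this toolkit; ISO-8601 timestamps, RFC-4180
# quoting). Bout level matches what the device logs per drinking event;
# lick level matches the updated firmware's per-lick stream.
BOUT_COLUMNS <- c("datetime", "device_id", "fluid", "rfid", "licks",
                  "volume_mL", "duration_s")
LICK_COLUMNS <- c("datetime", "device_id", "rfid")

# minimal RFC-4180 field quoting
csv_quote <- function(x) {
  x <- as.character(x)
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

csv_line <- function(...) paste(csv_quote(c(...)), collapse = ",")

#' Read a device log file
#'
#' Parses a bout-level or lick-level CSV log into a [session_log()].
#' Rows are sorted by timestamp (stable for ties); rows that violate the
#' record invariants (unparseable timestamp or number, negative lick count
#' or volume) are excluded and reported with their line numbers in the
#' `problems` attribute. Unknown RFIDs are kept but flagged with a
#' warning. Extra columns beyond the dialect are ignored.
#'
#' @param path path to the CSV log.
#' @param dialect `"bout"` or `"lick"`.
#' @param registry a [subject_registry()].
#' @param config an [experiment_config()].
#' @param licks_path optional lick-level log to attach when
#'   `dialect = "bout"`.
#' @return a [session_log()]; attribute `"problems"` holds a data frame of
#'   row-level issues (line, field, message).
#' @export
read_log <- function(path, dialect = c("bout", "lick"), registry, config,
                     licks_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_log: no such file: ", path)
  cols <- if (dialect == "bout") BOUT_COLUMNS else LICK_COLUMNS
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  miss <- setdiff(cols, names(raw))
  if (length(miss)) {
    stop("read_log: log header does not match the ", dialect,
         " dialect; missing column(s): ", paste(miss, collapse = ", "))
  }
  problems <- data.frame(line = integer(), field = character(),
                         message = character(), stringsAsFactors = FALSE)
  note <- function(lines, field, msg) {
    if (length(lines)) {
      problems <<- rbind(problems, data.frame(
        line = lines, field = field, message = msg, stringsAsFactors = FALSE))
    }
  }
  lineno <- seq_len(nrow(raw)) + 1L  # header is line 1

  dt <- parse_datetime(raw$datetime)
  bad <- is.na(dt)
  note(lineno[bad], "datetime", "unparseable timestamp")

  if (dialect == "bout") {
    licks <- suppressWarnings(as.numeric(raw$licks))
    vol <- suppressWarnings(as.numeric(raw$volume_mL))
    dur <- suppressWarnings(ifelse(raw$duration_s == "", NA, raw$duration_s))
    dur <- suppressWarnings(as.numeric(dur))
    b <- is.na(licks) & raw$licks != ""
    note(lineno[b], "licks", "unparseable number"); bad <- bad | b
    b <- !is.na(licks) & (licks < 0 | licks != floor(licks))
    note(lineno[b], "licks", "lick count must be a nonnegative integer"); bad <- bad | b
    b <- is.na(vol)
    note(lineno[b], "volume_mL", "unparseable number"); bad <- bad | b
    b <- !is.na(vol) & vol < 0
    note(lineno[b], "volume_mL", "volume must be nonnegative"); bad <- bad | b
    b <- !is.na(dur) & dur < 0
    note(lineno[b], "duration_s", "duration must be nonnegative"); bad <- bad | b
    keep <- !bad
    df <- data.frame(datetime = dt[keep], device_id = raw$device_id[keep],
                     fluid = raw$fluid[keep], rfid = raw$rfid[keep],
                     licks = as.integer(licks[keep]), volume_mL = vol[keep],
                     duration_s = dur[keep], stringsAsFactors = FALSE)
  } else {
    keep <- !bad
    df <- data.frame(datetime = dt[keep], device_id = raw$device_id[keep],
                     rfid = raw$rfid[keep], stringsAsFactors = FALSE)
  }
  if (nrow(problems)) {
    warning("read_log: ", nrow(problems), " row-level problem(s); ",
            "offending rows excluded (see attr(, 'problems'))")
  }
  if (nrow(df) > 1 && is.unsorted(df$datetime)) {
    warning("read_log: rows out of time order; sorted by timestamp")
  }
  sess <- if (dialect == "bout") {
    lk <- if (!is.null(licks_path)) {
      read_log(licks_path, "lick", registry, config)$licks
    } else NULL
    session_log(df, config, registry, licks = lk)
  } else {
    empty <- data.frame(datetime = dt[0], device_id = character(),
                        fluid = character(), rfid = character(),
                        licks = integer(), volume_mL = numeric(),
                        duration_s = numeric(), stringsAsFactors = FALSE)
    session_log(empty, config, registry, licks = df)
  }
  attr(sess, "problems") <- problems
  sess
}

#' Write a session to a device log file
#'
#' Timestamps are written in ISO-8601 at millisecond resolution; volumes
#' and durations with 3 decimals (microlitre precision). `write_log`
#' followed by [read_log()] is the identity on the records at stored
#' resolution; extinction-probe rows (volume 0, licks > 0) round-trip
#' verbatim.
#'
#' @param session a [session_log()].
#' @param path output path.
#' @param dialect `"bout"` or `"lick"` (lick requires a lick stream).
#' @return `path`, invisibly.
#' @export
write_log <- function(session, path, dialect = c("bout", "lick")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(session, "session_log"))
  con <- file(path, "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  if (dialect == "bout") {
    b <- session$bouts
    lines <- c(csv_line(BOUT_COLUMNS),
               if (nrow(b)) paste(format_datetime(b$datetime),
                                  csv_quote(b$device_id), csv_quote(b$fluid),
                                  csv_quote(b$rfid), b$licks,
                                  sprintf("%.3f", b$volume_mL),
                                  ifelse(is.na(b$duration_s), "",
                                         sprintf("%.3f", b$duration_s)),
                                  sep = ","))
  } else {
    if (is.null(session$licks)) stop("write_log: session has no lick stream")
    l <- session$licks
    lines <- c(csv_line(LICK_COLUMNS),
               if (nrow(l)) paste(format_datetime(l$datetime),
                                  csv_quote(l$device_id), csv_quote(l$rfid),
                                  sep = ","))
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read / write a subject registry file
#'
#' CSV with columns `subject_id,rfid,body_mass_g` (optional `notes`).
#'
#' @param path file path.
#' @return [read_registry()] returns a [subject_registry()].
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("subject_id", "rfid", "body_mass_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_registry: missing column(s): ", paste(miss, collapse = ", "))
  subject_registry(df$subject_id, df$rfid, as.numeric(df$body_mass_g),
                   notes = if ("notes" %in% names(df)) df$notes else "")
}

#' @rdname read_registry
#' @param registry a [subject_registry()].
#' @export
write_registry <- function(registry, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c(csv_line(c("subject_id", "rfid", "body_mass_g", "notes")),
               if (nrow(registry)) paste(csv_quote(registry$subject_id),
                                         csv_quote(registry$rfid),
                                         sprintf("%g", registry$body_mass_g),
                                         csv_quote(registry$notes), sep = ",")),
             con, sep = "\n")
  invisible(path)
}

#' Read / write an experiment config file
#'
#' Flat `key=value` text file; `#` starts a comment. Keys mirror the
#' fields of [experiment_config()]: `lights_off`, `dark_hours`,
#' `min_licks_per_bout`, `bout_gap_s`, `lick_bin_edges` (comma-separated),
#' `pump_uL_per_step`, `steps_per_lick`, `pump_noise_cv`,
#' `experiment_start`, `retry_mean_s`, `max_retries`, and per device
#' `fluid.<device>.label`, `fluid.<device>.ethanol_fraction`,
#' `fluid.<device>.density`. Unknown keys are an error.
#'
#' @param path file path.
#' @return [read_config()] returns an [experiment_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  eq <- regexpr("=", ln, fixed = TRUE)
  if (any(eq < 0)) stop("read_config: malformed line (no '='): ", ln[eq < 0][1])
  keys <- trimws(substr(ln, 1, eq - 1))
  vals <- trimws(substr(ln, eq + 1, nchar(ln)))
  kv <- stats::setNames(as.list(vals), keys)

  scalar_keys <- c("lights_off", "dark_hours", "min_licks_per_bout",
                   "bout_gap_s", "lick_bin_edges", "pump_uL_per_step",
                   "steps_per_lick", "pump_noise_cv", "experiment_start",
                   "retry_mean_s", "max_retries")
  fluid_key <- grepl("^fluid\\.[^.]+\\.(label|ethanol_fraction|density)$", keys)
  bad <- keys[!(keys %in% scalar_keys) & !fluid_key]
  if (length(bad)) stop("read_config: unknown config key(s): ", paste(bad, collapse = ", "))

  num <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("read_config: key '", key, "' is not a number: ", kv[[key]])
    v
  }
  devs <- unique(sub("^fluid\\.([^.]+)\\..*$", "\\1", keys[fluid_key]))
  fluids <- if (length(devs)) {
    do.call(rbind, lapply(devs, function(d) {
      data.frame(device_id = d,
                 label = kv[[paste0("fluid.", d, ".label")]] %||% d,
                 ethanol_fraction_vv = num(paste0("fluid.", d, ".ethanol_fraction"), 0),
                 density_g_per_mL = num(paste0("fluid.", d, ".density"), 0.789),
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  if (!is.null(fluids)) fluids$is_water <- fluids$ethanol_fraction_vv == 0

  default <- experiment_config()
  lo <- kv[["lights_off"]] %||% "08:00"
  experiment_config(
    light_cycle = light_cycle(lo, num("dark_hours", 12)),
    fluids = if (is.null(fluids)) default$fluids else fluids,
    min_licks_per_bout = num("min_licks_per_bout", 20),
    bout_gap_s = num("bout_gap_s", 10),
    lick_bin_edges = if (is.null(kv[["lick_bin_edges"]])) default$lick_bin_edges
                     else as.numeric(strsplit(kv[["lick_bin_edges"]], ",")[[1]]),
    pump_uL_per_step = num("pump_uL_per_step", 1.0),
    steps_per_lick = num("steps_per_lick", 5),
    pump_noise_cv = num("pump_noise_cv", 0.15),
    experiment_start = kv[["experiment_start"]] %||% "2024-03-01T20:00:00",
    retry_mean_s = num("retry_mean_s", 30),
    max_retries = num("max_retries", 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @param config an [experiment_config()].
#' @export
write_config <- function(config, path) {
  lc <- config$light_cycle
  ln <- c(sprintf("lights_off=%g", lc$lights_off_h),
          sprintf("dark_hours=%g", lc$dark_hours),
          sprintf("min_licks_per_bout=%d", config$min_licks_per_bout),
          sprintf("bout_gap_s=%g", config$bout_gap_s),
          paste0("lick_bin_edges=", paste(config$lick_bin_edges, collapse = ",")),
          sprintf("pump_uL_per_step=%g", config$pump_uL_per_step),
          sprintf("steps_per_lick=%d", config$steps_per_lick),
          sprintf("pump_noise_cv=%g", config$pump_noise_cv),
          paste0("experiment_start=", format_datetime(config$experiment_start)),
          sprintf("retry_mean_s=%g", config$retry_mean_s),
          sprintf("max_retries=%d", config$max_retries),
          unlist(lapply(seq_len(nrow(config$fluids)), function(i) {
            f <- config$fluids[i, ]
            c(sprintf("fluid.%s.label=%s", f$device_id, f$label),
              sprintf("fluid.%s.ethanol_fraction=%g", f$device_id, f$ethanol_fraction_vv),
              sprintf("fluid.%s.density=%g", f$device_id, f$density_g_per_mL))
          })))
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(ln, con, sep = "\n")
  invisible(path)
}

# count/list overlapping bout pairs on one device; intervals [s, s+d)
overlap_pairs <- function(start_s, dur_s) {
  n <- length(start_s)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  o <- order(start_s)
  s <- start_s[o]; e <- s + dur_s[o]
  out_i <- integer(); out_j <- integer()
  for (i in seq_len(n - 1)) {
    if (!is.finite(e[i]) || e[i] <= s[i]) next
    # indices j > i with s[j] strictly below e[i]
    hi <- findInterval(e[i], s, left.open = TRUE)
    if (hi > i) { out_i <- c(out_i, rep(i, hi - i)); out_j <- c(out_j, (i + 1):hi) }
  }
  data.frame(i = o[out_i], j = o[out_j])
}

#' Validate a session log
#'
#' Checks the device-exclusivity invariant (only one rat is measured at a
#' time, so bouts on one device must not overlap), RFIDs against the
#' registry, field sanity (negative or missing numbers), timestamp order,
#' and physiologically implausible durations (a bout of n licks cannot be
#' shorter than (n-1) x 30 ms -- rats do not lick above ~12 Hz).
#'
#' @param session a [session_log()].
#' @return object of class `session_validation`: data frames `overlaps`,
#'   `unknown_rfid`, `bad_fields`, `implausible_duration`, a logical
#'   `sorted`, and the overlap count `n_overlap_violations`.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session_log"))
  b <- session$bouts
  t0 <- as.numeric(session$config$experiment_start)

  overlaps <- data.frame(device_id = character(), row_i = integer(),
                         row_j = integer(), overlap_s = numeric(),
                         stringsAsFactors = FALSE)
  if (nrow(b)) {
    for (dev in unique(b$device_id)) {
      idx <- which(b$device_id == dev)
      d <- ifelse(is.na(b$duration_s[idx]), 0, b$duration_s[idx])
      s <- as.numeric(b$datetime[idx]) - t0
      op <- overlap_pairs(s, d)
      if (nrow(op)) {
        ov <- pmin(s[op$i] + d[op$i], s[op$j] + d[op$j]) - pmax(s[op$i], s[op$j])
        overlaps <- rbind(overlaps, data.frame(
          device_id = dev, row_i = idx[op$i], row_j = idx[op$j],
          overlap_s = ov, stringsAsFactors = FALSE))
      }
    }
  }

  unk <- which(!(b$rfid %in% session$subjects$rfid))
  unknown_rfid <- data.frame(row = unk, rfid = b$rfid[unk], stringsAsFactors = FALSE)

  bad <- data.frame(row = integer(), field = character(), stringsAsFactors = FALSE)
  flag <- function(rows, field) {
    if (length(rows)) bad <<- rbind(bad, data.frame(row = rows, field = field,
                                                    stringsAsFactors = FALSE))
  }
  if (nrow(b)) {
    flag(which(is.na(b$licks) | b$licks < 0), "licks")
    flag(which(is.na(b$volume_mL) | b$volume_mL < 0 | is.nan(b$volume_mL)), "volume_mL")
    flag(which(!is.na(b$duration_s) & b$duration_s < 0), "duration_s")
  }

  imp <- if (nrow(b)) {
    which(!is.na(b$duration_s) & b$licks >= 2 &
            b$duration_s < (b$licks - 1) * 0.03)
  } else integer()
  implausible <- data.frame(row = imp, licks = b$licks[imp],
                            duration_s = b$duration_s[imp], stringsAsFactors = FALSE)

  structure(list(overlaps = overlaps,
                 unknown_rfid = unknown_rfid,
                 bad_fields = bad,
                 implausible_duration = implausible,
                 sorted = !is.unsorted(b$datetime),
                 n_overlap_violations = nrow(overlaps)),
            class = "session_validation")
}

#' @export
print.session_validation <- function(x, ...) {
  cat("<session_validation>\n",
      "  exclusivity (device-overlap) violations: ", x$n_overlap_violations, "\n",
      "  unknown RFIDs: ", nrow(x$unknown_rfid), "\n",
      "  bad fields: ", nrow(x$bad_fields), "\n",
      "  implausible durations: ", nrow(x$implausible_duration), "\n",
      "  timestamps sorted: ", x$sorted, "\n", sep = "")
  invisible(x)
}

#' Does a validation report contain any violation?
#' @param report a `session_validation`.
#' @return logical.
#' @export
has_violations <- function(report) {
  report$n_overlap_violations > 0 || nrow(report$unknown_rfid) > 0 ||
    nrow(report$bad_fields) > 0 || nrow(report$implausible_duration) > 0
}

#' Plant device-exclusivity violations in a clean session (testing utility)
#'
#' Inserts `k` synthetic bouts, each strictly contained in the time
#' interval of a distinct existing bout on the same device, so that the
#' corrupted session has exactly `k` overlapping bout pairs. Used to
#' verify that [validate_session()] finds precisely what was planted.
#'
#' @param session a clean [session_log()] (zero overlap violations).
#' @param k number of violations to plant.
#' @param seed RNG seed for victim selection.
#' @return a corrupted [session_log()].
#' @export
plant_overlaps <- function(session, k, seed = 1) {
  stopifnot(inherits(session, "session_log"), k >= 1)
  b <- session$bouts
  cand <- which(!is.na(b$duration_s) & b$duration_s >= 0.2)
  if (length(cand) < k) stop("plant_overlaps: not enough bouts with usable durations")
  set.seed(seed)
  victims <- sample(cand, k)
  extra <- b[victims, , drop = FALSE]
  extra$datetime <- extra$datetime + round(extra$duration_s * 0.25, 3)
  extra$duration_s <- round(extra$duration_s * 0.5, 3)
  extra$licks <- pmax(20L, extra$licks %/% 2L)
  extra$volume_mL <- round(extra$volume_mL / 2, 3)
  session_log(rbind(b, extra), session$config, session$subjects,
              licks = session$licks)
}
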