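# Drinking-microstructure metrics from a session log. All outputs are
# long-format "metric tables": one row per (subject, fluid, stratum,
# metric), with units attached and undefined ratios flagged rather than
# silently zeroed.

metric_table <- function(subject_id = NA_character_, fluid = NA_character_,
                         day = NA_integer_, phase = NA_character_,
                         zt_hour = NA_integer_, lick_bin = NA_character_,
                         metric, value, units, flag = NA_character_) {
  out <- data.frame(subject_id = subject_id, fluid = fluid, day = day,
                    phase = phase, zt_hour = zt_hour, lick_bin = lick_bin,
                    metric = metric, value = value, units = units,
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("metric_table", "data.frame")
  out
}

rbind_metrics <- function(...) {
  out <- do.call(rbind, Filter(Negate(is.null), list(...)))
  class(out) <- c("metric_table", "data.frame")
  rownames(out) <- NULL
  out
}

# label for a lick-count range given ascending integer edges
lick_bin_label <- function(licks, edges) {
  k <- findInterval(licks, edges)
  labs <- c(paste0("<", edges[1]),
            ifelse(seq_along(edges) < length(edges),
                   paste0(edges, "-", c(edges[-1] - 1, NA)),
                   paste0(edges, "+")))
  labs[k + 1]
}

lick_bin_levels <- function(edges) {
  c(ifelse(seq_along(edges) < length(edges),
           paste0(edges, "-", c(edges[-1] - 1, NA)),
           paste0(edges, "+")))
}

#' Filter and annotate bouts for analysis
#'
#' Keeps bouts with at least `min_licks` licks (a bout is a drinking
#' event of at least 20 licks by default) and annotates each with the
#' subject, day index from experiment start, Zeitgeber time, light/dark
#' phase and lick-count range. Bouts whose RFID is not in the registry
#' are dropped with a warning.
#'
#' @param session a [session_log()].
#' @param min_licks bout threshold; default from the session config.
#' @param n_days analysis window length in days; default the number of
#'   24 h windows needed to cover the data (minimum 1). Bouts outside
#'   `[start, start + n_days)` are excluded so that every aggregation
#'   sees the same analysis window; days with no bouts are enumerated,
#'   not dropped, by the downstream metrics.
#' @return a `bout_table` data frame (bout columns plus `subject_id`,
#'   `day`, `zt`, `zt_hour`, `phase`, `lick_bin`); attributes `n_removed`,
#'   `n_days`, `config`, `registry`.
#' @export
filter_bouts <- function(session, min_licks = NULL, n_days = NULL) {
  stopifnot(inherits(session, "session_log"))
  config <- session$config
  if (is.null(min_licks)) min_licks <- config$min_licks_per_bout
  b <- session$bouts
  if (is.null(n_days)) {
    n_days <- if (nrow(b)) max(1L, max(day_index(b$datetime, config)) + 1L) else 1L
  }
  unknown <- !(b$rfid %in% session$subjects$rfid)
  if (any(unknown)) {
    warning("filter_bouts: dropping ", sum(unknown), " bout(s) with unknown RFID")
    b <- b[!unknown, , drop = FALSE]
  }
  # restrict to the analysis window [start, start + n_days) so every
  # aggregation (daily, phase, hourly, lick-range) sees the same bouts
  dayi <- day_index(b$datetime, config)
  outside <- dayi < 0 | dayi >= n_days
  if (any(outside)) b <- b[!outside, , drop = FALSE]
  keep <- b$licks >= min_licks
  n_removed <- sum(!keep)
  b <- b[keep, , drop = FALSE]
  b$subject_id <- subject_for_rfid(session$subjects, b$rfid)
  b$day <- day_index(b$datetime, config)
  b$zt <- to_zeitgeber(b$datetime, config$light_cycle)
  b$zt_hour <- as.integer(floor(b$zt)) %% 24L
  b$phase <- ifelse(is_dark(b$datetime, config$light_cycle), "dark", "light")
  b$lick_bin <- lick_bin_label(b$licks, config$lick_bin_edges)
  rownames(b) <- NULL
  structure(b, class = c("bout_table", "data.frame"),
            n_removed = n_removed, n_days = as.integer(n_days),
            config = config, registry = session$subjects,
            min_licks = min_licks)
}

bt_meta <- function(bt) {
  list(config = attr(bt, "config"), registry = attr(bt, "registry"),
       n_days = attr(bt, "n_days"))
}

# sum `values` over the full grid of the given keys, filling 0
grid_sum <- function(df, values, keys, grid) {
  if (nrow(df)) {
    agg <- stats::aggregate(df[[values]], df[keys], sum)
    names(agg)[ncol(agg)] <- "value"
    out <- merge(grid, agg, by = keys, all.x = TRUE, sort = FALSE)
  } else {
    out <- grid
    out$value <- NA_real_
  }
  out$value[is.na(out$value)] <- 0
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Daily fluid intake per subject
#'
#' Raw intake in mL per subject, fluid and day, and daily ethanol dose in
#' g/kg per subject (summed over ethanol-containing fluids, converted via
#' volume x ethanol fraction x density / body mass). Days without bouts
#' are enumerated with intake 0.
#'
#' @param bt a `bout_table` from [filter_bouts()].
#' @return a `metric_table` with metrics `intake_mL` (per subject-fluid-
#'   day) and `ethanol_intake_g_per_kg` (per subject-day).
#' @export
daily_intake <- function(bt) {
  m <- bt_meta(bt)
  subjects <- m$registry$subject_id
  fluids <- unique(m$config$fluids$label)
  days <- seq_len(m$n_days) - 1L
  grid <- expand.grid(subject_id = subjects, fluid = fluids, day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mL <- grid_sum(as.data.frame(bt), "volume_mL",
                 c("subject_id", "fluid", "day"), grid)
  out_mL <- metric_table(subject_id = mL$subject_id, fluid = mL$fluid,
                         day = mL$day, metric = "intake_mL",
                         value = mL$value, units = "mL")

  fl <- m$config$fluids
  fl <- fl[!duplicated(fl$label), ]
  i <- match(bt$fluid, fl$label)
  mass <- m$registry$body_mass_g[match(bt$subject_id, m$registry$subject_id)]
  if (anyNA(mass) && nrow(bt)) {
    stop("daily_intake: no body mass for subject(s): ",
         paste(unique(bt$subject_id[is.na(mass)]), collapse = ", "))
  }
  dosed <- as.data.frame(bt)
  dosed$dose <- if (nrow(bt)) {
    bt$volume_mL * fl$ethanol_fraction_vv[i] * fl$density_g_per_mL[i] / (mass / 1000)
  } else numeric(0)
  gridd <- expand.grid(subject_id = subjects, day = days,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gk <- grid_sum(dosed, "dose", c("subject_id", "day"), gridd)
  out_gkg <- metric_table(subject_id = gk$subject_id, day = gk$day,
                          metric = "ethanol_intake_g_per_kg",
                          value = gk$value, units = "g/kg")
  rbind_metrics(out_mL, out_gkg)
}

#' Two-bottle preference
#'
#' Ethanol preference as a percentage of total fluid intake by volume:
#' `100 * ethanol mL / (ethanol mL + water mL)`, per subject-day or over
#' the whole window. Undefined when nothing was drunk (flagged, not 0).
#'
#' @param bt a `bout_table`.
#' @param per `"day"` or `"overall"`.
#' @return a `metric_table` with metric `preference_pct`.
#' @export
preference <- function(bt, per = c("day", "overall")) {
  per <- match.arg(per)
  m <- bt_meta(bt)
  fl <- m$config$fluids[!duplicated(m$config$fluids$label), ]
  eth_labels <- fl$label[!fl$is_water]
  b <- as.data.frame(bt)
  b$is_eth <- b$fluid %in% eth_labels
  subjects <- m$registry$subject_id
  if (per == "day") {
    grid <- expand.grid(subject_id = subjects, day = seq_len(m$n_days) - 1L,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keys <- c("subject_id", "day")
  } else {
    grid <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
    keys <- "subject_id"
  }
  eth <- grid_sum(b[b$is_eth, , drop = FALSE], "volume_mL", keys, grid)
  wat <- grid_sum(b[!b$is_eth, , drop = FALSE], "volume_mL", keys, grid)
  tot <- eth$value + wat$value
  val <- ifelse(tot > 0, 100 * eth$value / tot, NA_real_)
  metric_table(subject_id = eth$subject_id,
               day = if (per == "day") eth$day else NA_integer_,
               metric = "preference_pct", value = val, units = "%",
               flag = ifelse(tot > 0, NA_character_, "undefined"))
}

#' Hourly intake profile in Zeitgeber time
#'
#' Fluid consumption binned by hour of Zeitgeber time (24 half-open bins
#' `[h, h+1)`), averaged across the days of the analysis window: each
#' bin holds total mL in that ZT hour divided by `n_days`, so the bins
#' times `n_days` sum back to the total volume.
#'
#' @param bt a `bout_table`.
#' @return a `metric_table` with metric `intake_mL_per_h` per subject,
#'   fluid and ZT hour.
#' @export
hourly_zt_profile <- function(bt) {
  m <- bt_meta(bt)
  grid <- expand.grid(subject_id = m$registry$subject_id,
                      fluid = unique(m$config$fluids$label),
                      zt_hour = 0:23,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- grid_sum(as.data.frame(bt), "volume_mL",
                  c("subject_id", "fluid", "zt_hour"), grid)
  metric_table(subject_id = agg$subject_id, fluid = agg$fluid,
               zt_hour = agg$zt_hour, metric = "intake_mL_per_h",
               value = agg$value / m$n_days, units = "mL")
}

#' Light/dark-phase intake totals
#'
#' Consumption during the light and the dark phase, per subject, fluid
#' and day (the two phases partition each day, so light + dark equals the
#' daily total exactly), plus the mean across days per phase.
#'
#' @param bt a `bout_table`.
#' @return a `metric_table` with metrics `phase_intake_mL` (per day) and
#'   `mean_phase_intake_mL` (day = NA).
#' @export
phase_totals <- function(bt) {
  m <- bt_meta(bt)
  grid <- expand.grid(subject_id = m$registry$subject_id,
                      fluid = unique(m$config$fluids$label),
                      day = seq_len(m$n_days) - 1L,
                      phase = c("light", "dark"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- grid_sum(as.data.frame(bt), "volume_mL",
                  c("subject_id", "fluid", "day", "phase"), grid)
  per_day <- metric_table(subject_id = agg$subject_id, fluid = agg$fluid,
                          day = agg$day, phase = agg$phase,
                          metric = "phase_intake_mL", value = agg$value,
                          units = "mL")
  mn <- stats::aggregate(value ~ subject_id + fluid + phase, agg, mean)
  means <- metric_table(subject_id = mn$subject_id, fluid = mn$fluid,
                        phase = mn$phase, metric = "mean_phase_intake_mL",
                        value = mn$value, units = "mL")
  rbind_metrics(per_day, means)
}

#' Bout-size statistics
#'
#' Per subject and fluid over the analysis window: mean and max bout
#' volume (mL), volume per lick (total mL / total licks, a pooled
#' per-lick estimate), and bout frequency (bouts per day, counting
#' zero-bout days in the denominator). Lick-count variants of bout size
#' are also emitted, explicitly labelled. Empty strata are flagged.
#'
#' @param bt a `bout_table`.
#' @return a `metric_table` with metrics `mean_bout_volume_mL`,
#'   `max_bout_volume_mL`, `volume_per_lick_mL`, `bout_frequency_per_day`,
#'   `mean_bout_licks`, `max_bout_licks`.
#' @export
bout_stats <- function(bt) {
  m <- bt_meta(bt)
  grid <- expand.grid(subject_id = m$registry$subject_id,
                      fluid = unique(m$config$fluids$label),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b <- as.data.frame(bt)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- b[b$subject_id == grid$subject_id[i] & b$fluid == grid$fluid[i], ]
    n <- nrow(g)
    empty_flag <- if (n == 0) "empty" else NA_character_
    v <- function(x) if (n) x else NA_real_
    metric_table(
      subject_id = grid$subject_id[i], fluid = grid$fluid[i],
      metric = c("mean_bout_volume_mL", "max_bout_volume_mL",
                 "volume_per_lick_mL", "bout_frequency_per_day",
                 "mean_bout_licks", "max_bout_licks"),
      value = c(v(mean(g$volume_mL)), v(max(g$volume_mL, -Inf)),
                if (n && sum(g$licks) > 0) sum(g$volume_mL) / sum(g$licks) else NA_real_,
                n / m$n_days,
                v(mean(g$licks)), v(max(g$licks, -Inf))),
      units = c("mL", "mL", "mL", "bouts/day", "licks", "licks"),
      flag = c(empty_flag, empty_flag,
               if (n && sum(g$licks) > 0) NA_character_ else
                 if (n) "undefined" else "empty",
               NA_character_, empty_flag, empty_flag))
  })
  do.call(rbind_metrics, rows)
}

#' Volume by lick-count bout range
#'
#' Each bout is assigned to one lick-count range (ascending edges with an
#' open top bin; 8 ranges by default). Emits volume per subject, fluid
#' and range, the pooled per-fluid volume per range, and the per-fluid
#' normalized fraction (fractions sum to 1 per fluid when its total is
#' positive).
#'
#' @param bt a `bout_table`.
#' @param edges optional override of the lick-count edges; the first edge
#'   should not exceed the bout threshold used for filtering (bouts below
#'   the first edge are reported with a warning).
#' @return a `metric_table` with metrics `bin_volume_mL` (per subject),
#'   `bin_volume_mL_total` and `bin_volume_fraction` (per fluid).
#' @export
bout_range_volumes <- function(bt, edges = NULL) {
  m <- bt_meta(bt)
  if (is.null(edges)) edges <- m$config$lick_bin_edges
  if (any(diff(edges) <= 0)) stop("bout_range_volumes: edges must be strictly ascending")
  b <- as.data.frame(bt)
  b$lick_bin <- lick_bin_label(b$licks, edges)
  below <- sum(b$licks < edges[1])
  if (below > 0) {
    warning("bout_range_volumes: ", below, " bout(s) below the first edge (",
            edges[1], " licks); binned as '<", edges[1], "'")
  }
  levs <- lick_bin_levels(edges)
  if (below > 0) levs <- c(paste0("<", edges[1]), levs)
  grid <- expand.grid(subject_id = m$registry$subject_id,
                      fluid = unique(m$config$fluids$label),
                      lick_bin = levs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- grid_sum(b, "volume_mL", c("subject_id", "fluid", "lick_bin"), grid)
  per_subj <- metric_table(subject_id = agg$subject_id, fluid = agg$fluid,
                           lick_bin = agg$lick_bin, metric = "bin_volume_mL",
                           value = agg$value, units = "mL")
  gridf <- expand.grid(fluid = unique(m$config$fluids$label), lick_bin = levs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  aggf <- grid_sum(b, "volume_mL", c("fluid", "lick_bin"), gridf)
  tot <- stats::ave(aggf$value, aggf$fluid, FUN = sum)
  frac <- ifelse(tot > 0, aggf$value / tot, NA_real_)
  per_fluid <- rbind_metrics(
    metric_table(fluid = aggf$fluid, lick_bin = aggf$lick_bin,
                 metric = "bin_volume_mL_total", value = aggf$value, units = "mL"),
    metric_table(fluid = aggf$fluid, lick_bin = aggf$lick_bin,
                 metric = "bin_volume_fraction", value = frac, units = "fraction",
                 flag = ifelse(tot > 0, NA_character_, "undefined")))
  rbind_metrics(per_subj, per_fluid)
}

# segment a per-(rfid, device) lick stream into bouts by inter-lick gap
segment_licks <- function(times_s, gap_s) {
  if (!length(times_s)) return(integer(0))
  c(0L, cumsum(diff(times_s) > gap_s)) + 1L
}

#' Lick-level microstructure
#'
#' Requires a lick-level stream in the session. Licks are segmented into
#' bouts per (animal, device) using the configured inter-lick gap; bouts
#' below the bout threshold are discarded. Per subject and fluid:
#' mean and median interlick interval (within bouts only; pairs spanning
#' a bout boundary are excluded), mean interbout interval (end of one
#' bout to start of the next on the same device), mean bout duration
#' (first to last lick) and mean within-bout lick frequency
#' `(licks - 1) / duration`. One-lick bouts have duration 0 and no
#' defined frequency; strata with no defined value are flagged.
#'
#' @param session a [session_log()] with a lick stream.
#' @param min_licks bout threshold; default from the session config.
#' @return a `metric_table` with metrics `mean_ili_s`, `median_ili_s`,
#'   `mean_ibi_s`, `mean_bout_duration_s`, `mean_lick_freq_hz`.
#' @export
lick_microstructure <- function(session, min_licks = NULL) {
  stopifnot(inherits(session, "session_log"))
  if (is.null(session$licks) || nrow(session$licks) == 0) {
    stop("lick_microstructure: lick-level data required (session has no lick stream)")
  }
  config <- session$config
  if (is.null(min_licks)) min_licks <- config$min_licks_per_bout
  l <- session$licks
  l <- l[l$rfid %in% session$subjects$rfid, , drop = FALSE]
  l$subject_id <- subject_for_rfid(session$subjects, l$rfid)
  l$fluid <- fluid_for_device(config, l$device_id)$label
  l$t <- as.numeric(l$datetime)

  per_bout <- list()
  for (key in unique(paste(l$rfid, l$device_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- l[l$rfid == parts[1] & l$device_id == parts[2], , drop = FALSE]
    g <- g[order(g$t), , drop = FALSE]
    bid <- segment_licks(g$t, config$bout_gap_s)
    for (bb in unique(bid)) {
      tt <- g$t[bid == bb]
      n <- length(tt)
      if (n < min_licks) next
      per_bout[[length(per_bout) + 1L]] <- list(
        subject_id = g$subject_id[1], fluid = g$fluid[1],
        device_id = parts[2],
        start = tt[1], end = tt[n], n = n,
        duration = tt[n] - tt[1],
        ilis = if (n > 1) diff(tt) else numeric(0))
    }
  }
  subjects <- session$subjects$subject_id
  fluids <- unique(config$fluids$label)
  grid <- expand.grid(subject_id = subjects, fluid = fluids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    bs <- Filter(function(pb) pb$subject_id == grid$subject_id[i] &&
                   pb$fluid == grid$fluid[i], per_bout)
    if (!length(bs)) {
      return(metric_table(subject_id = grid$subject_id[i], fluid = grid$fluid[i],
                          metric = c("mean_ili_s", "median_ili_s", "mean_ibi_s",
                                     "mean_bout_duration_s", "mean_lick_freq_hz"),
                          value = NA_real_,
                          units = c("s", "s", "s", "s", "Hz"), flag = "empty"))
    }
    ilis <- unlist(lapply(bs, `[[`, "ilis"))
    durs <- vapply(bs, `[[`, 0, "duration")
    ns <- vapply(bs, `[[`, 0, "n")
    freqs <- (ns[ns > 1] - 1) / durs[ns > 1]
    # interbout gaps per device, bout end to next bout start
    ibis <- numeric(0)
    for (dv in unique(vapply(bs, `[[`, "", "device_id"))) {
      bd <- bs[vapply(bs, `[[`, "", "device_id") == dv]
      if (length(bd) >= 2) {
        o <- order(vapply(bd, `[[`, 0, "start"))
        st <- vapply(bd, `[[`, 0, "start")[o]
        en <- vapply(bd, `[[`, 0, "end")[o]
        ibis <- c(ibis, st[-1] - en[-length(en)])
      }
    }
    vals <- c(if (length(ilis)) mean(ilis) else NA_real_,
              if (length(ilis)) stats::median(ilis) else NA_real_,
              if (length(ibis)) mean(ibis) else NA_real_,
              mean(durs),
              if (length(freqs)) mean(freqs) else NA_real_)
    metric_table(subject_id = grid$subject_id[i], fluid = grid$fluid[i],
                 metric = c("mean_ili_s", "median_ili_s", "mean_ibi_s",
                            "mean_bout_duration_s", "mean_lick_freq_hz"),
                 value = vals, units = c("s", "s", "s", "s", "Hz"),
                 flag = ifelse(is.na(vals), "undefined", NA_character_))
  })
  do.call(rbind_metrics, rows)
}

#' Wide per-subject summary
#'
#' A compact wide table with the headline quantities per subject and
#' fluid: total and mean daily intake (mL), overall preference (%), mean
#' daily ethanol dose (g/kg), bout statistics, and the dark-phase share
#' of volume.
#'
#' @param bt a `bout_table`.
#' @return a data frame, one row per subject x fluid.
#' @export
session_summary <- function(bt) {
  m <- bt_meta(bt)
  di <- daily_intake(bt)
  pr <- preference(bt, per = "overall")
  bs <- bout_stats(bt)
  ph <- phase_totals(bt)
  grid <- expand.grid(subject_id = m$registry$subject_id,
                      fluid = unique(m$config$fluids$label),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pick <- function(tab, metric, keys) {
    t2 <- tab[tab$metric == metric, c(keys, "value")]
    names(t2)[ncol(t2)] <- metric
    t2
  }
  mL <- stats::aggregate(value ~ subject_id + fluid,
                         di[di$metric == "intake_mL", ], sum)
  names(mL)[3] <- "total_mL"
  out <- merge(grid, mL, by = c("subject_id", "fluid"), all.x = TRUE)
  out$mean_daily_mL <- out$total_mL / m$n_days
  for (met in c("mean_bout_volume_mL", "max_bout_volume_mL",
                "volume_per_lick_mL", "bout_frequency_per_day")) {
    out <- merge(out, pick(bs, met, c("subject_id", "fluid")),
                 by = c("subject_id", "fluid"), all.x = TRUE)
  }
  dk <- stats::aggregate(value ~ subject_id + fluid,
                         ph[ph$metric == "phase_intake_mL" & ph$phase == "dark", ], sum)
  names(dk)[3] <- "dark_mL"
  out <- merge(out, dk, by = c("subject_id", "fluid"), all.x = TRUE)
  out$dark_share_pct <- ifelse(out$total_mL > 0, 100 * out$dark_mL / out$total_mL, NA)
  out <- merge(out, pick(pr, "preference_pct", "subject_id"),
               by = "subject_id", all.x = TRUE)
  gk <- stats::aggregate(value ~ subject_id,
                         di[di$metric == "ethanol_intake_g_per_kg", ], mean)
  names(gk)[2] <- "mean_daily_g_per_kg"
  out <- merge(out, gk, by = "subject_id", all.x = TRUE)
  out[order(out$subject_id, out$fluid), ]
}

#' Plot an hourly Zeitgeber profile
#'
#' Minimal base-graphics line plot of per-fluid mean hourly intake for
#' one subject, with the dark phase shaded.
#'
#' @param mt `metric_table` from [hourly_zt_profile()].
#' @param subject subject to plot (default: first present).
#' @param dark_from ZT hour at which the dark phase starts (12 for 12:12).
#' @export
plot_zt_profile <- function(mt, subject = NULL, dark_from = 12) {
  h <- mt[mt$metric == "intake_mL_per_h", ]
  if (is.null(subject)) subject <- h$subject_id[1]
  h <- h[h$subject_id == subject, ]
  fluids <- unique(h$fluid)
  ylim <- c(0, max(h$value, 0.01))
  graphics::plot(NULL, xlim = c(0, 24), ylim = ylim, xlab = "Zeitgeber time (h)",
                 ylab = "intake (mL/h)", main = subject, xaxs = "i")
  graphics::rect(dark_from, ylim[1], 24, ylim[2] * 1.04,
                 col = "grey92", border = NA)
  for (i in seq_along(fluids)) {
    g <- h[h$fluid == fluids[i], ]
    graphics::lines(g$zt_hour + 0.5, g$value, type = "b", pch = 16,
                    col = i, lty = i)
  }
  graphics::legend("topleft", legend = fluids, col = seq_along(fluids),
                   lty = seq_along(fluids), pch = 16, bty = "n")
  graphics::box()
  invisible(h)
}
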