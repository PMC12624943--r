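# Digital twin of the device: per-rat stochastic drinking shaped by the
# light cycle and fluid preference, passed through a firmware model
# (RFID gating, exclusive spout occupancy, lick-driven step-quantized
# pump) and logged the way the device logs.

#' Per-rat behavioural parameters
#'
#' Defaults describe an adult rat in a two-bottle-choice experiment with
#' strong dark-phase drinking and an alcohol preference: bout initiations
#' at 5/h in the dark vs 1.25/h in the light (about 75 drinking events per
#' day, ~30 mL/day total fluid), lognormal lick counts per bout (median 70
#' licks), and a ~6.7 Hz licking rhythm (gamma inter-lick intervals with
#' mean 0.15 s, shape 20).
#'
#' @param subject_id subject label (must exist in the registry used for
#'   simulation).
#' @param bout_rate_dark,bout_rate_light bout initiation rates, bouts/h.
#' @param ethanol_choice_p probability that a bout is directed at the
#'   ethanol spout (in `[0, 1]`).
#' @param lick_count_logmean,lick_count_logsd log-scale parameters of the
#'   lognormal lick count per bout (rounded to an integer >= 1).
#' @param interlick_mean_s mean inter-lick interval, seconds (> 0).
#' @param interlick_shape gamma shape of the inter-lick interval.
#' @return one-row data frame of class `rat_behavior`.
#' @export
rat_behavior <- function(subject_id,
                         bout_rate_dark = 5,
                         bout_rate_light = 1.25,
                         ethanol_choice_p = 0.7,
                         lick_count_logmean = log(70),
                         lick_count_logsd = 0.6,
                         interlick_mean_s = 0.15,
                         interlick_shape = 20) {
  if (bout_rate_dark < 0 || bout_rate_light < 0) {
    stop("rat_behavior: bout rates must be >= 0")
  }
  if (ethanol_choice_p < 0 || ethanol_choice_p > 1) {
    stop("rat_behavior: ethanol_choice_p must be in [0, 1]")
  }
  if (interlick_mean_s <= 0 || interlick_shape <= 0) {
    stop("rat_behavior: inter-lick parameters must be positive")
  }
  out <- data.frame(subject_id = as.character(subject_id),
                    bout_rate_dark = bout_rate_dark,
                    bout_rate_light = bout_rate_light,
                    ethanol_choice_p = ethanol_choice_p,
                    lick_count_logmean = lick_count_logmean,
                    lick_count_logsd = lick_count_logsd,
                    interlick_mean_s = interlick_mean_s,
                    interlick_shape = interlick_shape,
                    stringsAsFactors = FALSE)
  class(out) <- c("rat_behavior", "data.frame")
  out
}

#' Default behaviour table for a small group of rats
#'
#' Individual differences mimic what group-housed rats show: one strongly
#' alcohol-preferring animal, one near-indifferent, the rest in between.
#'
#' @param subject_ids subject labels (2-8 rats typical).
#' @return behaviour table (one `rat_behavior` row per subject).
#' @export
default_behaviors <- function(subject_ids = paste0("rat", 1:4)) {
  n <- length(subject_ids)
  p <- rep_len(c(0.85, 0.75, 0.70, 0.50), n)
  rd <- rep_len(c(5, 6, 4.5, 5.5), n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rat_behavior(subject_ids[i], bout_rate_dark = rd[i],
                 bout_rate_light = rd[i] / 4, ethanol_choice_p = p[i])
  }))
}

#' Read / write a behaviour table CSV
#'
#' Columns: `subject_id,bout_rate_dark,bout_rate_light,ethanol_choice_p,`
#' `lick_count_logmean,lick_count_logsd,interlick_mean_s,interlick_shape`.
#'
#' @param path file path.
#' @export
read_behaviors <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  need <- c("subject_id", "bout_rate_dark", "bout_rate_light", "ethanol_choice_p",
            "lick_count_logmean", "lick_count_logsd", "interlick_mean_s",
            "interlick_shape")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_behaviors: missing column(s): ",
                         paste(miss, collapse = ", "))
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    do.call(rat_behavior, as.list(df[i, need]))
  }))
}

#' @rdname read_behaviors
#' @param behaviors a behaviour table.
#' @export
write_behaviors <- function(behaviors, path) {
  con <- file(path, "wb"); on.exit(close(con))
  cols <- c("subject_id", "bout_rate_dark", "bout_rate_light", "ethanol_choice_p",
            "lick_count_logmean", "lick_count_logsd", "interlick_mean_s",
            "interlick_shape")
  writeLines(c(paste(cols, collapse = ","),
               apply(behaviors[, cols], 1, function(r) paste(trimws(r), collapse = ","))),
             con, sep = "\n")
  invisible(path)
}

#' Pump model
#'
#' The peristaltic pump is driven by a stepper motor: dispensed volume is
#' an integer number of steps times a calibration constant, with optional
#' multiplicative per-step mechanical noise (i.i.d. Normal(1, cv),
#' truncated at 0). The device meters volume as steps x uL_per_step; the
#' noise affects only what is actually delivered.
#'
#' @param uL_per_step calibration constant, microlitre per step (> 0).
#' @param steps_per_lick steps issued per detected lick.
#' @param noise_cv coefficient of variation of the delivered per-step
#'   volume (0 = ideal pump).
#' @return object of class `pump_model`.
#' @export
pump_model <- function(uL_per_step = 1.0, steps_per_lick = 5, noise_cv = 0.15) {
  if (uL_per_step <= 0) stop("pump_model: uL_per_step must be > 0")
  if (noise_cv < 0) stop("pump_model: noise_cv must be >= 0")
  if (steps_per_lick < 1) stop("pump_model: steps_per_lick must be >= 1")
  structure(list(uL_per_step = uL_per_step,
                 steps_per_lick = as.integer(steps_per_lick),
                 noise_cv = noise_cv), class = "pump_model")
}

#' @rdname pump_model
#' @param config an [experiment_config()]; builds the pump from its keys.
#' @export
pump_from_config <- function(config) {
  pump_model(config$pump_uL_per_step, config$steps_per_lick, config$pump_noise_cv)
}

# light/dark segments of [0, duration_h] hours, in seconds from start
phase_segments <- function(config, duration_h) {
  lc <- config$light_cycle
  zt0 <- to_zeitgeber(config$experiment_start, lc)
  D <- duration_h
  # ZT values at which the phase flips
  flips <- sort(c((24 - lc$dark_hours - zt0) %% 24 + 24 * (0:ceiling(D / 24 + 1)),
                  (24 - zt0) %% 24 + 24 * (0:ceiling(D / 24 + 1))))
  flips <- unique(flips[flips > 0 & flips < D])
  bounds <- c(0, flips, D)
  mid <- (utils::head(bounds, -1) + utils::tail(bounds, -1)) / 2
  data.frame(start_s = utils::head(bounds, -1) * 3600,
             end_s = utils::tail(bounds, -1) * 3600,
             dark = ((zt0 + mid) %% 24) >= 24 - lc$dark_hours)
}

#' Simulate a group-housed drinking session
#'
#' For each rat, bout initiations are drawn from an inhomogeneous Poisson
#' process whose rate is `bout_rate_dark` during the dark phase and
#' `bout_rate_light` during the light phase. Each bout is directed at the
#' ethanol spout with probability `ethanol_choice_p`, carries a lognormal
#' lick count, and a lick train with gamma inter-lick intervals. The
#' firmware model then enforces exclusive spout occupancy (a rat arriving
#' at a busy spout retries after an exponential delay, up to
#' `config$max_retries` times, else the attempt is dropped) and delivers
#' `steps_per_lick` pump steps per lick; logged volume is
#' `steps x uL_per_step x noise / 1000` mL rounded to 3 decimals.
#'
#' All randomness flows from one seeded generator in a fixed order (per
#' rat: segment bout counts and times, fluid choices, lick counts, lick
#' trains; then retry delays in event order; then pump noise), so equal
#' `(parameters, seed)` give byte-identical logs.
#'
#' @param behaviors behaviour table ([rat_behavior()] rows).
#' @param config an [experiment_config()].
#' @param registry a [subject_registry()] covering every subject in
#'   `behaviors`.
#' @param duration_h session length in hours (> 0).
#' @param seed integer RNG seed (reproducibility is mandatory).
#' @param pump a [pump_model()]; defaults to the config's pump.
#' @param include_licks keep the per-lick stream in the session (the lick
#'   trains are always drawn, so this does not change the RNG path).
#' @return list with elements `session` (a [session_log()] that passes
#'   [validate_session()] with zero violations) and `truth` (a
#'   `ground_truth` object: the intended schedule, per-attempt outcomes,
#'   and true delivered volumes before logging rounding).
#' @export
simulate_session <- function(behaviors, config, registry, duration_h, seed,
                             pump = pump_from_config(config),
                             include_licks = TRUE) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(registry, "subject_registry"),
            inherits(pump, "pump_model"))
  if (!is.numeric(duration_h) || duration_h <= 0) {
    stop("simulate_session: duration_h must be > 0")
  }
  if (missing(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("simulate_session: an integer seed is required")
  }
  bh <- as.data.frame(behaviors)
  need <- c("subject_id", "bout_rate_dark", "bout_rate_light", "ethanol_choice_p",
            "lick_count_logmean", "lick_count_logsd", "interlick_mean_s",
            "interlick_shape")
  miss <- setdiff(need, names(bh))
  if (length(miss)) stop("simulate_session: behaviors missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(bh$bout_rate_dark < 0) || any(bh$bout_rate_light < 0) ||
      any(bh$ethanol_choice_p < 0 | bh$ethanol_choice_p > 1) ||
      any(bh$interlick_mean_s <= 0) || any(bh$interlick_shape <= 0)) {
    stop("simulate_session: invalid behaviour parameters")
  }
  if (!all(bh$subject_id %in% registry$subject_id)) {
    stop("simulate_session: behaviors name subjects missing from the registry: ",
         paste(setdiff(bh$subject_id, registry$subject_id), collapse = ", "))
  }
  set.seed(as.integer(seed))

  fl <- config$fluids
  eth_dev <- fl$device_id[!fl$is_water]
  wat_dev <- fl$device_id[fl$is_water]
  if (!length(eth_dev)) eth_dev <- wat_dev
  if (!length(wat_dev)) wat_dev <- eth_dev

  segs <- phase_segments(config, duration_h)

  # 1) intended schedules, rat by rat
  sched <- vector("list", nrow(bh))
  ili_list <- list()
  for (r in seq_len(nrow(bh))) {
    p <- bh[r, ]
    t_s <- numeric(0)
    for (s in seq_len(nrow(segs))) {
      rate <- if (segs$dark[s]) p$bout_rate_dark else p$bout_rate_light
      len_h <- (segs$end_s[s] - segs$start_s[s]) / 3600
      n <- stats::rpois(1, rate * len_h)
      if (n > 0) t_s <- c(t_s, sort(stats::runif(n, segs$start_s[s], segs$end_s[s])))
    }
    n <- length(t_s)
    u <- stats::runif(n)
    dev <- ifelse(u < p$ethanol_choice_p, eth_dev[1], wat_dev[1])
    licks <- pmax(1L, as.integer(round(stats::rlnorm(n, p$lick_count_logmean,
                                                     p$lick_count_logsd))))
    ilis <- lapply(licks, function(k) {
      if (k > 1) stats::rgamma(k - 1L, shape = p$interlick_shape,
                               rate = p$interlick_shape / p$interlick_mean_s)
      else numeric(0)
    })
    sched[[r]] <- data.frame(subject_id = rep(p$subject_id, n), t_intended_s = t_s,
                             device_id = as.character(dev), licks = licks,
                             duration_s = vapply(ilis, sum, 0),
                             stringsAsFactors = FALSE)
    ili_list <- c(ili_list, ilis)
  }
  intended <- do.call(rbind, sched)
  if (is.null(intended) || nrow(intended) == 0) {
    intended <- data.frame(subject_id = character(), t_intended_s = numeric(),
                           device_id = character(), licks = integer(),
                           duration_s = numeric(), stringsAsFactors = FALSE)
  }
  intended$bout_id <- seq_len(nrow(intended))

  # 2) firmware occupancy resolution, chronological with retries
  n <- nrow(intended)
  t_att <- intended$t_intended_s
  retries <- rep(config$max_retries, n)
  pending <- rep(TRUE, n)
  outcome <- rep(NA_character_, n)
  t_actual <- rep(NA_real_, n)
  deferred <- rep(0L, n)
  dev_ids <- unique(fl$device_id)
  dev_busy <- stats::setNames(rep(-Inf, length(dev_ids)), dev_ids)
  rat_busy <- stats::setNames(rep(-Inf, nrow(bh)), bh$subject_id)
  while (any(pending)) {
    idx <- which(pending)
    i <- idx[which.min(t_att[idx])]
    tt <- t_att[i]
    dv <- intended$device_id[i]
    rt <- intended$subject_id[i]
    if (tt >= dev_busy[[dv]] && tt >= rat_busy[[rt]]) {
      pending[i] <- FALSE
      outcome[i] <- "logged"
      t_actual[i] <- tt
      until <- tt + intended$duration_s[i] + config$bout_gap_s
      dev_busy[[dv]] <- until
      rat_busy[[rt]] <- until
    } else if (retries[i] > 0) {
      retries[i] <- retries[i] - 1L
      deferred[i] <- deferred[i] + 1L
      t_att[i] <- tt + stats::rexp(1, 1 / config$retry_mean_s)
    } else {
      pending[i] <- FALSE
      outcome[i] <- "dropped"
    }
  }
  intended$outcome <- outcome
  intended$n_deferrals <- deferred
  intended$t_actual_s <- t_actual

  acc <- which(outcome == "logged")
  acc <- acc[order(t_actual[acc])]

  # 3) pump: steps while tag present and licking, with per-step noise
  steps <- intended$licks[acc] * pump$steps_per_lick
  if (length(steps) && sum(steps) > 0) {
    if (pump$noise_cv > 0) {
      z <- pmax(0, stats::rnorm(sum(steps), 1, pump$noise_cv))
      cz <- cumsum(z)
      ends <- cumsum(steps)
      step_sum <- cz[ends] - c(0, cz[utils::head(ends, -1)])
    } else {
      step_sum <- as.numeric(steps)
    }
    delivered_uL <- pump$uL_per_step * step_sum
  } else {
    delivered_uL <- numeric(0)
  }
  intended$delivered_uL_true <- rep(NA_real_, nrow(intended))
  intended$delivered_uL_true[acc] <- delivered_uL

  start <- config$experiment_start
  bouts <- data.frame(
    datetime = start + round(intended$t_actual_s[acc], 3),
    device_id = intended$device_id[acc],
    fluid = fluid_for_device(config, intended$device_id[acc])$label,
    rfid = registry$rfid[match(intended$subject_id[acc], registry$subject_id)],
    licks = intended$licks[acc],
    volume_mL = round(delivered_uL / 1000, 3),
    duration_s = round(intended$duration_s[acc], 3),
    stringsAsFactors = FALSE)

  licks_df <- NULL
  if (include_licks && length(acc)) {
    offs <- lapply(acc, function(i) c(0, cumsum(ili_list[[i]])))
    nl <- lengths(offs)
    licks_df <- data.frame(
      datetime = start + round(rep(intended$t_actual_s[acc], nl) + unlist(offs), 3),
      device_id = rep(intended$device_id[acc], nl),
      rfid = rep(bouts$rfid, nl),
      stringsAsFactors = FALSE)
  } else if (include_licks) {
    licks_df <- data.frame(datetime = start[0], device_id = character(),
                           rfid = character(), stringsAsFactors = FALSE)
  }

  session <- session_log(bouts, config, registry, licks = licks_df)
  truth <- structure(list(intended = intended,
                          pump = pump,
                          duration_h = duration_h,
                          seed = as.integer(seed),
                          n_dropped = sum(outcome == "dropped"),
                          n_deferred = sum(deferred > 0)),
                     class = "ground_truth")
  list(session = session, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$intended), " intended bouts; ",
      sum(x$intended$outcome == "logged"), " logged, ",
      x$n_dropped, " dropped (occupancy), ",
      x$n_deferred, " deferred at least once; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Bench-style pump dispense test
#'
#' Emulates the bench calibration protocol: the pump is activated until
#' the metered cumulative volume (steps x uL_per_step, what the display
#' reads) first reaches `target_mL`; the delivered volume includes the
#' per-step mechanical noise. Repeated `n_repeats` times without
#' resetting. With `noise_cv = 0` every absolute percent error is bounded
#' by one step's volume over the target (pure quantization).
#'
#' @param pump a [pump_model()].
#' @param n_repeats number of trials (>= 1; the bench protocol used 20).
#' @param target_mL metered target per trial (> 0; bench protocol 1.00 mL).
#' @param seed integer RNG seed.
#' @return object of class `dispense_test`: `$trials` data frame (trial,
#'   steps, metered_mL, delivered_mL, error_pct, abs_error_pct) and
#'   `$summary` (mean signed and absolute percent error, sd, two-sided
#'   95 percent t-interval for the mean signed error, and the linear drift slope
#'   of error against trial index).
#' @export
simulate_dispense_test <- function(pump, n_repeats = 20, target_mL = 1.00,
                                   seed = 1) {
  stopifnot(inherits(pump, "pump_model"), n_repeats >= 1, target_mL > 0)
  set.seed(as.integer(seed))
  steps <- ceiling(target_mL * 1000 / pump$uL_per_step)
  metered <- steps * pump$uL_per_step / 1000
  delivered <- vapply(seq_len(n_repeats), function(i) {
    if (pump$noise_cv > 0) {
      pump$uL_per_step * sum(pmax(0, stats::rnorm(steps, 1, pump$noise_cv))) / 1000
    } else metered
  }, 0)
  err <- 100 * (delivered - target_mL) / target_mL
  trials <- data.frame(trial = seq_len(n_repeats), steps = steps,
                       metered_mL = metered, delivered_mL = delivered,
                       error_pct = err, abs_error_pct = abs(err))
  m <- mean(err)
  s <- stats::sd(err)
  ci <- if (n_repeats > 1 && s > 0) {
    m + stats::qt(c(0.025, 0.975), n_repeats - 1) * s / sqrt(n_repeats)
  } else c(m, m)
  slope <- if (n_repeats > 2 && s > 0) {
    unname(stats::coef(stats::lm(err ~ trials$trial))[2])
  } else 0
  structure(list(trials = trials,
                 summary = list(mean_error_pct = m,
                                mean_abs_error_pct = mean(abs(err)),
                                sd_error_pct = s,
                                ci95_lo = ci[1], ci95_hi = ci[2],
                                drift_slope_pct_per_trial = slope)),
            class = "dispense_test")
}

#' @export
print.dispense_test <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<dispense_test> %d trials: mean error %+.3f%% ",
                     "(95%% CI %+.3f..%+.3f), mean |error| %.3f%%\n"),
              nrow(x$trials), s$mean_error_pct, s$ci95_lo, s$ci95_hi,
              s$mean_abs_error_pct))
  invisible(x)
}

#' Apply an RFID access policy to a session
#'
#' Access to a device can be restricted per animal and time window; the
#' lickometer stays active when access is denied, so denied bouts keep
#' their lick counts but log volume 0 (extinction-probe semantics).
#'
#' @param session a [session_log()].
#' @param policy data frame with columns `rfid`, `device_id`, `start`,
#'   `end` (POSIXct or ISO-8601 strings) and optional `action`
#'   (`"deny"`, the default, or `"allow"`; allow rows are no-ops since
#'   access defaults to allowed). `NA` in `rfid` or `device_id` is a
#'   wildcard. An empty policy is the identity.
#' @return the gated [session_log()].
#' @export
apply_access_policy <- function(session, policy) {
  stopifnot(inherits(session, "session_log"))
  if (is.null(policy) || nrow(policy) == 0) return(session)
  need <- c("rfid", "device_id", "start", "end")
  miss <- setdiff(need, names(policy))
  if (length(miss)) stop("apply_access_policy: policy missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.character(policy$start)) policy$start <- parse_datetime(policy$start)
  if (is.character(policy$end)) policy$end <- parse_datetime(policy$end)
  if (anyNA(policy$start) || anyNA(policy$end)) {
    stop("apply_access_policy: unparseable policy window timestamps")
  }
  if (any(as.numeric(policy$end) <= as.numeric(policy$start))) {
    stop("apply_access_policy: malformed policy window (end <= start)")
  }
  action <- if ("action" %in% names(policy)) policy$action else rep("deny", nrow(policy))
  b <- session$bouts
  denied <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(policy))) {
    if (action[i] != "deny") next
    hit <- (is.na(policy$rfid[i]) | b$rfid == policy$rfid[i]) &
      (is.na(policy$device_id[i]) | b$device_id == policy$device_id[i]) &
      b$datetime >= policy$start[i] & b$datetime < policy$end[i]
    denied <- denied | hit
  }
  b$volume_mL[denied] <- 0
  session_log(b, session$config, session$subjects, licks = session$licks)
}
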