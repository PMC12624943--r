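make_bt <- function(cfg, bouts, reg = quick_registry(), n_days = NULL,
                    min_licks = NULL) {
  filter_bouts(hand_session(cfg, bouts, reg), min_licks = min_licks,
               n_days = n_days)
}

test_that("bout filter keeps exactly the bouts at or above the threshold", {
  cfg <- quick_config()  # default threshold 20 licks
  b <- bout_df(cfg, c(100, 200, 300, 400), "E",
               licks = c(25L, 19L, 20L, 3L), volume_mL = 0.1)
  bt <- make_bt(cfg, b)
  expect_equal(sort(bt$licks), c(20L, 25L))
  expect_equal(attr(bt, "n_removed"), 2L)
  bt1 <- make_bt(cfg, b, min_licks = 1)
  expect_equal(nrow(bt1), 4)
  # linear-scan oracle on a batch of random bouts
  set.seed(17)
  licks <- sample(0:200, 1000, replace = TRUE)
  br <- bout_df(cfg, seq(10, by = 30, length.out = 1000), "E",
                licks = licks, volume_mL = 0.05)
  kept <- 0L; for (k in licks) if (k >= 20) kept <- kept + 1L
  expect_equal(nrow(make_bt(cfg, br)), kept)
})

test_that("filter annotations carry day, ZT, phase and lick bin", {
  cfg <- quick_config()  # start 2024-03-01T20:00 = lights-on = ZT0
  b <- bout_df(cfg, c(2 * 3600, 14 * 3600, 25 * 3600), "E",
               licks = c(30L, 200L, 46L), volume_mL = 0.1)
  bt <- make_bt(cfg, b)
  expect_equal(bt$day, c(0L, 0L, 1L))
  expect_equal(bt$zt_hour, c(2L, 14L, 1L))
  expect_equal(bt$phase, c("light", "dark", "light"))
  expect_equal(bt$lick_bin, c("20-44", "195+", "45-69"))
})

test_that("daily intake: dose arithmetic, day enumeration, additivity", {
  cfg <- quick_config()
  reg <- quick_registry()
  b <- bout_df(cfg, 3600, "E", licks = 100L, volume_mL = 12.0)
  di <- daily_intake(make_bt(cfg, b, reg, n_days = 3))
  gk <- expect_metric(di, "ethanol_intake_g_per_kg", subject = "rat1")
  expect_equal(gk$value[gk$day == 0], 3.156)       # 12 * 0.1 * 0.789 / 0.3
  expect_equal(gk$value[gk$day %in% 1:2], c(0, 0)) # empty days enumerated
  expect_equal(nrow(expect_metric(di, "intake_mL")), 4 * 2 * 3)
  # splitting the same volume across N bouts leaves the daily total fixed
  bN <- bout_df(cfg, 3600 + (0:5) * 600, "E", licks = 100L, volume_mL = 2.0)
  diN <- daily_intake(make_bt(cfg, bN, reg, n_days = 1))
  expect_equal(expect_metric(diN, "intake_mL", "rat1", "etoh10")$value, 12)
  expect_equal(expect_metric(diN, "ethanol_intake_g_per_kg", "rat1")$value, 3.156)
})

test_that("preference is a volume percentage, undefined on zero intake", {
  cfg <- quick_config(); reg <- quick_registry()
  b <- rbind(bout_df(cfg, 100, "E", 50L, 3.0),
             bout_df(cfg, 500, "W", 50L, 1.0))
  bt <- make_bt(cfg, b, reg, n_days = 1)
  pr <- preference(bt, per = "overall")
  expect_equal(pr$value[pr$subject_id == "rat1"], 75)
  r2 <- pr[pr$subject_id == "rat2", ]
  expect_true(is.na(r2$value) && r2$flag == "undefined")
  # equal volumes -> 50%
  b2 <- rbind(bout_df(cfg, 100, "E", 50L, 2.5), bout_df(cfg, 500, "W", 50L, 2.5))
  pr2 <- preference(make_bt(cfg, b2, reg, n_days = 1), per = "day")
  expect_equal(pr2$value[pr2$subject_id == "rat1" & pr2$day == 0], 50)
})

test_that("hourly ZT profile bins at the right hour and conserves volume", {
  cfg <- quick_config(); reg <- quick_registry()
  # all drinking at clock 02:30 = ZT 6.5 -> bin 6
  t_s <- (6.5 * 3600) + 86400 * (0:2)
  b <- bout_df(cfg, t_s, "E", licks = 40L, volume_mL = 0.3)
  bt <- make_bt(cfg, b, reg, n_days = 3)
  hz <- hourly_zt_profile(bt)
  h1 <- hz[hz$subject_id == "rat1" & hz$fluid == "etoh10", ]
  expect_equal(h1$value[h1$zt_hour == 6], 0.3)     # mean across 3 days
  expect_equal(sum(h1$value[h1$zt_hour != 6]), 0)
  expect_equal(sum(hz$value) * 3, 0.9)             # bins x n_days = total
})

test_that("phase totals partition each day exactly", {
  sim <- small_sim(seed = 8, duration_h = 72, n_rats = 3)
  bt <- filter_bouts(sim$session, n_days = 3)
  ph <- phase_totals(bt)
  di <- daily_intake(bt)
  pj <- expect_metric(ph, "phase_intake_mL")
  agg <- stats::aggregate(value ~ subject_id + fluid + day, pj, sum)
  dm <- expect_metric(di, "intake_mL")
  m <- merge(agg, dm[, c("subject_id", "fluid", "day", "value")],
             by = c("subject_id", "fluid", "day"))
  expect_equal(m$value.x, m$value.y, tolerance = 1e-12)
  # all-dark drinker: everything lands in the dark phase
  cfg <- quick_config(); reg <- quick_registry(1)
  bh <- rat_behavior("rat1", bout_rate_dark = 5, bout_rate_light = 0)
  s2 <- simulate_session(bh, cfg, reg, 48, seed = 2)$session
  ph2 <- phase_totals(filter_bouts(s2, n_days = 2))
  expect_equal(sum(expect_metric(ph2, "phase_intake_mL")$value[
    expect_metric(ph2, "phase_intake_mL")$phase == "light"]), 0)
})

test_that("bout statistics match hand arithmetic and scale correctly", {
  cfg <- quick_config(); reg <- quick_registry()
  b <- bout_df(cfg, c(3600, 90000), "E", licks = c(40L, 60L),
               volume_mL = c(0.2, 0.4))
  bt <- make_bt(cfg, b, reg, n_days = 2)
  bs <- bout_stats(bt)
  g <- function(met) expect_metric(bs, met, "rat1", "etoh10")$value
  expect_equal(g("mean_bout_volume_mL"), 0.3)
  expect_equal(g("max_bout_volume_mL"), 0.4)
  expect_equal(g("volume_per_lick_mL"), 0.006)
  expect_equal(g("bout_frequency_per_day"), 1.0)
  expect_equal(g("mean_bout_licks"), 50)
  # single bout: mean = max
  b1 <- bout_df(cfg, 3600, "E", 40L, 0.2)
  bs1 <- bout_stats(make_bt(cfg, b1, reg, n_days = 1))
  expect_equal(expect_metric(bs1, "mean_bout_volume_mL", "rat1", "etoh10")$value,
               expect_metric(bs1, "max_bout_volume_mL", "rat1", "etoh10")$value)
  # doubling volumes doubles sizes, leaves frequency alone
  b2 <- b; b2$volume_mL <- 2 * b$volume_mL
  bs2 <- bout_stats(make_bt(cfg, b2, reg, n_days = 2))
  g2 <- function(met) expect_metric(bs2, met, "rat1", "etoh10")$value
  expect_equal(g2("mean_bout_volume_mL"), 0.6)
  expect_equal(g2("volume_per_lick_mL"), 0.012)
  expect_equal(g2("bout_frequency_per_day"), 1.0)
  # empty strata flagged, frequency 0
  empty <- expect_metric(bs, "mean_bout_volume_mL", "rat2", "water")
  expect_true(is.na(empty$value) && empty$flag == "empty")
  expect_equal(expect_metric(bs, "bout_frequency_per_day", "rat2", "water")$value, 0)
})

test_that("bout-range volumes bin correctly and fractions sum to 1 per fluid", {
  cfg <- quick_config(); reg <- quick_registry()
  b <- bout_df(cfg, c(1, 2, 3, 4) * 3600, "E",
               licks = c(20L, 44L, 45L, 200L), volume_mL = c(0.1, 0.2, 0.3, 0.4))
  bt <- make_bt(cfg, b, reg, n_days = 1)
  brv <- bout_range_volumes(bt)
  tot <- expect_metric(brv, "bin_volume_mL_total", fluid = "etoh10")
  expect_equal(tot$value[tot$lick_bin == "20-44"], 0.3)
  expect_equal(tot$value[tot$lick_bin == "45-69"], 0.3)
  expect_equal(tot$value[tot$lick_bin == "195+"], 0.4)
  fr <- expect_metric(brv, "bin_volume_fraction", fluid = "etoh10")
  expect_equal(sum(fr$value), 1, tolerance = 1e-12)
  # single bout of one fluid -> its bin carries fraction 1
  b1 <- bout_df(cfg, 3600, "W", 80L, 0.25)
  brv1 <- bout_range_volumes(make_bt(cfg, b1, reg, n_days = 1))
  fr1 <- expect_metric(brv1, "bin_volume_fraction", fluid = "water")
  expect_equal(fr1$value[fr1$lick_bin == "70-94"], 1)
  # random bouts vs linear-scan binning oracle
  set.seed(23)
  licks <- sample(20:300, 400, replace = TRUE)
  vols <- round(runif(400, 0.05, 0.6), 3)
  br <- bout_df(cfg, seq(100, by = 200, length.out = 400), "E",
                licks = licks, volume_mL = vols)
  brv2 <- bout_range_volumes(make_bt(cfg, br, reg, n_days = 1))
  edges <- c(cfg$lick_bin_edges, Inf)
  for (k in seq_len(length(edges) - 1)) {
    oracle <- sum(vols[licks >= edges[k] & licks < edges[k + 1]])
    lab <- if (is.finite(edges[k + 1])) paste0(edges[k], "-", edges[k + 1] - 1)
           else paste0(edges[k], "+")
    tot2 <- expect_metric(brv2, "bin_volume_mL_total", fluid = "etoh10")
    expect_equal(tot2$value[tot2$lick_bin == lab], oracle)
  }
})

test_that("lick microstructure: closed forms on hand-built lick trains", {
  cfg <- loose_config()  # threshold 1 so 3-lick fixtures count as bouts
  reg <- quick_registry()
  lk <- data.frame(datetime = cfg$experiment_start + c(10, 10.15, 10.30),
                   device_id = "E", rfid = "RF000001", stringsAsFactors = FALSE)
  s <- hand_session(cfg, bout_df(cfg, numeric(0), character(0), integer(0),
                                 numeric(0), numeric(0)), reg, licks = lk)
  ms <- lick_microstructure(s)
  # tolerance: absolute times live on the POSIXct epoch scale, where
  # sub-second offsets carry ~1e-7 s float granularity
  g <- function(met) expect_metric(ms, met, "rat1", "etoh10")$value
  expect_equal(g("mean_ili_s"), 0.15, tolerance = 1e-5)
  expect_equal(g("median_ili_s"), 0.15, tolerance = 1e-5)
  expect_equal(g("mean_bout_duration_s"), 0.30, tolerance = 1e-5)
  expect_equal(g("mean_lick_freq_hz"), 2 / 0.30, tolerance = 1e-5)  # ~6.67 Hz
  # one-lick bout: duration 0, frequency flagged-undefined
  lk1 <- data.frame(datetime = cfg$experiment_start + 100, device_id = "E",
                    rfid = "RF000002", stringsAsFactors = FALSE)
  s1 <- hand_session(cfg, bout_df(cfg, numeric(0), character(0), integer(0),
                                  numeric(0), numeric(0)), reg, licks = lk1)
  ms1 <- lick_microstructure(s1)
  expect_equal(expect_metric(ms1, "mean_bout_duration_s", "rat2", "etoh10")$value, 0)
  fq <- expect_metric(ms1, "mean_lick_freq_hz", "rat2", "etoh10")
  expect_true(is.na(fq$value) && fq$flag == "undefined")
  # two bouts separated by more than the gap: IBI = end-to-start distance
  lk2 <- data.frame(datetime = cfg$experiment_start +
                      c(10, 10.2, 10.4, 100, 100.2),
                    device_id = "E", rfid = "RF000003", stringsAsFactors = FALSE)
  s2 <- hand_session(cfg, bout_df(cfg, numeric(0), character(0), integer(0),
                                  numeric(0), numeric(0)), reg, licks = lk2)
  ms2 <- lick_microstructure(s2)
  expect_equal(expect_metric(ms2, "mean_ibi_s", "rat3", "etoh10")$value, 89.6,
               tolerance = 1e-5)
  # the boundary-spanning 89.6 s gap is not an ILI
  expect_equal(expect_metric(ms2, "mean_ili_s", "rat3", "etoh10")$value, 0.2,
               tolerance = 1e-5)
  expect_error(lick_microstructure(hand_session(cfg,
    bout_df(cfg, 1, "E", 30L, 0.1), reg)), "lick-level data required")
})

test_that("metrics are invariant to input row order and log round-trip", {
  sim <- small_sim(seed = 19, duration_h = 48, n_rats = 3)
  s <- sim$session
  ref <- hourly_zt_profile(filter_bouts(s, n_days = 2))
  set.seed(5)
  shuf <- s$bouts[sample(nrow(s$bouts)), ]
  s2 <- session_log(shuf, s$config, s$subjects)
  expect_equal(hourly_zt_profile(filter_bouts(s2, n_days = 2)), ref)
  path <- withr::local_tempfile()
  write_log(s, path, "bout")
  s3 <- read_log(path, "bout", s$subjects, s$config)
  expect_equal(hourly_zt_profile(filter_bouts(s3, n_days = 2))$value, ref$value,
               tolerance = 1e-9)
  bs3 <- bout_stats(filter_bouts(s3, n_days = 2))
  bs1 <- bout_stats(filter_bouts(s, n_days = 2))
  expect_equal(bs3$value, bs1$value, tolerance = 1e-9)
})

test_that("raising the bout threshold never increases any volume total", {
  sim <- small_sim(seed = 29, duration_h = 48, n_rats = 3)
  tots <- vapply(c(1, 20, 50, 100), function(m) {
    di <- daily_intake(filter_bouts(sim$session, min_licks = m, n_days = 2))
    sum(expect_metric(di, "intake_mL")$value)
  }, 0)
  expect_true(all(diff(tots) <= 1e-12))
})

test_that("session summary agrees with its source tables", {
  sim <- small_sim(seed = 37, duration_h = 48, n_rats = 2)
  bt <- filter_bouts(sim$session, n_days = 2)
  sw <- session_summary(bt)
  bs <- bout_stats(bt)
  for (i in seq_len(nrow(sw))) {
    expect_equal(sw$mean_bout_volume_mL[i],
                 expect_metric(bs, "mean_bout_volume_mL",
                               sw$subject_id[i], sw$fluid[i])$value)
  }
  expect_equal(sum(sw$total_mL), sum(bt$volume_mL))
})
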