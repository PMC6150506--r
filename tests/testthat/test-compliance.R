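test_that("DWAS is the distance-weighted mean of in-zone segment speeds", {
  expect_equal(dwas(inzone_segments(c(1, 3), c(10, 14)), zfix$sra, pfix), 13)
  expect_equal(dwas(inzone_segments(c(2, 5, 1), c(11, 11, 11)), zfix$sra, pfix), 11)
  set.seed(4)
  for (i in 1:20) {
    sp <- stats::runif(5, 6, 18)
    d <- dwas(inzone_segments(stats::runif(5, 0.5, 3), sp), zfix$sra, pfix)
    expect_gte(d, min(sp)); expect_lte(d, max(sp))
  }
  # zero in-zone length -> undefined
  far <- inzone_segments(2, 12)
  far$lon1 <- far$lon2 <- -69.2; # outside the SRA
  expect_true(is.na(dwas(far, zfix$sra, pfix)))
})

test_that("DWAS counts only the in-zone share of boundary-crossing segments", {
  # one segment half inside the western SRA edge, one fully inside
  west <- zfix$sra[1, 1]
  lat <- sra_center[2]
  deg_nm <- 1 / (60.04054 * cos(lat * pi / 180))
  seg <- data.frame(
    lon1 = c(west - 1 * deg_nm, west + 1 * deg_nm),
    lat1 = lat, lon2 = c(west + 1 * deg_nm, west + 3 * deg_nm), lat2 = lat,
    t1 = as.POSIXct("2015-07-01", tz = "UTC") + c(0, 600),
    t2 = as.POSIXct("2015-07-01", tz = "UTC") + c(600, 1200),
    length_nm = 2, duration_s = 600, speed = c(14, 10), speed_ltd = c(14, 10))
  # in-zone: 1 nm @ 14 + 2 nm @ 10 -> 34/3
  expect_equal(dwas(seg, zfix$sra, pfix), 34 / 3, tolerance = 1e-3)
})

test_that("strict compliance is all-or-nothing with an inclusive boundary", {
  t0 <- as.POSIXct("2015-07-01", tz = "UTC")
  mkfix <- function(stw, tid) data.frame(
    transit_id = tid, lon = sra_center[1], lat = sra_center[2],
    t = t0 + seq_along(stw), stw = stw)
  ok <- strict_compliance(mkfix(c(9.8, 9.9, 10.0), "A"), zfix$sra, pfix)
  expect_equal(ok$pct, 100)
  # one fix over the limit condemns the whole transit
  mixed <- strict_compliance(rbind(mkfix(c(9.8, 9.9, 10.0), "A"),
                                   mkfix(c(9.8, 10.1, 9.9), "B")),
                             zfix$sra, pfix)
  expect_equal(mixed$pct, 50)
  expect_false(mixed$by_transit[["B"]])
  # no transits in zone -> absent, not zero
  outside <- mkfix(c(9, 9), "C"); outside$lon <- -69.2
  none <- strict_compliance(outside, zfix$sra, pfix)
  expect_true(is.na(none$pct))
  expect_equal(none$n, 0L)
})

test_that("slow-down effort compares the 3-km approach with the zone", {
  lat <- sra_center[2]
  deg_nm <- 1 / (60.04054 * cos(lat * pi / 180))
  east <- zfix$sra[2, 1]  # eastern SRA edge; approach from the east going west
  mkseg <- function(lon_start, n, speed, len = 0.5) {
    lon1 <- lon_start - (seq_len(n) - 1) * len * deg_nm
    data.frame(lon1 = lon1, lat1 = lat, lon2 = lon1 - len * deg_nm, lat2 = lat,
               t1 = as.POSIXct("2015-07-01", tz = "UTC") + (seq_len(n) - 1) * 60,
               t2 = as.POSIXct("2015-07-01", tz = "UTC") + seq_len(n) * 60,
               length_nm = len, duration_s = 60, speed = speed, speed_ltd = speed)
  }
  approach <- mkseg(east + 4 * 0.5 * deg_nm, 4, 13)   # 2 nm outside at 13 kn
  inzone <- mkseg(east, 8, 10)                        # 4 nm inside at 10 kn
  seg <- rbind(approach, inzone)
  seg$t1 <- seg$t1[1] + (seq_len(nrow(seg)) - 1) * 60
  seg$t2 <- seg$t1 + 60
  expect_equal(slowdown_effort(seg, zfix$sra, pfix), 3, tolerance = 1e-4)
  # constant speed -> no effort
  seg2 <- rbind(mkseg(east + 2 * deg_nm, 4, 12), mkseg(east, 6, 12))
  expect_equal(slowdown_effort(seg2, zfix$sra, pfix), 0, tolerance = 1e-9)
  # transit starting inside the zone has no approach -> absent
  expect_true(is.na(slowdown_effort(mkseg(east, 6, 12), zfix$sra, pfix)))
})

test_that("non-compliance profile matches closed-form fixtures", {
  prof <- noncompliance_profile(inzone_segments(c(2, 3, 1), c(9, 12, 13)),
                                zfix$sra, pfix)
  expect_equal(prof$I6, 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(prof$I7, (3 * 12 + 1 * 13) / 4)
  all_slow <- noncompliance_profile(inzone_segments(c(2, 2), c(9, 10)),
                                    zfix$sra, pfix)
  expect_equal(all_slow$I6, 0)
  expect_true(is.na(all_slow$I7))
  all_fast <- inzone_segments(c(1, 2), c(12, 15))
  prof_fast <- noncompliance_profile(all_fast, zfix$sra, pfix)
  expect_equal(prof_fast$I6, 100)
  expect_equal(prof_fast$I7, dwas(all_fast, zfix$sra, pfix))
  # constant in-zone speed pins I6 to exactly 0 or 100
  expect_equal(noncompliance_profile(inzone_segments(c(1, 1), c(11, 11)),
                                     zfix$sra, pfix)$I6, 100)
})

test_that("indicator I7 exceeds the limit whenever I6 is positive", {
  set.seed(11)
  for (i in 1:30) {
    seg <- inzone_segments(stats::runif(6, 0.2, 2), stats::runif(6, 7, 16))
    prof <- noncompliance_profile(seg, zfix$sra, pfix)
    if (!is.na(prof$I7)) expect_gt(prof$I7, 10)
    expect_gte(prof$I6, 0); expect_lte(prof$I6, 100)
  }
})

test_that("time-based sampling understates speed; distance weighting fixes it", {
  # half the distance at 14 kn, half at 10 kn
  v_of_s <- function(s) ifelse(s < 5, 14, 10)
  fx <- sample_trajectory(v_of_s, 10, step_s = 10)
  seg <- segmentize(fx)
  naive <- mean(fx$stw)
  d <- sum(seg$length_nm * seg$speed) / sum(seg$length_nm)
  expect_equal(d, 12, tolerance = 0.02)
  expect_equal(naive, 35 / 3, tolerance = 0.02)  # time-weighted 11.67
  expect_lt(naive, d)
})

test_that("DWAS is invariant to the AIS fix rate", {
  v_of_s <- function(s) 14 - 0.4 * s  # smooth deceleration 14 -> 10 kn
  fine <- segmentize(sample_trajectory(v_of_s, 10, step_s = 10))
  coarse <- segmentize(sample_trajectory(v_of_s, 10, step_s = 120))
  d_fine <- sum(fine$length_nm * fine$speed) / sum(fine$length_nm)
  d_coarse <- sum(coarse$length_nm * coarse$speed) / sum(coarse$length_nm)
  expect_lt(abs(d_fine - d_coarse), 0.05)
  # continuous-trajectory oracle: total distance / total time
  ltd <- sum(fine$length_nm) / (sum(fine$duration_s) / 3600)
  expect_equal(d_fine, ltd, tolerance = 0.02)
})

test_that("no-go-area usage separates partial from complete users", {
  t0 <- as.POSIXct("2015-07-01", tz = "UTC")
  mkpath <- function(lons, lats, id) {
    fx <- data.frame(vessel_id = id, t = t0 + seq_along(lons) * 60,
                     lon = lons, lat = lats, sog = 12, cog = 90, stw = 12)
    segmentize(fx)
  }
  paths <- list(
    none = mkpath(seq(-69.9, -69.1, length.out = 20), rep(48.15, 20), "none"),
    complete = mkpath(seq(-69.80, -69.40, length.out = 20), rep(48.40, 20), "complete"),
    corner = mkpath(c(-69.70, -69.62, -69.55), c(48.26, 48.32, 48.26), "corner"))
  use <- nga_usage(paths, zfix)
  expect_equal(use$partial, c(FALSE, TRUE, TRUE))
  expect_equal(use$complete, c(FALSE, TRUE, FALSE))
})

test_that("island-route classification uses the reference gates", {
  t0 <- as.POSIXct("2015-07-01", tz = "UTC")
  mkpath <- function(lat_end, id) {
    lons <- seq(-69.60, -69.20, length.out = 15)
    lats <- seq(48.30, lat_end, length.out = 15)
    segmentize(data.frame(vessel_id = id, t = t0 + seq_along(lons) * 60,
                          lon = lons, lat = lats, sog = 12, cog = 90, stw = 12))
  }
  res <- rr_compliance(list(a = mkpath(48.45, "a"), b = mkpath(48.45, "b"),
                            c = mkpath(48.15, "c")), zfix)
  expect_equal(res$pct_north, 100 * 2 / 3)
  expect_equal(res$n, 3L)
  # a path stopping short of the gates is unclassifiable and excluded
  short <- segmentize(data.frame(
    vessel_id = "s", t = t0 + 1:5 * 60, lon = seq(-69.9, -69.8, length.out = 5),
    lat = 48.3, sog = 12, cog = 90, stw = 12))
  res2 <- rr_compliance(list(a = mkpath(48.45, "a"), s = short), zfix)
  expect_equal(res2$n, 1L)
  expect_match(res2$log, "excluded")
})

test_that("portfolio recovers the planted per-transit truth", {
  s <- small_scenario()
  port <- build_portfolio(s$bt$transits, s$bt$fixes, s$scn$zones,
                          s$scn$calendar)
  expect_s3_class(port, "compliance_portfolio")
  # one row per (year, status)
  expect_equal(nrow(as.data.frame(port)), 6)
  expect_true(all(port$n_vessels <= port$n_transits))
  per <- attr(port, "per_transit")
  mt <- match_truth(s$bt$transits, s$scn$truth)
  truth <- s$scn$truth[mt, ]
  idx <- match(s$bt$transits$transit_id, per$transit_id)
  # DWAS within a few hundredths of a knot of the planted value
  expect_lt(max(abs(per$I5[idx] - truth$dwas_true), na.rm = TRUE), 0.05)
  # strict-compliance classification identical to the planted flag
  expect_equal(per$strict[idx], truth$strict_true)
  # aggregate counts match the generation plan
  plan <- s$cfg$n_transits
  for (r in seq_len(nrow(plan))) {
    got <- as.data.frame(port)
    row <- got[got$year == plan$year[r] & got$status == plan$status[r], ]
    expect_equal(row$n_transits, plan$n[r])
  }
})

test_that("portfolio handles an all-compliant and an empty period", {
  cfg <- scenario_config(seed = 13, p_strict = 1,
                         n_transits = data.frame(year = 2015, status = "active",
                                                 n = 6))
  scn <- gen_transits(cfg)
  fx <- add_stw(clean_fixes(scn$fixes, scn$zones$study_area)$fixes,
                synthetic_current_function(cfg))
  bt <- build_transits(fx, scn$vessels, scn$pilots, scn$zones, scn$calendar)
  port <- build_portfolio(bt$transits, bt$fixes, scn$zones, scn$calendar)
  df <- as.data.frame(port)
  act <- df[df$status == "active", ]
  expect_equal(act$I1, 100)
  expect_equal(act$I6, 0)
  # the inactive row exists with zero transits and absent indicators
  inact <- df[df$status == "inactive", ]
  expect_equal(inact$n_transits, 0)
  expect_true(is.na(inact$I1))
})
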