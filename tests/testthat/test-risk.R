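lmod <- calibrate_lethality()

test_that("the two-anchor logistic calibration matches logit algebra", {
  logit <- function(p) log(p / (1 - p))
  b1 <- (logit(0.5) - logit(0.31)) / (11.8 - 10)
  expect_equal(lmod$beta1, b1, tolerance = 1e-12)
  expect_equal(lmod$beta0, logit(0.31) - b1 * 10, tolerance = 1e-12)
  # anchors reproduced exactly
  expect_equal(lethality_probability(lmod, 10), 0.31, tolerance = 1e-12)
  expect_equal(lethality_probability(lmod, 11.8), 0.50, tolerance = 1e-12)
  # near-symmetric anchors put the midpoint at the crossing speed
  m2 <- calibrate_lethality(0, 0.5 - 1e-9, 1, 0.5 + 1e-9)
  expect_equal(stats::plogis(m2$beta0), 0.5, tolerance = 1e-6)
  expect_error(calibrate_lethality(10, 0.31, 10, 0.5), "differ")
  expect_error(calibrate_lethality(10, 0.31, 11.8, 0.31), "differ")
  expect_error(calibrate_lethality(10, 0.5, 11.8, 0.31), "increase")
})

test_that("lethality probability is monotone and spans the printed points", {
  v <- seq(0, 25, by = 0.1)
  p <- lethality_probability(lmod, v)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  expect_equal(lethality_probability(lmod, 14.1), 0.7354, tolerance = 1e-4)
  expect_equal(predict(lmod, 11.8), 0.5, tolerance = 1e-12)
})

straight_transit <- function(speed_kn, total_nm = 10, lat = 48.30, id = "T") {
  v_of_s <- function(s) speed_kn
  fx <- sample_trajectory(v_of_s, total_nm, lat = lat, step_s = 60)
  fx$vessel_id <- id
  segmentize(fx)
}

risk_grid <- function(cell = 2000) {
  sa <- slowzone:::project_poly(zfix$study_area, pfix)
  grid_spec(min(sa[, 1]), min(sa[, 2]), cell,
            ceiling(diff(range(sa[, 2])) / cell),
            ceiling(diff(range(sa[, 1])) / cell), pfix)
}

test_that("traffic surface conserves distance and weights it by lethality", {
  g <- risk_grid()
  seg <- straight_transit(14.1)
  ts <- traffic_surface(list(T1 = seg), g, lmod)
  expect_equal(sum(ts$distance_nm), sum(seg$length_nm), tolerance = 1e-6)
  expect_equal(sum(ts$weighted_nm),
               sum(seg$length_nm) * lethality_probability(lmod, 14.1),
               tolerance = 1e-4)
  ts10 <- traffic_surface(list(T1 = straight_transit(10)), g, lmod)
  expect_equal(sum(ts10$weighted_nm), sum(ts10$distance_nm) * 0.31,
               tolerance = 1e-6)
  empty <- traffic_surface(list(), g, lmod)
  expect_equal(sum(empty$distance_nm), 0)
  expect_equal(sum(empty$weighted_nm), 0)
})

test_that("distance conservation holds for the full synthetic scenario", {
  s <- small_scenario()
  g <- risk_grid(4000)
  ts <- traffic_surface(s$seg, g, lmod)
  inlens <- sum(vapply(s$seg, function(x) sum(x$length_nm), numeric(1)))
  skipped <- sum(as.numeric(sub(".*: ([0-9.]+)%.*", "\\1", ts$log))) / 100
  expect_equal(sum(ts$distance_nm), inlens, tolerance = 2e-3 + skipped)
})

test_that("risk maps multiply density by weighted traffic, with guards", {
  g <- risk_grid()
  ts <- traffic_surface(list(T1 = straight_transit(12)), g, lmod)
  uni <- whale_density(matrix(1, g$nrows, g$ncols), g, "uniform")
  r1 <- risk_map(ts, uni, normalize_per_transit = FALSE)
  expect_equal(sum(r1), sum(ts$weighted_nm) / (g$nrows * g$ncols),
               tolerance = 1e-9)
  # doubling density before normalisation changes nothing (relative density)
  dbl <- whale_density(matrix(2, g$nrows, g$ncols), g, "uniform")
  expect_equal(sum(risk_map(ts, dbl, FALSE)), sum(r1), tolerance = 1e-12)
  # hotspot cell with 3x relative density and equal traffic carries 3x the
  # risk of an equal-traffic reference cell of the same surface
  trafficked <- which(ts$distance_nm > 0, arr.ind = TRUE)
  hot_rc <- trafficked[1, ]; ref_rc <- trafficked[2, ]
  vals <- matrix(1, g$nrows, g$ncols); vals[hot_rc[1], hot_rc[2]] <- 3
  hot <- whale_density(vals, g, "hot")
  rh <- risk_map(ts, hot, FALSE)
  traffic_ratio <- ts$weighted_nm[hot_rc[1], hot_rc[2]] /
    ts$weighted_nm[ref_rc[1], ref_rc[2]]
  expect_equal(rh[hot_rc[1], hot_rc[2]] / rh[ref_rc[1], ref_rc[2]],
               3 * traffic_ratio, tolerance = 1e-9)
  g2 <- risk_grid(3000)
  expect_error(risk_map(ts, whale_density(matrix(1, g2$nrows, g2$ncols), g2)),
               "match")
})

test_that("effectiveness follows the closed form for single-speed fleets", {
  g <- risk_grid()
  uni <- whale_density(matrix(1, g$nrows, g$ncols), g, "uniform")
  ts_fast <- traffic_surface(list(T1 = straight_transit(14.1)), g, lmod)
  ts_slow <- traffic_surface(list(T1 = straight_transit(10)), g, lmod)
  before <- risk_map(ts_fast, uni); after <- risk_map(ts_slow, uni)
  red <- effectiveness(before, after)
  expect_equal(red, 100 * (1 - 0.31 / lethality_probability(lmod, 14.1)),
               tolerance = 1e-6)
  # identical maps -> 0; halved maps -> 50
  expect_equal(effectiveness(before, before), 0, tolerance = 1e-12)
  half <- before; half[] <- before / 2
  expect_equal(effectiveness(before, half), 50, tolerance = 1e-12)
  # invariant to global density rescaling
  uni2 <- whale_density(matrix(7, g$nrows, g$ncols), g, "uniform")
  red2 <- effectiveness(risk_map(ts_fast, uni2), risk_map(ts_slow, uni2))
  expect_equal(red2, red, tolerance = 1e-9)
  # restricting to a region with zero baseline is an error
  zero <- before; zero[] <- 0
  expect_error(effectiveness(zero, after), "baseline")
})

test_that("slowing every transit never decreases effectiveness", {
  g <- risk_grid()
  uni <- whale_density(matrix(1, g$nrows, g$ncols), g, "uniform")
  before <- risk_map(traffic_surface(list(T1 = straight_transit(14)), g, lmod), uni)
  speeds <- c(13, 12, 11, 10)
  reds <- vapply(speeds, function(v) {
    after <- risk_map(traffic_surface(list(T1 = straight_transit(v)), g, lmod), uni)
    effectiveness(before, after)
  }, numeric(1))
  expect_true(all(diff(reds) > 0))
})

test_that("gate-to-gate transit times interpolate the crossing instants", {
  t0 <- as.POSIXct("2016-07-01 00:00:00", tz = "UTC")
  cross <- make_crossing("VT", t0, speed_kn = 12, step_s = 360)
  cal <- default_calendar()
  bt <- build_transits(cross, NULL, NULL, zfix, cal)
  seg <- slowzone:::split_segments(bt$fixes, bt$transits$transit_id)
  tt <- transit_time_stats(seg, bt$transits, zfix)
  gate_nm <- geodesic_nm(-70.10, 48.30, -69.10, 48.30)
  expect_equal(tt$per_transit$minutes, gate_nm / 12 * 60, tolerance = 0.2)
  # slowing from 12 to 10 kn over a 5.4-nm stretch adds 5.4*60*(1/10-1/12) min
  deg_nm <- 1 / (60.04054 * cos(48.30 * pi / 180))
  slow_from <- -69.92
  v_of_lon <- function(lon) ifelse(lon > slow_from & lon < slow_from + 5.4 * deg_nm, 10, 12)
  fx <- cross
  # rebuild times from the piecewise speed profile
  lon <- fx$lon
  dt <- numeric(length(lon)); dt[1] <- 0
  for (i in 2:length(lon)) {
    d <- geodesic_nm(lon[i - 1], 48.30, lon[i], 48.30)
    v <- v_of_lon((lon[i - 1] + lon[i]) / 2)
    dt[i] <- dt[i - 1] + d / v * 3600
  }
  fx$t <- t0 + dt
  fx$sog <- fx$stw <- v_of_lon(lon)
  bt2 <- build_transits(fx, NULL, NULL, zfix, cal)
  seg2 <- slowzone:::split_segments(bt2$fixes, bt2$transits$transit_id)
  tt2 <- transit_time_stats(seg2, bt2$transits, zfix)
  expect_equal(tt2$per_transit$minutes - tt$per_transit$minutes,
               5.4 * 60 * (1 / 10 - 1 / 12), tolerance = 0.3)
  # a transit that never reaches the second gate is excluded and logged
  half <- cross[cross$lon < -69.5, ]
  bt3 <- build_transits(half, NULL, NULL, zfix, cal)
  if (nrow(bt3$transits)) {
    seg3 <- slowzone:::split_segments(bt3$fixes, bt3$transits$transit_id)
    tt3 <- transit_time_stats(seg3, bt3$transits, zfix)
    expect_null(tt3$per_transit)
    expect_match(tt3$log, "excluded")
  }
})

test_that("density surfaces read and write as CSV", {
  g <- risk_grid(4000)
  d <- gen_whale_density(scenario_config(), "fin", g)
  path <- tempfile(fileext = ".csv")
  write_density_csv(d, path)
  d2 <- read_density_csv(path)
  expect_equal(d2$values, d$values, tolerance = 1e-12)
  expect_equal(d2$species, "fin")
})
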