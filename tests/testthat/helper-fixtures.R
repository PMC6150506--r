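# Shared fixtures: all built in code, nothing read from disk.

unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

# Zone set and projection reused across compliance/risk tests.
zfix <- synthetic_zones()
pfix <- zfix$projection

# Centre of the slow-down area (lon/lat), handy anchor for in-zone fixtures.
sra_center <- c(mean(range(zfix$sra[, 1])), mean(range(zfix$sra[, 2])))

# Segment table wholly inside the SRA with prescribed lengths (nm) and speeds
# (kn). Geometry is collapsed to the zone centre: clipping sees fraction 1,
# and the stated lengths drive all distance-weighted statistics.
inzone_segments <- function(lengths_nm, speeds_kn) {
  n <- length(lengths_nm)
  t0 <- as.POSIXct("2015-07-01 12:00:00", tz = "UTC")
  data.frame(lon1 = sra_center[1], lat1 = sra_center[2],
             lon2 = sra_center[1], lat2 = sra_center[2],
             t1 = t0 + (seq_len(n) - 1) * 60, t2 = t0 + seq_len(n) * 60,
             length_nm = lengths_nm, duration_s = 60,
             speed = speeds_kn, speed_ltd = speeds_kn)
}

# Straight east-west crossing of the study area at constant speed (kn),
# fixes every `step_s` seconds, at a chosen latitude. Returns a fix table
# compatible with clean_fixes / build_transits (stw = sog; zero current).
make_crossing <- function(vessel_id, t0, speed_kn = 12, lat = 48.30,
                          lon_from = -70.15, lon_to = -69.05, step_s = 120) {
  dist_nm <- geodesic_nm(lon_from, lat, lon_to, lat)
  dur_s <- dist_nm / speed_kn * 3600
  tt <- seq(0, dur_s, by = step_s)
  lon <- lon_from + (lon_to - lon_from) * tt / dur_s
  data.frame(vessel_id = vessel_id, t = t0 + tt, lon = lon, lat = lat,
             sog = speed_kn, cog = if (lon_to > lon_from) 90 else 270,
             stw = speed_kn, stringsAsFactors = FALSE)
}

# Continuous 1-D trajectory with speed profile v(s) in kn along a parallel,
# sampled every `step_s` seconds; used for DWAS resampling/bias checks.
sample_trajectory <- function(v_of_s, total_nm, lat = 48.30, lon_from = -69.90,
                              step_s = 10, t0 = as.POSIXct("2015-07-01", tz = "UTC")) {
  deg_per_nm <- 1 / (60.04054 * cos(lat * pi / 180))
  s <- 0; t <- 0
  ss <- 0; tt <- 0; vv <- v_of_s(0)
  while (s < total_nm - 1e-9) {
    v <- v_of_s(s)
    step <- min(step_s, (total_nm - s) / v * 3600)  # land exactly on total_nm
    if (step < 1e-6) break
    s <- s + v * step / 3600
    t <- t + step
    ss <- c(ss, s); tt <- c(tt, t); vv <- c(vv, v_of_s(s))
  }
  data.frame(vessel_id = "VTRAJ", t = t0 + tt, lon = lon_from + ss * deg_per_nm,
             lat = lat, sog = vv, cog = 90, stw = vv, stringsAsFactors = FALSE)
}

# Random convex polygon (planar) around the origin.
random_convex_poly <- function(n = 6, radius = 1) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.5, 1) * radius
  cbind(r * cos(ang), r * sin(ang))
}

# Small scenario used by several test files (generated once per test run).
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config(seed = 42, n_transits = do.call(rbind, lapply(
        2013:2015, function(y) rbind(
          data.frame(year = y, status = "active", n = 8),
          data.frame(year = y, status = "inactive", n = 4)))))
      scn <- gen_transits(cfg)
      cl <- clean_fixes(scn$fixes, scn$zones$study_area)
      fx <- add_stw(cl$fixes, synthetic_current_function(cfg))
      bt <- build_transits(fx, scn$vessels, scn$pilots, scn$zones, scn$calendar)
      cache <<- list(cfg = cfg, scn = scn, fixes = fx, bt = bt,
                     seg = slowzone:::split_segments(bt$fixes, bt$transits$transit_id))
    }
    cache
  }
})
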