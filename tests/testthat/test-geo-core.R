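test_that("geodesic distance matches independent spherical oracles", {
  expect_identical(geodesic_nm(-69.5, 48.2, -69.5, 48.2), 0)
  # one degree of meridian arc: (pi/180) * R / 1852
  expect_equal(geodesic_nm(0, 0, 0, 1), (pi / 180) * 6371008.8 / 1852,
               tolerance = 1e-9)
  # spherical law of cosines oracle, independent of the haversine path
  slc <- function(lon1, lat1, lon2, lat2) {
    r <- pi / 180
    c_ang <- acos(sin(lat1 * r) * sin(lat2 * r) +
                    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r))
    c_ang * 6371008.8 / 1852
  }
  expect_equal(geodesic_nm(-69, 48, -68, 48), slc(-69, 48, -68, 48),
               tolerance = 1e-9)
  expect_equal(geodesic_nm(-69, 48, -68, 48), 40.1747, tolerance = 1e-4)
  set.seed(1)
  for (i in 1:50) {
    p <- matrix(c(stats::runif(3, -75, -65), stats::runif(3, 45, 50)), ncol = 2)
    d12 <- geodesic_nm(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d23 <- geodesic_nm(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    d13 <- geodesic_nm(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(d13, d12 + d23 + 1e-9)
    expect_equal(d12, slc(p[1, 1], p[1, 2], p[2, 1], p[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("local projection round-trips and preserves local distances", {
  proj <- local_projection(-69.6, 48.3)
  set.seed(2)
  lon <- stats::runif(200, -70.2, -69.0); lat <- stats::runif(200, 48.05, 48.55)
  xy <- proj$forward(lon, lat)
  ll <- proj$inverse(xy[, 1], xy[, 2])
  expect_equal(unname(ll[, 1]), lon, tolerance = 1e-9)
  expect_equal(unname(ll[, 2]), lat, tolerance = 1e-9)
  # planar distance approximates geodesic distance at study-area scale
  d_geo <- geodesic_nm(lon[1:100], lat[1:100], lon[101:200], lat[101:200]) * 1852
  d_pla <- sqrt((xy[1:100, 1] - xy[101:200, 1])^2 +
                  (xy[1:100, 2] - xy[101:200, 2])^2)
  expect_equal(d_pla, d_geo, tolerance = 1e-4)
})

test_that("segment clipping handles inside, outside and crossing cases", {
  whole_in <- clip_segment_to_polygon(c(0.2, 0.5), c(0.8, 0.5), unit_square)
  expect_equal(nrow(whole_in), 1)
  expect_true(whole_in$inside)
  expect_equal(whole_in$fraction, 1)
  whole_out <- clip_segment_to_polygon(c(-1, 0.5), c(-0.2, 0.5), unit_square)
  expect_false(whole_out$inside)
  expect_equal(whole_out$fraction, 1)
  cross <- clip_segment_to_polygon(c(-0.5, 0.5), c(0.5, 0.5), unit_square)
  expect_equal(cross$fraction, c(0.5, 0.5))
  expect_equal(cross$inside, c(FALSE, TRUE))
  expect_error(clip_segment_to_polygon(c(0, 0), c(0, 0), unit_square),
               "length")
  expect_error(clip_segment_to_polygon(c(0, 0), c(1, 1), unit_square[1:2, ]),
               "degenerate")
})

test_that("clipped fractions sum to one and agree with the convex fast path", {
  set.seed(3)
  for (i in 1:200) {
    poly <- random_convex_poly(sample(3:8, 1))
    a <- stats::runif(2, -2, 2); b <- stats::runif(2, -2, 2)
    if (sum((a - b)^2) == 0) next
    cl <- clip_segment_to_polygon(a, b, poly)
    expect_equal(sum(cl$fraction), 1, tolerance = 1e-6)
    # dual route: exact clip vs Cyrus-Beck interval
    fast <- slowzone:::inzone_fractions(a[1], a[2], b[1], b[2], poly)
    expect_equal(sum(cl$fraction[cl$inside]), fast, tolerance = 1e-9)
  }
})

test_that("point-in-polygon counts boundary as inside and matches winding", {
  expect_true(point_in_polygon(0.5, 0.5, unit_square))
  expect_true(point_in_polygon(0, 0.5, unit_square))   # on edge
  expect_false(point_in_polygon(1.5, 0.5, unit_square))
  # concave polygon: the notched upper-left square is excluded
  notch <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 2, 2, 1, 1))
  expect_true(point_in_polygon(0.5, 0.5, notch))
  expect_true(point_in_polygon(1.5, 1.5, notch))
  expect_false(point_in_polygon(0.5, 1.5, notch))
})

test_that("measure calendar reproduces the deployment history", {
  cal <- default_calendar()
  expect_true(is_measure_active(as.POSIXct("2014-07-15", tz = "UTC"), "SRA", cal))
  expect_false(is_measure_active(as.POSIXct("2015-12-01", tz = "UTC"), "SRA", cal))
  # first season started in June; mid-May of that year is inactive
  expect_false(is_measure_active(as.POSIXct("2013-05-15", tz = "UTC"), "SRA", cal))
  expect_true(is_measure_active(as.POSIXct("2013-06-15", tz = "UTC"), "SRA", cal))
  # the route recommendation never predates its introduction
  expect_false(is_measure_active(as.POSIXct("2013-07-15", tz = "UTC"), "RR", cal))
  expect_true(is_measure_active(as.POSIXct("2014-07-15", tz = "UTC"), "RR", cal))
  expect_error(measure_calendar(data.frame(
    year = 2013, start_date = "2013-06-01", end_date = "2013-10-31",
    measures = "SRA;RR")), "RR")
  expect_error(measure_calendar(data.frame(
    year = c(2014, 2014), start_date = c("2014-05-01", "2014-08-01"),
    end_date = c("2014-09-30", "2014-10-31"), measures = "SRA")), "overlap")
  # every timestamp gets a definite answer
  tt <- as.POSIXct("2012-01-01", tz = "UTC") + seq(0, 5 * 365, by = 17) * 86400
  act <- is_measure_active(tt, "SRA", cal)
  expect_type(act, "logical")
  expect_false(anyNA(act))
})

test_that("calendar CSV and zone GeoJSON round-trip", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(year = 2014, start_date = "2014-05-01",
                   end_date = "2014-10-31", measures = "SRA;NGA;RR")
  utils::write.csv(df, path, row.names = FALSE)
  cal <- read_calendar(path)
  expect_true(is_measure_active(as.POSIXct("2014-06-01", tz = "UTC"), "NGA", cal))
  zpath <- tempfile(fileext = ".geojson")
  write_zones(zfix, zpath)
  z2 <- read_zones(zpath)
  expect_equal(z2$sra[, 1], zfix$sra[, 1] , tolerance = 1e-9)
  expect_equal(z2$rr_gate_n, zfix$rr_gate_n, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("grid cell indexing round-trips exactly", {
  proj <- local_projection(-69.6, 48.3)
  g <- grid_spec(-5000, -3000, 250, 40, 60, proj)
  idx <- expand.grid(row = c(1L, 7L, 40L), col = c(1L, 33L, 60L))
  ctr <- slowzone:::cell_center(idx$row, idx$col, g)
  rc <- slowzone:::cell_of(ctr[, 1], ctr[, 2], g)
  expect_equal(rc[, "row"], idx$row, ignore_attr = TRUE)
  expect_equal(rc[, "col"], idx$col, ignore_attr = TRUE)
  expect_true(all(is.na(slowzone:::cell_of(-6000, 0, g))))
})
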