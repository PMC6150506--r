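# Geometry, geodesy, grid and calendar primitives shared by all pipeline stages.
#
# All geographic I/O is in longitude/latitude (degrees); planar work (polygon
# clipping, gridding) happens in a local azimuthal equal-area projection, in
# metres. Distances are great-circle on a sphere of radius 6371.0088 km and
# are reported in nautical miles (1 nm = 1852 m).

EARTH_RADIUS_M <- 6371008.8
M_PER_NM <- 1852
MS_PER_KN <- 0.514444

#' Great-circle distance in nautical miles
#'
#' Haversine distance on a spherical Earth (radius 6371.0088 km). Vectorised
#' over coordinates.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in nautical miles.
#' @export
geodesic_nm <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90), all(abs(lat2) <= 90))
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M) / M_PER_NM
}

#' Local azimuthal equal-area projection
#'
#' Builds a Lambert azimuthal equal-area projection (spherical form) centred
#' on `lon0, lat0`. Returned object carries `forward(lon, lat)` and
#' `inverse(x, y)` closures working in metres. Used for all planar geometry;
#' lon/lat are kept for I/O only.
#'
#' @param lon0,lat0 Projection centre in degrees.
#' @return An object of class `local_projection`.
#' @export
local_projection <- function(lon0, lat0) {
  rad <- pi / 180
  l0 <- lon0 * rad
  phi0 <- lat0 * rad
  R <- EARTH_RADIUS_M
  forward <- function(lon, lat) {
    lam <- lon * rad
    phi <- lat * rad
    dl <- lam - l0
    denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
    k <- sqrt(2 / pmax(denom, 1e-12))
    cbind(x = R * k * cos(phi) * sin(dl),
          y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl)))
  }
  inverse <- function(x, y) {
    rho <- sqrt(x^2 + y^2)
    c_ang <- 2 * asin(pmin(1, rho / (2 * R)))
    phi <- ifelse(rho < 1e-9, phi0,
                  asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / pmax(rho, 1e-12)))
    lam <- l0 + atan2(x * sin(c_ang),
                      rho * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang))
    cbind(lon = ifelse(rho < 1e-9, lon0, lam / rad), lat = phi / rad)
  }
  structure(list(lon0 = lon0, lat0 = lat0, forward = forward, inverse = inverse),
            class = "local_projection")
}

#' Regular analysis grid
#'
#' A planar grid in projected coordinates. Cells are indexed `(row, col)`
#' starting at 1 in the lower-left corner; `origin` is the lower-left corner
#' of cell (1,1).
#'
#' @param origin_x,origin_y Lower-left corner, metres (projected).
#' @param cell_size Cell edge, metres (> 0).
#' @param nrows,ncols Grid dimensions.
#' @param projection A [local_projection()] tying the grid to the globe.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, nrows, ncols, projection) {
  stopifnot(cell_size > 0, nrows >= 1, ncols >= 1,
            inherits(projection, "local_projection"))
  structure(list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
                 nrows = nrows, ncols = ncols, projection = projection),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.0f m, origin (%.0f, %.0f)\n",
              x$nrows, x$ncols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

# Cell containing projected point; NA outside the grid.
cell_of <- function(x, y, grid) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1L
  bad <- col < 1L | col > grid$ncols | row < 1L | row > grid$nrows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

# Centre of cell (row, col) in projected metres.
cell_center <- function(row, col, grid) {
  cbind(x = grid$origin_x + (col - 0.5) * grid$cell_size,
        y = grid$origin_y + (row - 0.5) * grid$cell_size)
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param x,y Point coordinates (vectorised), same planar system as `poly`.
#' @param poly Two-column matrix of polygon vertices (closed or open ring).
#' @return Logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- close_ring(poly)
  px <- poly[, 1]; py <- poly[, 2]
  m <- length(px) - 1L
  n <- length(x)
  inside <- logical(n); on_edge <- logical(n)
  for (j in seq_len(m)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- px[j + 1L]; y2 <- py[j + 1L]
    # boundary tolerance: a point on the segment counts as inside
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    tolj <- 1e-6 * max(1, abs(x2 - x1), abs(y2 - y1))
    on_edge <- on_edge | (abs(cross) < tolj &
                            x >= min(x1, x2) - 1e-9 & x <= max(x1, x2) + 1e-9 &
                            y >= min(y1, y2) - 1e-9 & y <= max(y1, y2) + 1e-9)
    crosses <- (y1 > y) != (y2 > y)
    if (any(crosses)) {
      xint <- x1 + (y[crosses] - y1) / (y2 - y1) * (x2 - x1)
      inside[crosses] <- xor(inside[crosses], x[crosses] < xint)
    }
  }
  inside | on_edge
}

# Convex-polygon edge set with inward normals, or NULL when not convex.
convex_info <- function(poly) {
  poly <- close_ring(poly)
  v <- diff(poly)
  cr <- v[, 1] * c(v[-1, 2], v[1, 2]) - v[, 2] * c(v[-1, 1], v[1, 1])
  if (all(cr >= -1e-9)) ccw <- TRUE
  else if (all(cr <= 1e-9)) ccw <- FALSE
  else return(NULL)
  list(px = poly[-nrow(poly), 1], py = poly[-nrow(poly), 2],
       nx = if (ccw) -v[, 2] else v[, 2],
       ny = if (ccw) v[, 1] else -v[, 1])
}

# Inside-length fraction of segments (x1,y1)-(x2,y2) w.r.t. a polygon,
# vectorised over segments. Convex polygons use a Cyrus-Beck interval
# intersection; general polygons fall back to the exact per-segment clip.
inzone_fractions <- function(x1, y1, x2, y2, poly) {
  n <- length(x1)
  if (n == 0) return(numeric(0))
  ci <- convex_info(poly)
  if (!is.null(ci)) {
    t0 <- rep(0, n); t1 <- rep(1, n)
    dx <- x2 - x1; dy <- y2 - y1
    for (j in seq_along(ci$nx)) {
      a <- ci$nx[j] * (x1 - ci$px[j]) + ci$ny[j] * (y1 - ci$py[j])
      b <- ci$nx[j] * dx + ci$ny[j] * dy
      par <- abs(b) < 1e-12
      tc <- ifelse(par, 0, -a / ifelse(par, 1, b))
      ent <- !par & b > 0
      ext <- !par & b < 0
      t0[ent] <- pmax(t0[ent], tc[ent])
      t1[ext] <- pmin(t1[ext], tc[ext])
      t1[par & a < 0] <- -1
    }
    return(pmax(0, t1 - t0))
  }
  vapply(seq_len(n), function(i) {
    cl <- clip_segment_to_polygon(c(x1[i], y1[i]), c(x2[i], y2[i]), poly)
    sum(cl$fraction[cl$inside])
  }, numeric(1))
}

close_ring <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) stop("degenerate polygon: fewer than 3 vertices")
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Clip a planar segment to a polygon
#'
#' Splits the segment `a`--`b` at every polygon-edge crossing and labels each
#' piece inside or outside. Fractions are of total segment length and sum to 1.
#'
#' @param a,b Numeric length-2 vectors, planar coordinates.
#' @param poly Two-column vertex matrix.
#' @return data.frame with `t0`, `t1` (segment parameters), `fraction`, `inside`.
#' @export
clip_segment_to_polygon <- function(a, b, poly) {
  poly <- close_ring(poly)
  if (sum((b - a)^2) == 0) stop("segment length must be > 0")
  ts <- c(0, 1)
  m <- nrow(poly) - 1L
  d <- b - a
  for (j in seq_len(m)) {
    p <- poly[j, ]; q <- poly[j + 1L, ]
    e <- q - p
    denom <- d[1] * e[2] - d[2] * e[1]
    if (abs(denom) < 1e-15) next
    rhs <- p - a
    t <- (rhs[1] * e[2] - rhs[2] * e[1]) / denom
    s <- (rhs[1] * d[2] - rhs[2] * d[1]) / denom
    if (t > 0 && t < 1 && s >= 0 && s <= 1) ts <- c(ts, t)
  }
  ts <- sort(unique(ts))
  mid <- (ts[-length(ts)] + ts[-1]) / 2
  mx <- a[1] + mid * d[1]
  my <- a[2] + mid * d[2]
  inside <- point_in_polygon(mx, my, poly)
  out <- data.frame(t0 = ts[-length(ts)], t1 = ts[-1],
                    fraction = diff(ts), inside = inside)
  # merge adjacent pieces with equal status (crossings at vertices)
  keep <- c(TRUE, diff(as.integer(out$inside)) != 0)
  grp <- cumsum(keep)
  data.frame(t0 = tapply(out$t0, grp, min),
             t1 = tapply(out$t1, grp, max),
             fraction = as.numeric(tapply(out$fraction, grp, sum)),
             inside = as.logical(tapply(out$inside, grp, any)),
             row.names = NULL)
}

# Intersection parameter of segment a-b with segment p-q, or NA.
# Returns t along a-b in [0,1] when the segments properly intersect.
segment_intersection_t <- function(a, b, p, q) {
  d <- b - a; e <- q - p
  denom <- d[1] * e[2] - d[2] * e[1]
  if (abs(denom) < 1e-15) return(NA_real_)
  t <- ((p[1] - a[1]) * e[2] - (p[2] - a[2]) * e[1]) / denom
  s <- ((p[1] - a[1]) * d[2] - (p[2] - a[2]) * d[1]) / denom
  if (t >= 0 && t <= 1 && s >= 0 && s <= 1) t else NA_real_
}

# First crossing of a polyline path (matrix of planar points) with a gate
# (two-point transect). Returns list(seg = index, t = parameter) or NULL.
path_gate_crossing <- function(path, gate) {
  for (i in seq_len(nrow(path) - 1L)) {
    t <- segment_intersection_t(path[i, ], path[i + 1L, ], gate[1, ], gate[2, ])
    if (!is.na(t)) return(list(seg = i, t = t))
  }
  NULL
}

#' Management-zone set
#'
#' Bundles the polygons and transects of the voluntary-measure system: the
#' speed reduction area (SRA), no-go area (NGA), caution area, study area,
#' the two island gates whose crossing classifies a track as north or south
#' of the island, the two transit-time gates, and the pilot station.
#' All geometries are lon/lat; `projection` is the shared planar projection.
#'
#' @param sra,nga,caution,study_area Two-column lon/lat vertex matrices.
#' @param rr_gate_n,rr_gate_s,gate_esc,gate_sts Two-point lon/lat transects.
#' @param nga_chord_up,nga_chord_dn Up/downstream crossing chords of the NGA
#'   (used by the "complete use" classification).
#' @param pilot_station Length-2 lon/lat.
#' @param projection Optional [local_projection()]; defaults to one centred
#'   on the study-area centroid.
#' @return An object of class `zone_set`.
#' @export
zone_set <- function(sra, nga, caution, study_area, rr_gate_n, rr_gate_s,
                     gate_esc, gate_sts, nga_chord_up = NULL, nga_chord_dn = NULL,
                     pilot_station = NULL, projection = NULL) {
  study_area <- close_ring(study_area)
  for (p in list(sra, nga, caution)) close_ring(p)  # validates
  if (is.null(projection)) {
    projection <- local_projection(mean(range(study_area[, 1])),
                                   mean(range(study_area[, 2])))
  }
  z <- structure(list(sra = as.matrix(sra), nga = as.matrix(nga),
                      caution = as.matrix(caution), study_area = study_area,
                      rr_gate_n = as.matrix(rr_gate_n), rr_gate_s = as.matrix(rr_gate_s),
                      gate_esc = as.matrix(gate_esc), gate_sts = as.matrix(gate_sts),
                      nga_chord_up = if (!is.null(nga_chord_up)) as.matrix(nga_chord_up),
                      nga_chord_dn = if (!is.null(nga_chord_dn)) as.matrix(nga_chord_dn),
                      pilot_station = pilot_station, projection = projection),
                 class = "zone_set")
  gn <- project_poly(z$rr_gate_n, projection)
  gs <- project_poly(z$rr_gate_s, projection)
  if (!is.na(segment_intersection_t(gn[1, ], gn[2, ], gs[1, ], gs[2, ])))
    stop("the two island gates must not intersect")
  z
}

project_poly <- function(poly, projection) {
  xy <- projection$forward(poly[, 1], poly[, 2])
  colnames(xy) <- c("x", "y")
  xy
}

#' Read a zone set from GeoJSON
#'
#' Expects a FeatureCollection with one feature per zone, property `zone_id`
#' in `SRA, NGA, CAUTION, STUDY_AREA, RR_GATE_N, RR_GATE_S, GATE_ESC,
#' GATE_STS` and optionally `NGA_CHORD_UP, NGA_CHORD_DN, PILOT_STATION`.
#'
#' @param path GeoJSON file path.
#' @return A [zone_set()].
#' @export
read_zones <- function(path) {
  gj <- jsonlite::read_json(path)
  geoms <- list()
  for (f in gj$features) {
    id <- f$properties$zone_id
    g <- f$geometry
    coords <- if (g$type == "Polygon") g$coordinates[[1]] else g$coordinates
    m <- do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    geoms[[id]] <- m
  }
  zone_set(sra = geoms$SRA, nga = geoms$NGA, caution = geoms$CAUTION,
           study_area = geoms$STUDY_AREA, rr_gate_n = geoms$RR_GATE_N,
           rr_gate_s = geoms$RR_GATE_S, gate_esc = geoms$GATE_ESC,
           gate_sts = geoms$GATE_STS, nga_chord_up = geoms$NGA_CHORD_UP,
           nga_chord_dn = geoms$NGA_CHORD_DN,
           pilot_station = if (!is.null(geoms$PILOT_STATION)) geoms$PILOT_STATION[1, ])
}

#' Write a zone set to GeoJSON
#'
#' @param zones A [zone_set()].
#' @param path Output file path.
#' @export
write_zones <- function(zones, path) {
  feat <- function(id, m, type) {
    coords <- lapply(seq_len(nrow(m)), function(i) list(m[i, 1], m[i, 2]))
    geom <- if (type == "Polygon") list(type = "Polygon", coordinates = list(coords))
            else list(type = "LineString", coordinates = coords)
    list(type = "Feature", properties = list(zone_id = id), geometry = geom)
  }
  feats <- list(
    feat("SRA", zones$sra, "Polygon"), feat("NGA", zones$nga, "Polygon"),
    feat("CAUTION", zones$caution, "Polygon"),
    feat("STUDY_AREA", zones$study_area, "Polygon"),
    feat("RR_GATE_N", zones$rr_gate_n, "LineString"),
    feat("RR_GATE_S", zones$rr_gate_s, "LineString"),
    feat("GATE_ESC", zones$gate_esc, "LineString"),
    feat("GATE_STS", zones$gate_sts, "LineString"))
  if (!is.null(zones$nga_chord_up))
    feats <- c(feats, list(feat("NGA_CHORD_UP", zones$nga_chord_up, "LineString"),
                           feat("NGA_CHORD_DN", zones$nga_chord_dn, "LineString")))
  if (!is.null(zones$pilot_station))
    feats <- c(feats, list(feat("PILOT_STATION", rbind(zones$pilot_station,
                                                       zones$pilot_station), "LineString")))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
}

#' Measure calendar
#'
#' Active windows of the voluntary measures, whole-day granularity. One row
#' per (year, window) with the set of measures in force. The island-route
#' recommendation (`RR`) was added in the second season and is rejected for
#' earlier years.
#'
#' @param entries data.frame with columns `year`, `start_date`, `end_date`
#'   (Date or yyyy-mm-dd strings) and `measures` (semicolon-separated subset
#'   of `SRA;NGA;RR`).
#' @return Object of class `measure_calendar`.
#' @export
measure_calendar <- function(entries) {
  entries$start_date <- as.Date(entries$start_date)
  entries$end_date <- as.Date(entries$end_date)
  stopifnot(all(entries$start_date <= entries$end_date))
  for (yr in unique(entries$year)) {
    e <- entries[entries$year == yr, ]
    if (nrow(e) > 1) {
      e <- e[order(e$start_date), ]
      if (any(e$start_date[-1] <= e$end_date[-nrow(e)]))
        stop("calendar windows overlap within year ", yr)
    }
  }
  has_rr <- grepl("\\bRR\\b", entries$measures)
  if (any(has_rr & entries$year < 2014))
    stop("RR cannot be active before 2014")
  structure(list(entries = entries), class = "measure_calendar")
}

#' Default measure calendar
#'
#' The deployment history of the measures: first season June–October 2013
#' (SRA and NGA only), then May–October from 2014 on with the recommended
#' route added.
#'
#' @param years Years to cover (default 2012:2016).
#' @return A [measure_calendar()].
#' @export
default_calendar <- function(years = 2012:2016) {
  rows <- lapply(years, function(y) {
    if (y < 2013) return(NULL)
    if (y == 2013)
      data.frame(year = y, start_date = sprintf("%d-06-01", y),
                 end_date = sprintf("%d-10-31", y), measures = "SRA;NGA")
    else
      data.frame(year = y, start_date = sprintf("%d-05-01", y),
                 end_date = sprintf("%d-10-31", y), measures = "SRA;NGA;RR")
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(year = integer(), start_date = character(),
                       end_date = character(), measures = character())
  measure_calendar(rows)
}

#' Read a measure calendar from CSV
#'
#' Columns: `year, start_date, end_date, measures` (semicolon-separated).
#'
#' @param path CSV file path.
#' @return A [measure_calendar()].
#' @export
read_calendar <- function(path) {
  measure_calendar(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Is a measure active at a given time?
#'
#' @param t POSIXct (or Date) timestamps, vectorised.
#' @param measure One of `"SRA"`, `"NGA"`, `"RR"`.
#' @param cal A [measure_calendar()].
#' @return Logical vector; FALSE for years the calendar does not cover.
#' @export
is_measure_active <- function(t, measure, cal) {
  stopifnot(inherits(cal, "measure_calendar"))
  d <- as.Date(t, tz = "UTC")
  out <- logical(length(d))
  e <- cal$entries[grepl(paste0("\\b", measure, "\\b"), cal$entries$measures), ]
  for (i in seq_len(nrow(e))) {
    out <- out | (d >= e$start_date[i] & d <= e$end_date[i])
  }
  out
}
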