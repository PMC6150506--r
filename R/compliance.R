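# The compliance-indicator portfolio for the voluntary measures.
#
# Seven indicators capture complementary dimensions of compliance with the
# 10-knot speed-through-water limit and the routing measures:
#   I1 strict compliance   — every in-zone fix at or below the limit
#   I2 no-go-area usage    — % of transits through the NGA, partial/complete
#   I3 route compliance    — % of transits north of the island
#   I4 slow-down effort    — speed drop from the 3-km approach to the zone
#   I5 DWAS                — distance-weighted average speed in the zone
#   I6 non-compliant distance — % of in-zone distance above the limit
#   I7 non-compliant speed — distance-weighted mean speed of that distance
#
# Distance weighting corrects the over-representation of slow fixes produced
# by speed-dependent AIS reporting rates.

# In-zone length (nm) of each segment, by planar clipping.
segment_inzone_lengths <- function(segments, zone_poly, projection) {
  if (nrow(segments) == 0) return(numeric(0))
  poly <- project_poly(close_ring(zone_poly), projection)
  p1 <- projection$forward(segments$lon1, segments$lat1)
  p2 <- projection$forward(segments$lon2, segments$lat2)
  fr <- inzone_fractions(p1[, 1], p1[, 2], p2[, 1], p2[, 2], poly)
  ifelse(segments$length_nm > 0, segments$length_nm * fr, 0)
}

#' Distance-weighted average speed in a zone (indicator I5)
#'
#' `DWAS = sum(d_i v_i) / sum(d_i)` over the segments of a transit clipped to
#' the zone, with `d_i` the in-zone geodesic length and `v_i` the segment
#' speed (endpoint-mean STW).
#'
#' @param segments Segment table from [segmentize()].
#' @param zone_poly Lon/lat polygon.
#' @param projection The [local_projection()] shared by the analysis
#'   (use `zones$projection`).
#' @return DWAS in knots, or `NA` (with a warning-free skip) when the transit
#'   has zero in-zone length.
#' @export
dwas <- function(segments, zone_poly, projection) {
  d <- segment_inzone_lengths(segments, zone_poly, projection)
  if (sum(d) <= 0) return(NA_real_)
  sum(d * segments$speed) / sum(d)
}

#' Strict compliance (indicator I1)
#'
#' A transit is strictly compliant iff every one of its fixes inside the zone
#' has speed through water at or below the limit — a single faster fix makes
#' the whole transit non-compliant. The denominator is transits with at least
#' one in-zone fix; with none, the result is `NA`, not 0.
#'
#' @param fixes Fix table with `transit_id` and `stw`.
#' @param zone_poly Lon/lat polygon.
#' @param projection Shared [local_projection()].
#' @param limit Speed limit, knots (default 10; the boundary is inclusive:
#'   exactly 10.0 kn complies).
#' @return list: `pct` (percent compliant), `n` (transits assessed),
#'   `by_transit` (named logical).
#' @export
strict_compliance <- function(fixes, zone_poly, projection, limit = 10.0) {
  poly <- project_poly(close_ring(zone_poly), projection)
  xy <- projection$forward(fixes$lon, fixes$lat)
  inz <- point_in_polygon(xy[, 1], xy[, 2], poly)
  f <- fixes[inz, ]
  if (nrow(f) == 0) return(list(pct = NA_real_, n = 0L, by_transit = logical(0)))
  ok <- tapply(f$stw <= limit, f$transit_id, all)
  list(pct = 100 * mean(ok), n = length(ok), by_transit = ok)
}

# Along-track pre-entry buffer: segment lengths (nm) falling in the last
# `buffer_m` metres of track before the first zone entry.
buffer_lengths <- function(segments, zone_poly, projection, buffer_m) {
  d_in <- segment_inzone_lengths(segments, zone_poly, projection)
  first_in <- which(d_in > 0)[1]
  if (is.na(first_in)) return(NULL)
  poly <- project_poly(close_ring(zone_poly), projection)
  # distance along the entering segment up to the zone boundary
  p1 <- projection$forward(segments$lon1[first_in], segments$lat1[first_in])
  p2 <- projection$forward(segments$lon2[first_in], segments$lat2[first_in])
  cl <- clip_segment_to_polygon(as.numeric(p1), as.numeric(p2), poly)
  t_entry <- if (cl$inside[1]) 0 else cl$t1[1]
  buf_nm <- buffer_m / M_PER_NM
  out <- numeric(nrow(segments))
  # walk backwards from the entry point accumulating track length
  remaining <- buf_nm
  lead <- segments$length_nm[first_in] * t_entry   # outside part of entry segment
  take <- min(lead, remaining)
  out[first_in] <- take
  remaining <- remaining - take
  i <- first_in - 1L
  while (remaining > 1e-12 && i >= 1L) {
    take <- min(segments$length_nm[i], remaining)
    out[i] <- take
    remaining <- remaining - take
    i <- i - 1L
  }
  if (sum(out) <= 0) NULL else out
}

#' Slow-down effort (indicator I4)
#'
#' Speed change between the 3-km along-track approach to the zone and the
#' zone interior: `dv = DWAS(approach) - DWAS(in-zone)`; positive values mean
#' the ship slowed down. Distance-weighted averages are used on both sides
#' for robustness to reporting-rate bias.
#'
#' @inheritParams dwas
#' @param buffer_m Approach length measured backwards along the track from
#'   the first zone entry, metres (default 3000).
#' @return `dv` in knots, or `NA` when the transit has no approach coverage
#'   or no in-zone length.
#' @export
slowdown_effort <- function(segments, zone_poly, projection, buffer_m = 3000) {
  d_in <- segment_inzone_lengths(segments, zone_poly, projection)
  if (sum(d_in) <= 0) return(NA_real_)
  buf <- buffer_lengths(segments, zone_poly, projection, buffer_m)
  if (is.null(buf)) return(NA_real_)
  v_buf <- sum(buf * segments$speed) / sum(buf)
  v_in <- sum(d_in * segments$speed) / sum(d_in)
  v_buf - v_in
}

#' Non-compliance profile (indicators I6 and I7)
#'
#' `I6` is the percentage of the transit's in-zone distance covered at
#' segment speeds strictly above the limit; `I7` is the distance-weighted
#' mean speed over that non-compliant distance only (`NA` when `I6` is 0).
#'
#' @inheritParams dwas
#' @param limit Speed limit, knots.
#' @return list(`I6` percent, `I7` knots).
#' @export
noncompliance_profile <- function(segments, zone_poly, projection, limit = 10.0) {
  d <- segment_inzone_lengths(segments, zone_poly, projection)
  tot <- sum(d)
  if (tot <= 0) return(list(I6 = NA_real_, I7 = NA_real_))
  fast <- segments$speed > limit
  d_fast <- sum(d[fast])
  I6 <- 100 * d_fast / tot
  I7 <- if (d_fast > 0) sum(d[fast] * segments$speed[fast]) / d_fast else NA_real_
  list(I6 = I6, I7 = I7)
}

#' No-go-area usage (indicator I2)
#'
#' A transit is a partial user iff its path intersects the NGA at all; a
#' complete user iff it crosses both NGA chords (the area's upstream and
#' downstream ends) and essentially all (>= 99.9%) of its between-chord path
#' length lies inside the NGA. Complete users are a subset of partial users.
#' Route choice is a ground-track property, so geometry uses positions only.
#'
#' @param seg_by_transit Named list of segment tables, one per transit.
#' @param zones A [zone_set()] carrying `nga` and the two chords.
#' @return data.frame `transit_id, partial, complete, inzone_nm`.
#' @export
nga_usage <- function(seg_by_transit, zones) {
  proj <- zones$projection
  nga <- project_poly(close_ring(zones$nga), proj)
  ch_up <- if (!is.null(zones$nga_chord_up)) project_poly(zones$nga_chord_up, proj)
  ch_dn <- if (!is.null(zones$nga_chord_dn)) project_poly(zones$nga_chord_dn, proj)
  res <- lapply(names(seg_by_transit), function(tid) {
    seg <- seg_by_transit[[tid]]
    d_in <- segment_inzone_lengths(seg, zones$nga, proj)
    partial <- sum(d_in) > 1e-9
    complete <- FALSE
    if (partial && !is.null(ch_up) && !is.null(ch_dn)) {
      path <- rbind(proj$forward(seg$lon1, seg$lat1),
                    proj$forward(seg$lon2[nrow(seg)], seg$lat2[nrow(seg)]))
      x_up <- path_gate_crossing(path, ch_up)
      x_dn <- path_gate_crossing(path, ch_dn)
      if (!is.null(x_up) && !is.null(x_dn)) {
        # path length between the two chord crossings, and its in-NGA share
        a <- x_up; b <- x_dn
        if (a$seg > b$seg || (a$seg == b$seg && a$t > b$t)) { a <- x_dn; b <- x_up }
        lens <- seg$length_nm
        between <- 0; inside_between <- 0
        for (i in a$seg:b$seg) {
          t0 <- if (i == a$seg) a$t else 0
          t1 <- if (i == b$seg) b$t else 1
          if (t1 <= t0) next
          between <- between + lens[i] * (t1 - t0)
          frac_in <- if (lens[i] > 0) d_in[i] / lens[i] else 0
          # approximate: assume the in-NGA part of the segment falls in [t0,t1]
          inside_between <- inside_between + min(d_in[i], lens[i] * (t1 - t0)) *
            (frac_in > 0)
        }
        complete <- between > 0 && inside_between / between >= 0.999
      }
    }
    data.frame(transit_id = tid, partial = partial, complete = complete,
               inzone_nm = sum(d_in), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Island-route compliance (indicator I3)
#'
#' Classifies each transit north or south of the island by which reference
#' gate its ground track crosses. Transits crossing both or neither gate are
#' unclassifiable and excluded from the denominator.
#'
#' @param seg_by_transit Named list of segment tables.
#' @param zones A [zone_set()] with `rr_gate_n`, `rr_gate_s`.
#' @return list: `pct_north`, `n` classifiable, `by_transit` (factor
#'   north/south/unclassifiable), `log`.
#' @export
rr_compliance <- function(seg_by_transit, zones) {
  proj <- zones$projection
  gn <- project_poly(zones$rr_gate_n, proj)
  gs <- project_poly(zones$rr_gate_s, proj)
  cls <- vapply(names(seg_by_transit), function(tid) {
    seg <- seg_by_transit[[tid]]
    path <- rbind(proj$forward(seg$lon1, seg$lat1),
                  proj$forward(seg$lon2[nrow(seg)], seg$lat2[nrow(seg)]))
    hit_n <- !is.null(path_gate_crossing(path, gn))
    hit_s <- !is.null(path_gate_crossing(path, gs))
    if (hit_n && !hit_s) "north" else if (hit_s && !hit_n) "south"
    else "unclassifiable"
  }, character(1))
  ok <- cls != "unclassifiable"
  log <- if (any(!ok))
    sprintf("transit %s: crossed both or neither island gate, excluded",
            names(seg_by_transit)[!ok]) else character(0)
  list(pct_north = if (any(ok)) 100 * mean(cls[ok] == "north") else NA_real_,
       n = sum(ok), by_transit = cls, log = log)
}

#' Build the compliance portfolio (one row per zone-year-status)
#'
#' Computes the full indicator portfolio on built transits, split by year and
#' measure status (active/inactive). Empty periods get a row with zero counts
#' and absent indicators.
#'
#' @param transits Transit table from [build_transits()].
#' @param fixes Fix table with `transit_id` and `stw`.
#' @param zones A [zone_set()].
#' @param cal A [measure_calendar()].
#' @param limit Speed limit, knots.
#' @param buffer_m Slow-down approach length, metres.
#' @return Object of class `compliance_portfolio`: a data.frame with columns
#'   `year, status, n_transits, n_vessels, I1, I2_partial, I2_complete, I3,
#'   I4_median, I4_pct_ge1, I5_mean, I5_sd, I6, I7`, plus attribute
#'   `per_transit` (long per-transit indicator table).
#' @export
build_portfolio <- function(transits, fixes, zones, cal, limit = 10.0,
                            buffer_m = 3000) {
  proj <- zones$projection
  seg_by_transit <- split_segments(fixes, transits$transit_id)
  per <- per_transit_indicators(transits, fixes, seg_by_transit, zones, limit,
                                buffer_m)
  rows <- list()
  for (yr in sort(unique(transits$year))) {
    for (st in c("active", "inactive")) {
      sel <- per$year == yr & per$status == st
      p <- per[sel, ]
      # SRA indicators restricted to transits touching the SRA
      psra <- p[!is.na(p$I5), ]
      n_tr <- nrow(psra)
      i6tot <- if (n_tr) 100 * sum(psra$d_fast_nm) / sum(psra$d_in_nm) else NA_real_
      i7tot <- if (n_tr && sum(psra$d_fast_nm) > 0)
        sum(psra$d_fast_nm * psra$I7, na.rm = TRUE) / sum(psra$d_fast_nm) else NA_real_
      rows[[paste(yr, st)]] <- data.frame(
        year = yr, status = st, n_transits = n_tr,
        n_vessels = length(unique(psra$vessel_id)),
        I1 = if (n_tr) 100 * mean(psra$strict) else NA_real_,
        I2_partial = if (nrow(p)) 100 * mean(p$nga_partial) else NA_real_,
        I2_complete = if (nrow(p)) 100 * mean(p$nga_complete) else NA_real_,
        I3 = if (any(p$rr_class != "unclassifiable"))
          100 * mean(p$rr_class[p$rr_class != "unclassifiable"] == "north") else NA_real_,
        I4_median = if (any(!is.na(p$I4))) stats::median(p$I4, na.rm = TRUE) else NA_real_,
        I4_pct_ge1 = if (any(!is.na(p$I4))) 100 * mean(p$I4 >= 1, na.rm = TRUE) else NA_real_,
        I5_mean = if (n_tr) mean(psra$I5) else NA_real_,
        I5_sd = if (n_tr > 1) stats::sd(psra$I5) else NA_real_,
        I6 = i6tot, I7 = i7tot)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, per_transit = per, class = c("compliance_portfolio", "data.frame"))
}

#' @export
print.compliance_portfolio <- function(x, ...) {
  cat("Compliance portfolio (speed limit indicators I1..I7 by year and status)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 1))
  print(df, row.names = FALSE)
  invisible(x)
}

# Split fix table into per-transit segment tables (named list).
split_segments <- function(fixes, transit_ids) {
  out <- list()
  for (tid in transit_ids) {
    f <- fixes[fixes$transit_id == tid, ]
    f <- f[order(f$t), ]
    if (nrow(f) >= 2) out[[tid]] <- segmentize(f)
  }
  out
}

# Long per-transit indicator table backing the portfolio.
per_transit_indicators <- function(transits, fixes, seg_by_transit, zones,
                                   limit, buffer_m) {
  proj <- zones$projection
  sc <- strict_compliance(fixes, zones$sra, proj, limit)
  nga <- nga_usage(seg_by_transit, zones)
  rr <- rr_compliance(seg_by_transit, zones)
  rows <- lapply(seq_len(nrow(transits)), function(i) {
    tid <- transits$transit_id[i]
    seg <- seg_by_transit[[tid]]
    if (is.null(seg)) return(NULL)
    d_in <- segment_inzone_lengths(seg, zones$sra, proj)
    tot <- sum(d_in)
    fast <- seg$speed > limit
    d_fast <- sum(d_in[fast])
    i5 <- if (tot > 0) sum(d_in * seg$speed) / tot else NA_real_
    i7 <- if (d_fast > 0) sum(d_in[fast] * seg$speed[fast]) / d_fast else NA_real_
    data.frame(
      transit_id = tid, vessel_id = transits$vessel_id[i],
      year = transits$year[i],
      status = if (isTRUE(transits$measures_active[i])) "active" else "inactive",
      strict = if (tid %in% names(sc$by_transit)) unname(sc$by_transit[tid]) else NA,
      I4 = slowdown_effort(seg, zones$sra, proj, buffer_m),
      I5 = i5, I6 = if (tot > 0) 100 * d_fast / tot else NA_real_, I7 = i7,
      d_in_nm = tot, d_fast_nm = d_fast,
      nga_partial = nga$partial[nga$transit_id == tid],
      nga_complete = nga$complete[nga$transit_id == tid],
      rr_class = rr$by_transit[[tid]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
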