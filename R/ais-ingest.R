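# AIS pre-processing: parse decoded fix tables, drop poor data points
# (erroneous speed, bad position, duplicates, implausible jumps), group the
# survivors into per-vessel transits of the study area, and segmentise
# transits for the distance-weighted statistics.
#
# Thresholds follow the cleaning categories the monitoring programme names
# (incomplete transit, erroneous speed, bad position); the numeric values are
# deliberately generous for merchant vessels and are arguments, not constants.

#' Read a decoded AIS fix table
#'
#' CSV columns: `vessel_id, timestamp_iso8601, lat, lon, sog_kn, cog_deg`.
#' Unparseable rows are dropped with a logged reason, never an error.
#'
#' @param path CSV path.
#' @return list with `fixes` (data.frame `vessel_id, t, lon, lat, sog, cog`)
#'   and `rejections` (data.frame `fix_id, reason`).
#' @export
read_ais_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  t <- as.POSIXct(raw$timestamp_iso8601, tz = "UTC",
                  format = "%Y-%m-%dT%H:%M:%OSZ")
  alt <- is.na(t)
  t[alt] <- as.POSIXct(raw$timestamp_iso8601[alt], tz = "UTC",
                       format = "%Y-%m-%d %H:%M:%OS")
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  sog <- suppressWarnings(as.numeric(raw$sog_kn))
  cog <- suppressWarnings(as.numeric(raw$cog_deg))
  bad <- is.na(t) | is.na(lon) | is.na(lat) | is.na(sog) | is.na(cog)
  rej <- data.frame(fix_id = which(bad),
                    reason = rep("unparseable", sum(bad)))
  fixes <- data.frame(vessel_id = raw$vessel_id, t = t, lon = lon, lat = lat,
                      sog = sog, cog = cog, stringsAsFactors = FALSE)[!bad, ]
  list(fixes = fixes, rejections = rej)
}

#' Clean AIS fixes
#'
#' Applies, in order: finite/parseable check, position inside the study-area
#' bounding box, absolute SOG cap, duplicate `(vessel, time)` removal
#' (keeping the first), and an implied point-to-point speed cap within each
#' vessel's time-ordered sequence. One reason is logged per rejected fix.
#' Cleaning is idempotent.
#'
#' @param fixes Fix data.frame (`vessel_id, t, lon, lat, sog, cog`).
#' @param study_area Lon/lat polygon (its bounding box is the position filter).
#' @param max_sog Absolute speed cap, knots (default 35).
#' @param max_implied Implied point-to-point speed cap, knots (default 50).
#' @return list with `fixes` (survivors, ordered by vessel then time) and
#'   `rejections` (data.frame `fix_id, reason`; `fix_id` indexes the input).
#' @export
clean_fixes <- function(fixes, study_area, max_sog = 35, max_implied = 50) {
  n <- nrow(fixes)
  if (n == 0) return(list(fixes = fixes,
                          rejections = data.frame(fix_id = integer(),
                                                  reason = character())))
  fixes$.id <- seq_len(n)
  reason <- rep(NA_character_, n)
  bb <- apply(close_ring(study_area), 2, range)
  bad_pos <- fixes$lon < bb[1, 1] | fixes$lon > bb[2, 1] |
             fixes$lat < bb[1, 2] | fixes$lat > bb[2, 2] |
             !is.finite(fixes$lon) | !is.finite(fixes$lat)
  reason[bad_pos] <- "bad position"
  bad_sog <- is.na(reason) & (fixes$sog < 0 | fixes$sog > max_sog | !is.finite(fixes$sog))
  reason[bad_sog] <- "erroneous speed"
  keep <- is.na(reason)
  f <- fixes[keep, ]
  f <- f[order(f$vessel_id, f$t, f$.id), ]
  dup <- duplicated(f[, c("vessel_id", "t")])
  reason[f$.id[dup]] <- "duplicate fix"
  f <- f[!dup, ]
  # implied-speed filter: greedy forward pass per vessel against last kept fix.
  # Fast path: when no consecutive pair violates the cap, nothing can be
  # rejected (removals only lengthen gaps), so skip the sequential pass.
  n_f <- nrow(f)
  if (n_f > 1) {
    same <- f$vessel_id[-1] == f$vessel_id[-n_f]
    dt_h <- (as.numeric(f$t[-1]) - as.numeric(f$t[-n_f])) / 3600
    d_nm <- geodesic_nm(f$lon[-n_f], f$lat[-n_f], f$lon[-1], f$lat[-1])
    any_fast <- any(same & dt_h > 0 & d_nm / dt_h > max_implied)
  } else any_fast <- FALSE
  for (vid in if (any_fast) unique(f$vessel_id) else character(0)) {
    idx <- which(f$vessel_id == vid)
    if (length(idx) < 2) next
    last <- idx[1]
    for (i in idx[-1]) {
      dt_h <- as.numeric(difftime(f$t[i], f$t[last], units = "hours"))
      d_nm <- geodesic_nm(f$lon[last], f$lat[last], f$lon[i], f$lat[i])
      if (dt_h > 0 && d_nm / dt_h > max_implied) {
        reason[f$.id[i]] <- "implausible jump"
      } else {
        last <- i
      }
    }
  }
  out <- fixes[is.na(reason), setdiff(names(fixes), ".id")]
  out <- out[order(out$vessel_id, out$t), ]
  rownames(out) <- NULL
  rej <- data.frame(fix_id = which(!is.na(reason)), reason = reason[!is.na(reason)])
  list(fixes = out, rejections = rej)
}

#' Build transits from cleaned fixes
#'
#' Groups fixes by vessel, splits passages at silent gaps longer than
#' `max_gap_min` or at study-area exits, and keeps passages that are
#' complete: at least `min_fixes` fixes inside the study area and spanning
#' both halves of the along-channel axis. Direction is the sign of the net
#' along-channel displacement (upstream = toward the inland transit-time
#' gate). The measure-active flag is evaluated at the transit's mid-time.
#'
#' @param fixes Cleaned fix data.frame.
#' @param vessels data.frame `vessel_id, ship_class, flag`; vessels missing
#'   from it get class/flag `"unknown"` and a log entry.
#' @param pilots data.frame `vessel_id, t_start, t_end, pilot_onboard`
#'   matching passages by vessel and time window, or `NULL` (no pilot info).
#' @param zones A [zone_set()].
#' @param cal A [measure_calendar()].
#' @param max_gap_min Gap splitting passages, minutes (default 30).
#' @param min_fixes Minimum in-area fixes for a complete transit (default 5).
#' @return list with `transits` (one row per complete transit: `transit_id,
#'   vessel_id, ship_class, flag, pilot_onboard, direction, year,
#'   measures_active, n_fixes, t_start, t_end`), `fixes` (with `transit_id`),
#'   `log` (character vector of notes on excluded passages / unknown vessels).
#' @export
build_transits <- function(fixes, vessels = NULL, pilots = NULL, zones, cal,
                           max_gap_min = 30, min_fixes = 5) {
  stopifnot(inherits(zones, "zone_set"))
  proj <- zones$projection
  sa <- project_poly(zones$study_area, proj)
  log <- character()
  empty <- data.frame(transit_id = character(), vessel_id = character(),
                      ship_class = character(), flag = character(),
                      pilot_onboard = logical(), direction = character(),
                      year = integer(), measures_active = logical(),
                      n_fixes = integer(),
                      t_start = as.POSIXct(character(), tz = "UTC"),
                      t_end = as.POSIXct(character(), tz = "UTC"))
  if (nrow(fixes) == 0)
    return(list(transits = empty, fixes = cbind(fixes, transit_id = character(0)),
                log = log))

  # along-channel axis: inland (Saint-Simeon) gate -> seaward (Escoumins) gate
  g_in <- colMeans(project_poly(zones$gate_sts, proj))
  g_out <- colMeans(project_poly(zones$gate_esc, proj))
  axis <- (g_out - g_in) / sqrt(sum((g_out - g_in)^2))  # points downstream
  xy <- proj$forward(fixes$lon, fixes$lat)
  s <- (xy[, 1] - g_in[1]) * axis[1] + (xy[, 2] - g_in[2]) * axis[2]
  s_mid <- (0 +  (g_out - g_in) %*% axis / 2)[1]
  inside <- point_in_polygon(xy[, 1], xy[, 2], sa)

  fixes$.s <- s
  fixes$.inside <- inside
  ord <- order(fixes$vessel_id, fixes$t)
  fixes <- fixes[ord, ]

  transit_rows <- list()
  fix_tid <- rep(NA_character_, nrow(fixes))
  counter <- 0L
  for (vid in unique(fixes$vessel_id)) {
    idx <- which(fixes$vessel_id == vid)
    gap <- c(FALSE, diff(as.numeric(fixes$t[idx])) > max_gap_min * 60)
    # a study-area exit (inside -> outside transition) also ends a passage
    exit <- c(FALSE, diff(fixes$.inside[idx]) == -1)
    passage <- cumsum(gap | exit)
    for (p in unique(passage)) {
      pid <- idx[passage == p]
      pin <- pid[fixes$.inside[pid]]
      if (length(pin) < min_fixes) {
        log <- c(log, sprintf("vessel %s: passage with %d in-area fixes excluded (incomplete)",
                              vid, length(pin)))
        next
      }
      srange <- range(fixes$.s[pin])
      if (!(srange[1] < s_mid && srange[2] > s_mid)) {
        log <- c(log, sprintf("vessel %s: passage not spanning the study area excluded",
                              vid))
        next
      }
      if (length(unique(as.numeric(fixes$t[pin]))) < 2) next
      counter <- counter + 1L
      tid <- sprintf("%s_%03d", vid, counter)
      fix_tid[pin] <- tid
      net <- fixes$.s[pin[length(pin)]] - fixes$.s[pin[1]]
      mid_t <- fixes$t[pin[1]] + (as.numeric(fixes$t[pin[length(pin)]]) -
                                  as.numeric(fixes$t[pin[1]])) / 2
      transit_rows[[tid]] <- data.frame(
        transit_id = tid, vessel_id = vid,
        direction = if (net >= 0) "downstream" else "upstream",
        year = as.integer(format(mid_t, "%Y", tz = "UTC")),
        measures_active = is_measure_active(mid_t, "SRA", cal),
        n_fixes = length(pin), t_start = fixes$t[pin[1]],
        t_end = fixes$t[pin[length(pin)]], stringsAsFactors = FALSE)
    }
  }
  tr <- if (length(transit_rows)) do.call(rbind, transit_rows) else empty
  rownames(tr) <- NULL

  # vessel metadata join
  if (!is.null(vessels) && nrow(tr)) {
    m <- match(tr$vessel_id, vessels$vessel_id)
    tr$ship_class <- ifelse(is.na(m), "unknown", vessels$ship_class[m])
    tr$flag <- ifelse(is.na(m), "unknown", vessels$flag[m])
    if (anyNA(m))
      log <- c(log, sprintf("vessel %s: missing from metadata, class/flag unknown",
                            unique(tr$vessel_id[is.na(m)])))
  } else if (nrow(tr)) {
    tr$ship_class <- "unknown"; tr$flag <- "unknown"
  }
  # pilot join by vessel + overlapping time window
  if (nrow(tr)) tr$pilot_onboard <- FALSE
  if (!is.null(pilots) && nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      hit <- pilots$vessel_id == tr$vessel_id[i] &
             as.numeric(pilots$t_start) <= as.numeric(tr$t_end[i]) &
             as.numeric(pilots$t_end) >= as.numeric(tr$t_start[i])
      if (any(hit)) tr$pilot_onboard[i] <- any(pilots$pilot_onboard[hit])
    }
  }
  fixes$transit_id <- fix_tid
  fixes$.s <- NULL; fixes$.inside <- NULL
  keep_cols <- c("transit_id", "vessel_id", "ship_class", "flag", "pilot_onboard",
                 "direction", "year", "measures_active", "n_fixes",
                 "t_start", "t_end")
  list(transits = tr[, intersect(keep_cols, names(tr))],
       fixes = fixes[!is.na(fixes$transit_id), ], log = log)
}

#' Segmentise one transit
#'
#' Consecutive-fix segments with geodesic length and a representative speed.
#' Segment speed is the mean of the endpoint speeds through water (falling
#' back to SOG when STW is absent) so the per-fix current correction
#' propagates into all distance-weighted statistics; length/duration speed is
#' retained as `speed_ltd` for QC.
#'
#' @param tr_fixes Time-ordered fixes of a single transit (with `stw` filled
#'   when available).
#' @return data.frame of `n-1` segments: endpoints, `t1`, `t2`, `length_nm`,
#'   `duration_s`, `speed` (kn), `speed_ltd` (kn).
#' @export
segmentize <- function(tr_fixes) {
  n <- nrow(tr_fixes)
  stopifnot(n >= 2, !is.unsorted(as.numeric(tr_fixes$t), strictly = TRUE))
  sp <- if (!is.null(tr_fixes$stw)) tr_fixes$stw else tr_fixes$sog
  i <- seq_len(n - 1)
  len <- geodesic_nm(tr_fixes$lon[i], tr_fixes$lat[i],
                     tr_fixes$lon[i + 1], tr_fixes$lat[i + 1])
  dur <- as.numeric(tr_fixes$t[i + 1]) - as.numeric(tr_fixes$t[i])
  data.frame(lon1 = tr_fixes$lon[i], lat1 = tr_fixes$lat[i],
             lon2 = tr_fixes$lon[i + 1], lat2 = tr_fixes$lat[i + 1],
             t1 = tr_fixes$t[i], t2 = tr_fixes$t[i + 1],
             length_nm = len, duration_s = dur,
             speed = (sp[i] + sp[i + 1]) / 2,
             speed_ltd = len / (dur / 3600))
}
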