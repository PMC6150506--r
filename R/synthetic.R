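# Synthetic study-system generator.
#
# Emulates the statistical structure of the monitored system so every
# pipeline stage is testable without any external data: rectangular zone
# geometry laid out like the real measure system (a slow-down area inside a
# mandatory-pilotage channel, a no-go area downstream of it, an island with
# north/south passages), tidal surface currents, per-period cruising-speed
# regimes (inactive 14.1 +/- 2.6 kn, active 11.3 +/- 1.7 kn), partial
# compliance behaviour (deceleration ramps into the slow-down area, strict
# compliers, island-route choice), and speed-dependent AIS emission with
# dropout — the mechanism that over-represents slow ships in fix counts.
#
# Vessels follow waypoint routes through the water: the heading crabs into
# the current so the ground track stays on the route, which makes speed
# through water exactly recoverable from emitted SOG/COG and the same
# current field (a property the tests rely on).

#' Synthetic management-zone set
#'
#' Rectangular zones approximating the layout of the real system on a
#' ~90 x 55 km estuary reach: the channel runs east-west, the slow-down area
#' (SRA) sits in the west (inland) half, the no-go area (NGA) hugs the north
#' shore downstream of it, an island with north/south reference gates lies
#' further seaward, and the two transit-time gates close off the reach.
#'
#' @return A [zone_set()].
#' @export
synthetic_zones <- function() {
  rect <- function(lon0, lon1, lat0, lat1)
    cbind(c(lon0, lon1, lon1, lon0), c(lat0, lat0, lat1, lat1))
  zone_set(
    study_area = rect(-70.20, -69.00, 48.05, 48.55),
    sra = rect(-69.920, -69.785, 48.10, 48.50),          # ~5.4 nm wide
    nga = rect(-69.68, -69.52, 48.30, 48.48),
    caution = rect(-69.50, -69.30, 48.05, 48.55),
    rr_gate_n = rbind(c(-69.45, 48.31), c(-69.45, 48.55)),
    rr_gate_s = rbind(c(-69.45, 48.05), c(-69.45, 48.29)),
    gate_sts = rbind(c(-70.10, 48.05), c(-70.10, 48.55)),  # inland gate
    gate_esc = rbind(c(-69.10, 48.05), c(-69.10, 48.55)),  # seaward gate
    nga_chord_up = rbind(c(-69.68, 48.30), c(-69.68, 48.48)),
    nga_chord_dn = rbind(c(-69.52, 48.30), c(-69.52, 48.48)),
    pilot_station = c(-69.08, 48.40))
}

#' Scenario configuration
#'
#' Bundles every knob of the generator with defaults matching the study
#' conditions: per-period cruising speed regimes (inactive 14.1 +/- 2.6 kn,
#' active 11.3 +/- 1.7 kn), ~10% strict compliers under active measures,
#' >= 90% pilotage, >= 93% north-route choice, semidiurnal tide, and a
#' speed-dependent AIS emission interval.
#'
#' @param seed Integer seed; identical config + seed give identical output.
#' @param years Years covered.
#' @param n_transits Named-by-status list or data.frame `year, status, n`;
#'   default 40 active + 20 inactive per year from 2013 (2012 inactive only).
#' @param speed_inactive,speed_active Mean/sd (kn) of cruising speed by period.
#' @param p_strict Probability a transit targets strict compliance when the
#'   measures are active.
#' @param p_north Probability of the north (recommended) route.
#' @param p_nga_cross Probability a north-route transit cuts through the NGA.
#' @param p_pilot Probability of a pilot onboard.
#' @param class_mix,flag_mix Named probability vectors for vessel class/flag.
#' @param ramp_m Deceleration ramp length before the SRA, metres.
#' @param tidal_amp_kn,tidal_period_h,tidal_phase Tidal current parameters.
#' @param emission_base_s,emission_ref_kn,emission_exponent,emission_cap_s
#'   Emission-interval rule: `clamp(base * (ref / speed)^exponent, 2 s, cap)`.
#'   The sublinear default (exponent 0.5) raises the reporting rate with
#'   speed more slowly than the steaming rate, so slow ships contribute more
#'   fixes per nautical mile — the over-representation bias that motivates
#'   distance weighting.
#' @param p_dropout Per-report dropout probability.
#' @param sog_noise_kn S.d. of noise added to emitted SOG (the 0.7-kn STW
#'   uncertainty budget is dominated by the current model; per-component
#'   current error of ~0.36 kn is injected separately in tests).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, years = 2012:2016, n_transits = NULL,
                            speed_inactive = c(mean = 14.1, sd = 2.6),
                            speed_active = c(mean = 11.3, sd = 1.7),
                            p_strict = 0.10, p_north = 0.93, p_nga_cross = 0.10,
                            p_pilot = 0.90,
                            class_mix = c(cargo = 0.6, tanker = 0.25, passenger = 0.15),
                            flag_mix = c(Canadian = 0.45, international = 0.55),
                            ramp_m = 3000, tidal_amp_kn = 1.5,
                            tidal_period_h = 12.42, tidal_phase = 0,
                            emission_base_s = 60, emission_ref_kn = 6,
                            emission_exponent = 0.5, emission_cap_s = 180,
                            p_dropout = 0, sog_noise_kn = 0) {
  if (is.null(n_transits)) {
    n_transits <- do.call(rbind, lapply(years, function(y) {
      if (y < 2013) data.frame(year = y, status = "inactive", n = 20)
      else rbind(data.frame(year = y, status = "active", n = 40),
                 data.frame(year = y, status = "inactive", n = 20))
    }))
  }
  stopifnot(p_strict >= 0, p_strict <= 1, p_north >= 0, p_north <= 1,
            speed_inactive["sd"] >= 0, speed_active["sd"] >= 0)
  structure(as.list(environment()), class = "scenario_config")
}

# Analytic tidal current in knots: along-channel (east-west) semidiurnal
# sinusoid with a smooth north-south amplitude gradient, plus a weak
# cross-channel component.
#' Analytic synthetic current as a function
#'
#' Returns `function(lon, lat, t) -> list(u, v)` in knots, usable
#' directly by [add_stw()] and by [gen_transits()]; [gen_current_field()]
#' materialises the same field on a grid.
#'
#' @param cfg A [scenario_config()].
#' @return A current function.
#' @export
synthetic_current_function <- function(cfg) {
  amp <- cfg$tidal_amp_kn; Th <- cfg$tidal_period_h; ph <- cfg$tidal_phase
  function(lon, lat, t) {
    th <- as.numeric(t) / 3600
    tide <- sin(2 * pi * th / Th + ph)
    grad <- 1 + 0.3 * (lat - 48.30)  # weak cross-channel amplitude gradient
    list(u = amp * tide * grad, v = 0.2 * amp * cos(2 * pi * th / Th + ph))
  }
}

#' Materialise the synthetic current on a grid
#'
#' Samples the analytic tidal field at cell centres and hourly snapshots.
#'
#' @param cfg A [scenario_config()].
#' @param zones A [zone_set()] (grid covers its study area).
#' @param start POSIXct of the first snapshot.
#' @param n_hours Number of hourly snapshots.
#' @param cell_size Cell size in metres (default 400, the operational
#'   resolution; tests use coarser grids).
#' @return A [current_field()].
#' @export
gen_current_field <- function(cfg, zones, start, n_hours, cell_size = 400) {
  proj <- zones$projection
  sa <- project_poly(zones$study_area, proj)
  pad <- 2 * cell_size
  xr <- range(sa[, 1]) + c(-pad, pad); yr <- range(sa[, 2]) + c(-pad, pad)
  ncols <- ceiling(diff(xr) / cell_size); nrows <- ceiling(diff(yr) / cell_size)
  grid <- grid_spec(xr[1], yr[1], cell_size, nrows, ncols, proj)
  times <- start + 3600 * (seq_len(n_hours) - 1)
  fn <- synthetic_current_function(cfg)
  idx <- expand.grid(row = seq_len(nrows), col = seq_len(ncols))
  ctr <- cell_center(idx$row, idx$col, grid)
  ll <- proj$inverse(ctr[, 1], ctr[, 2])
  u <- v <- array(0, c(n_hours, nrows, ncols))
  for (k in seq_len(n_hours)) {
    uv <- fn(ll[, 1], ll[, 2], times[k])
    u[k, , ][cbind(idx$row, idx$col)] <- uv$u * MS_PER_KN
    v[k, , ][cbind(idx$row, idx$col)] <- uv$v * MS_PER_KN
  }
  current_field(u, v, times, grid)
}

#' Synthetic whale relative-density surface
#'
#' Mixture of Gaussian hotspots, normalised to sum 1. The blue-whale hotspot
#' sits in the no-go area; fin, humpback and minke hotspots overlap the
#' slow-down area — mirroring which species benefit from which measure.
#'
#' @param cfg A [scenario_config()] (its seed fixes nothing here; the
#'   surface is deterministic).
#' @param species One of `"minke"`, `"fin"`, `"humpback"`, `"blue"`.
#' @param grid A [grid_spec()].
#' @return A [whale_density()].
#' @export
gen_whale_density <- function(cfg, species = c("fin", "minke", "humpback", "blue"),
                              grid) {
  species <- match.arg(species)
  proj <- grid$projection
  hot_ll <- switch(species,
    blue = list(c(-69.60, 48.39, 6000)),
    fin = list(c(-69.85, 48.30, 8000), c(-69.70, 48.25, 12000)),
    humpback = list(c(-69.87, 48.25, 9000), c(-69.60, 48.20, 14000)),
    minke = list(c(-69.84, 48.35, 7000), c(-69.45, 48.30, 15000)))
  idx <- expand.grid(row = seq_len(grid$nrows), col = seq_len(grid$ncols))
  ctr <- cell_center(idx$row, idx$col, grid)
  vals <- matrix(0, grid$nrows, grid$ncols)
  for (h in hot_ll) {
    c_xy <- proj$forward(h[1], h[2])
    d2 <- (ctr[, 1] - c_xy[1])^2 + (ctr[, 2] - c_xy[2])^2
    vals[cbind(idx$row, idx$col)] <- vals[cbind(idx$row, idx$col)] +
      exp(-d2 / (2 * h[3]^2))
  }
  whale_density(vals, grid, species)
}

# Route waypoint chains (lon/lat), west (inland) to east (seaward).
route_waypoints <- function(route = c("north", "north_nga", "south")) {
  route <- match.arg(route)
  switch(route,
    north = rbind(c(-70.18, 48.30), c(-69.95, 48.30), c(-69.73, 48.24),
                  c(-69.50, 48.26), c(-69.44, 48.40), c(-69.02, 48.40)),
    north_nga = rbind(c(-70.18, 48.30), c(-69.95, 48.30), c(-69.72, 48.33),
                      c(-69.60, 48.38), c(-69.50, 48.40), c(-69.45, 48.41),
                      c(-69.02, 48.40)),
    south = rbind(c(-70.18, 48.30), c(-69.95, 48.30), c(-69.70, 48.22),
                  c(-69.45, 48.18), c(-69.02, 48.18)))
}

# Densely resample a projected polyline at ~step_m spacing; returns matrix
# with columns x, y, s (arc length, m) and bearing (deg true, +x = east).
densify_route <- function(wp_xy, step_m = 200) {
  pts <- list()
  for (i in seq_len(nrow(wp_xy) - 1)) {
    a <- wp_xy[i, ]; b <- wp_xy[i + 1, ]
    L <- sqrt(sum((b - a)^2))
    n <- max(2, ceiling(L / step_m))
    tt <- seq(0, 1, length.out = n)
    if (i > 1) tt <- tt[-1]
    pts[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  xy <- do.call(rbind, pts)
  ds <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(ds))
  brg <- atan2(diff(xy[, 1]), diff(xy[, 2])) * 180 / pi
  brg <- c(brg, brg[length(brg)]) %% 360
  cbind(x = xy[, 1], y = xy[, 2], s = s, bearing = brg)
}

# Water-speed profile w(s): cruise outside, linear ramp of length ramp_m down
# to target ending at the zone entry, target inside the zone, symmetric ramp
# back after exit. s_in/s_out are zone entry/exit arc lengths (m).
speed_profile <- function(s, cruise, target, s_in, s_out, ramp_m) {
  w <- rep(cruise, length(s))
  if (is.na(s_in)) return(w)
  ramp <- pmax(ramp_m, 1)
  pre <- s >= (s_in - ramp) & s < s_in
  w[pre] <- cruise + (target - cruise) * (s[pre] - (s_in - ramp)) / ramp
  inz <- s >= s_in & s <= s_out
  w[inz] <- target
  post <- s > s_out & s <= s_out + ramp
  w[post] <- target + (cruise - target) * (s[post] - s_out) / ramp
  w
}

# Simulate one transit: returns list(fixes, truth) or NULL when degenerate.
simulate_transit <- function(tid, vid, t0, route, dirn, cruise, target, cfg,
                             zones, current_fn, dt = 10) {
  proj <- zones$projection
  wp <- route_waypoints(route)
  if (dirn == "upstream") wp <- wp[rev(seq_len(nrow(wp))), ]
  rt <- densify_route(project_poly(wp, proj))
  sra <- project_poly(close_ring(zones$sra), proj)
  in_sra <- point_in_polygon(rt[, "x"], rt[, "y"], sra)
  s_in <- if (any(in_sra)) rt[which(in_sra)[1], "s"] else NA_real_
  s_out <- if (any(in_sra)) rt[which(in_sra)[sum(in_sra)], "s"] else NA_real_
  s_end <- rt[nrow(rt), "s"]
  # planted truth: distance-weighted mean water speed inside the zone
  truth_dwas <- if (!is.na(s_in)) {
    sg <- seq(s_in, s_out, by = 50)
    mean(speed_profile(sg, cruise, target, s_in, s_out, cfg$ramp_m))
  } else NA_real_

  rs <- rt[, "s"]; rx <- rt[, "x"]; ry <- rt[, "y"]; rb <- rt[, "bearing"]
  s <- 0; t <- as.numeric(t0)
  next_emit <- t
  cap <- 8192L
  e_t <- numeric(cap); e_lon <- numeric(cap); e_lat <- numeric(cap)
  e_sog <- numeric(cap); e_cog <- numeric(cap)
  k <- 0L
  truth_strict <- TRUE
  while (s < s_end && k < cap) {
    w <- speed_profile(s, cruise, target, s_in, s_out, cfg$ramp_m)
    i <- findInterval(s, rs, all.inside = TRUE)
    fsh <- (s - rs[i]) / max(rs[i + 1] - rs[i], 1e-9)
    brg <- (rb[i] + fsh * (rb[i + 1] - rb[i])) * pi / 180
    x <- rx[i] + fsh * (rx[i + 1] - rx[i])
    y <- ry[i] + fsh * (ry[i + 1] - ry[i])
    ll <- proj$inverse(x, y)
    uv <- current_fn(ll[1], ll[2], t)
    c_par <- uv$u[1] * sin(brg) + uv$v[1] * cos(brg)
    c_perp <- -uv$u[1] * cos(brg) + uv$v[1] * sin(brg)
    G <- c_par + sqrt(max(w^2 - c_perp^2, 0.25))  # ground speed along track, kn
    if (!is.na(s_in) && s >= s_in && s <= s_out && w > 10) truth_strict <- FALSE
    if (t >= next_emit) {
      if (cfg$p_dropout <= 0 || stats::runif(1) >= cfg$p_dropout) {
        k <- k + 1L
        e_t[k] <- t; e_lon[k] <- ll[1]; e_lat[k] <- ll[2]
        e_sog[k] <- max(0, G + if (cfg$sog_noise_kn > 0)
          stats::rnorm(1, 0, cfg$sog_noise_kn) else 0)
        e_cog[k] <- (brg * 180 / pi) %% 360
      }
      next_emit <- next_emit +
        max(2, min(cfg$emission_cap_s,
                   cfg$emission_base_s *
                     (cfg$emission_ref_kn / max(w, 0.1))^cfg$emission_exponent))
    }
    s <- s + G * MS_PER_KN * dt
    t <- t + dt
  }
  if (k < 2) return(NULL)
  f <- data.frame(vessel_id = vid,
                  t = as.POSIXct(e_t[1:k], origin = "1970-01-01", tz = "UTC"),
                  lon = e_lon[1:k], lat = e_lat[1:k], sog = e_sog[1:k],
                  cog = e_cog[1:k], stringsAsFactors = FALSE)
  truth <- data.frame(transit_id = tid, vessel_id = vid, route = route,
                      direction = dirn, cruise_kn = cruise, target_kn = target,
                      dwas_true = truth_dwas, strict_true = truth_strict,
                      t_start = f$t[1], stringsAsFactors = FALSE)
  list(fixes = f, truth = truth)
}

# Uniformly sample a start time in the active or inactive part of a year.
sample_start_time <- function(year, status, cal) {
  for (i in 1:50) {
    day <- as.Date(sprintf("%d-01-01", year)) +
      floor(stats::runif(1, 0, 364))
    active <- is_measure_active(day, "SRA", cal)
    if ((status == "active") == active)
      return(as.POSIXct(paste(day, "00:00:00"), tz = "UTC") +
               round(stats::runif(1, 0, 86399)))
  }
  stop("could not sample a ", status, " start time in ", year)
}

#' Generate a synthetic AIS scenario
#'
#' Simulates every transit of the scenario through the water with tidal
#' currents, emission-rate bias and the configured compliance behaviour, and
#' returns the tables the ingest stage consumes plus a truth log with every
#' planted quantity.
#'
#' @param cfg A [scenario_config()].
#' @param zones A [zone_set()] (default [synthetic_zones()]).
#' @param current `NULL` (use the scenario's analytic tidal field), a
#'   current function, or a [current_field()] (interpolated; lets tests use
#'   the identical field for generation and recovery).
#' @return list: `fixes`, `vessels`, `pilots`, `truth` (per-transit planted
#'   values), `calendar`, `zones`, `cfg`.
#' @export
gen_transits <- function(cfg, zones = synthetic_zones(), current = NULL) {
  set.seed(cfg$seed)
  cal <- default_calendar(cfg$years)
  current_fn <- if (is.null(current)) synthetic_current_function(cfg)
    else if (inherits(current, "current_field"))
      function(lon, lat, t) current_at(current, lon, lat, t)
    else current
  plan <- cfg$n_transits
  n_total <- sum(plan$n)
  n_vessels <- max(3, round(n_total / 2.5))
  vessels <- data.frame(
    vessel_id = sprintf("V%04d", seq_len(n_vessels)),
    ship_class = sample(names(cfg$class_mix), n_vessels, TRUE, cfg$class_mix),
    flag = sample(names(cfg$flag_mix), n_vessels, TRUE, cfg$flag_mix),
    stringsAsFactors = FALSE)
  fixes <- list(); truths <- list(); pilots <- list()
  tid_n <- 0L
  for (r in seq_len(nrow(plan))) {
    yr <- plan$year[r]; st <- plan$status[r]
    for (j in seq_len(plan$n[r])) {
      tid_n <- tid_n + 1L
      tid <- sprintf("T%05d", tid_n)
      vid <- sample(vessels$vessel_id, 1)
      t0 <- sample_start_time(yr, st, cal)
      north <- stats::runif(1) < cfg$p_north
      route <- if (!north) "south"
        else if (stats::runif(1) < cfg$p_nga_cross) "north_nga" else "north"
      dirn <- if (stats::runif(1) < 0.5) "upstream" else "downstream"
      cruise <- max(4, stats::rnorm(1, cfg$speed_inactive["mean"],
                                    cfg$speed_inactive["sd"]))
      # ships slow down into the zone, never speed up to meet a target
      target <- if (st == "active") {
        if (stats::runif(1) < cfg$p_strict) min(cruise, stats::runif(1, 8.5, 9.7))
        else min(cruise, max(10.05, stats::rnorm(1, cfg$speed_active["mean"],
                                                 cfg$speed_active["sd"])))
      } else cruise
      sim <- simulate_transit(tid, vid, t0, route, dirn, cruise, target, cfg,
                              zones, current_fn)
      if (is.null(sim)) next
      fixes[[tid]] <- sim$fixes
      tr <- sim$truth
      tr$year <- yr; tr$status <- st
      tr$pilot_onboard <- stats::runif(1) < cfg$p_pilot
      truths[[tid]] <- tr
      pilots[[tid]] <- data.frame(vessel_id = vid,
                                  t_start = sim$fixes$t[1] - 600,
                                  t_end = sim$fixes$t[nrow(sim$fixes)] + 600,
                                  pilot_onboard = tr$pilot_onboard)
    }
  }
  list(fixes = do.call(rbind, c(fixes, list(make.row.names = FALSE))),
       vessels = vessels,
       pilots = do.call(rbind, c(pilots, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truths, list(make.row.names = FALSE))),
       calendar = cal, zones = zones, cfg = cfg)
}

#' Match ingested transits to the generator's truth log
#'
#' Joins on vessel id and first-fix time (within a tolerance), returning the
#' truth row index for each ingested transit (`NA` when unmatched).
#'
#' @param transits Transit table from [build_transits()].
#' @param truth Truth log from [gen_transits()].
#' @param tol_s Time tolerance, seconds.
#' @return Integer vector of row indices into `truth`.
#' @export
match_truth <- function(transits, truth, tol_s = 1) {
  vapply(seq_len(nrow(transits)), function(i) {
    j <- which(truth$vessel_id == transits$vessel_id[i] &
                 abs(as.numeric(truth$t_start) -
                       as.numeric(transits$t_start[i])) <= tol_s)
    if (length(j) == 1L) j else NA_integer_
  }, integer(1))
}

#' Simulate a transit-speed study for the active-measures design
#'
#' Draws per-transit DWAS directly from the planted mixed-model truth of the
#' first monitoring question: inactive baseline 14.1 kn, a fixed
#' active-measure shift (default -2.8 kn), a year random intercept and
#' residual noise. Used for parameter-recovery checks of
#' [fit_active_effect()].
#'
#' @param n_years Number of years (default 5).
#' @param per_year Transits per year (default 400).
#' @param intercept Inactive-period mean DWAS, kn.
#' @param active_effect Planted shift under active measures, kn.
#' @param resid_sd Residual s.d., kn (default 2.0).
#' @param year_sd Year-intercept s.d., kn (default 0.2).
#' @param seed Integer seed.
#' @return data.frame `dwas, active, year`.
#' @export
sim_speed_study <- function(n_years = 5, per_year = 400, intercept = 14.1,
                            active_effect = -2.8, resid_sd = 2.0,
                            year_sd = 0.2, seed = 1) {
  set.seed(seed)
  years <- 2012 + seq_len(n_years) - 1
  re <- stats::rnorm(n_years, 0, year_sd)
  rows <- lapply(seq_along(years), function(i) {
    active <- if (years[i] == years[1]) rep(FALSE, per_year)
      else stats::runif(per_year) < 0.5
    data.frame(dwas = intercept + re[i] + active_effect * active +
                 stats::rnorm(per_year, 0, resid_sd),
               active = active, year = years[i])
  })
  do.call(rbind, rows)
}

#' Simulate a transit-speed study for the covariate design
#'
#' Active-period transits with planted vessel-covariate effects on DWAS
#' (reference: tanker, Canadian flag, no pilot, upstream). Defaults plant
#' the pilotage and direction effects at -0.8 kn each.
#'
#' @param n Number of transits (default 2000).
#' @param intercept Reference-cell mean DWAS, kn.
#' @param pilot_effect,direction_effect,flag_effect Planted shifts, kn.
#' @param cargo_effect,passenger_effect Planted class shifts, kn.
#' @param p_pilot Pilot-onboard proportion (default 0.6).
#' @param resid_sd Residual s.d., kn (default 1.5).
#' @param year_sd Year-intercept s.d., kn.
#' @param years Years sampled uniformly.
#' @param seed Integer seed.
#' @return data.frame `dwas, year, ship_class, flag, pilot_onboard, direction`.
#' @export
sim_covariate_study <- function(n = 2000, intercept = 12.5,
                                pilot_effect = -0.8, direction_effect = -0.8,
                                flag_effect = -0.1, cargo_effect = 0.1,
                                passenger_effect = 0.2, p_pilot = 0.6,
                                resid_sd = 1.5, year_sd = 0.2,
                                years = 2014:2016, seed = 1) {
  set.seed(seed)
  re <- stats::setNames(stats::rnorm(length(years), 0, year_sd),
                        as.character(years))
  yr <- sample(years, n, TRUE)
  cls <- sample(c("tanker", "cargo", "passenger"), n, TRUE, c(0.3, 0.5, 0.2))
  flg <- sample(c("Canadian", "international"), n, TRUE, c(0.45, 0.55))
  pil <- stats::runif(n) < p_pilot
  dirn <- sample(c("upstream", "downstream"), n, TRUE)
  dwas <- intercept + re[as.character(yr)] +
    cargo_effect * (cls == "cargo") + passenger_effect * (cls == "passenger") +
    flag_effect * (flg == "international") + pilot_effect * pil +
    direction_effect * (dirn == "downstream") + stats::rnorm(n, 0, resid_sd)
  data.frame(dwas = unname(dwas), year = yr, ship_class = cls, flag = flg,
             pilot_onboard = pil, direction = dirn, stringsAsFactors = FALSE)
}

#' Monte-Carlo surrogate for slow-down-area risk reduction
#'
#' Draws before/after speeds from the printed per-period speed summaries
#' (normal, truncated at 0), weights them equally by distance under a
#' uniform density, and reports the percent reduction in mean lethality:
#' `100 * (1 - mean P(after) / mean P(before))`.
#'
#' @param m A [calibrate_lethality()] model.
#' @param n Draws per period (default 10000).
#' @param before,after Mean/sd (kn) of the two speed regimes.
#' @param seed Integer seed.
#' @return Percent reduction.
#' @export
surrogate_risk_reduction <- function(m = calibrate_lethality(), n = 10000,
                                     before = c(mean = 14.1, sd = 2.6),
                                     after = c(mean = 11.3, sd = 1.7),
                                     seed = 1) {
  set.seed(seed)
  rtnorm0 <- function(n, mu, sd) {
    x <- stats::rnorm(n, mu, sd)
    while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mu, sd)
    x
  }
  vb <- rtnorm0(n, before["mean"], before["sd"])
  va <- rtnorm0(n, after["mean"], after["sd"])
  100 * (1 - mean(lethality_probability(m, va)) /
           mean(lethality_probability(m, vb)))
}
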