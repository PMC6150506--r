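# Speed-lethality logistic, gridded co-occurrence risk mapping, before/after
# effectiveness, and the transit-time cost of slowing down.
#
# The lethality model is the standard logistic linking ship speed to the
# probability that a collision is lethal to the whale. Rather than copying
# published regression coefficients, the curve is calibrated from its two
# quoted operating points — about 31% lethality at the 10-knot limit and 50%
# at 11.8 knots — which pins down the unique two-parameter logistic.
# Risk in a cell is (relative whale density) x (lethality-weighted distance
# steamed); effectiveness is the percent reduction of summed risk over a
# region between a baseline and a measure-active period.

#' Calibrate the speed-lethality logistic from two anchor points
#'
#' Fits `P(v) = 1 / (1 + exp(-(b0 + b1 v)))` exactly through two (speed,
#' probability) anchors: `b1 = (logit p2 - logit p1) / (v2 - v1)`,
#' `b0 = logit p1 - b1 v1`.
#'
#' @param v1,p1 First anchor: speed (kn) and lethality probability in (0,1).
#'   Default 10 kn, 0.31.
#' @param v2,p2 Second anchor. Default 11.8 kn, 0.50.
#' @return Object of class `lethality_model` with fields `beta0`, `beta1`.
#' @export
calibrate_lethality <- function(v1 = 10, p1 = 0.31, v2 = 11.8, p2 = 0.50) {
  if (v1 == v2) stop("anchor speeds must differ")
  if (p1 == p2) stop("anchor probabilities must differ")
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  logit <- function(p) log(p / (1 - p))
  b1 <- (logit(p2) - logit(p1)) / (v2 - v1)
  if (b1 <= 0) stop("lethality must increase with speed (beta1 > 0)")
  structure(list(beta0 = logit(p1) - b1 * v1, beta1 = b1,
                 anchors = cbind(speed = c(v1, v2), p = c(p1, p2))),
            class = "lethality_model")
}

#' Lethality probability at given speeds
#'
#' @param m A [calibrate_lethality()] model.
#' @param v Speeds through water, knots (vectorised, >= 0).
#' @return Probabilities in (0, 1), strictly increasing in `v`.
#' @export
lethality_probability <- function(m, v) {
  stopifnot(inherits(m, "lethality_model"), all(v >= 0))
  stats::plogis(m$beta0 + m$beta1 * v)
}

#' @export
predict.lethality_model <- function(object, v, ...) {
  lethality_probability(object, v)
}

#' @export
print.lethality_model <- function(x, ...) {
  cat(sprintf("Speed-lethality logistic: logit P = %.4f + %.4f v\n",
              x$beta0, x$beta1))
  cat(sprintf("  P(10 kn) = %.3f,  P(11.8 kn) = %.3f\n",
              lethality_probability(x, 10), lethality_probability(x, 11.8)))
  invisible(x)
}

#' Whale relative-density surface
#'
#' @param values Matrix `[nrows, ncols]` of non-negative relative densities;
#'   normalised to sum to 1.
#' @param grid A [grid_spec()].
#' @param species Species label.
#' @return Object of class `whale_density`.
#' @export
whale_density <- function(values, grid, species = "unknown") {
  stopifnot(all(values >= 0), nrow(values) == grid$nrows,
            ncol(values) == grid$ncols, sum(values) > 0)
  structure(list(values = values / sum(values), grid = grid, species = species),
            class = "whale_density")
}

#' Read a density surface from CSV
#'
#' Columns `row, col, value`, grid metadata in `# key: value` header comments
#' as in [read_current_csv()], plus `# species: name`.
#'
#' @param path CSV path.
#' @return A [whale_density()].
#' @export
read_density_csv <- function(path) {
  hdr <- readLines(path, n = 20)
  meta <- list(); species <- "unknown"
  for (ln in hdr[startsWith(hdr, "#")]) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (kv[1] == "species") species <- kv[2] else meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  grid <- grid_spec(meta$origin_x, meta$origin_y, meta$cell_size, meta$nrows,
                    meta$ncols, local_projection(meta$lon0, meta$lat0))
  vals <- matrix(0, grid$nrows, grid$ncols)
  vals[cbind(df$row, df$col)] <- df$value
  whale_density(vals, grid, species)
}

#' Write a density surface to CSV
#'
#' @param dens A [whale_density()].
#' @param path Output path.
#' @export
write_density_csv <- function(dens, path) {
  g <- dens$grid
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# species: %s", dens$species),
               sprintf("# origin_x: %.6f", g$origin_x),
               sprintf("# origin_y: %.6f", g$origin_y),
               sprintf("# cell_size: %.6f", g$cell_size),
               sprintf("# nrows: %d", g$nrows), sprintf("# ncols: %d", g$ncols),
               sprintf("# lon0: %.8f", g$projection$lon0),
               sprintf("# lat0: %.8f", g$projection$lat0)), con)
  idx <- which(dens$values != 0, arr.ind = TRUE)
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2],
                              value = dens$values[idx]), con, row.names = FALSE)
}

# Split one planar segment across grid cells. Returns data.frame(row, col,
# fraction) with fractions of segment length per crossed cell.
segment_cell_fractions <- function(p1, p2, grid) {
  d <- p2 - p1
  ts <- c(0, 1)
  cs <- grid$cell_size
  for (ax in 1:2) {
    if (abs(d[ax]) == 0) next
    # grid lines are at k * cs relative to the grid origin
    o <- if (ax == 1) grid$origin_x else grid$origin_y
    k0 <- ceiling((min(p1[ax], p2[ax]) - o) / cs)
    k1 <- floor((max(p1[ax], p2[ax]) - o) / cs)
    if (k0 > k1) next
    ks <- k0:k1
    ts <- c(ts, (o + ks * cs - p1[ax]) / d[ax])
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  dt <- diff(ts)
  keep <- dt > 1e-12
  mid <- ((ts[-length(ts)] + ts[-1]) / 2)[keep]
  rc <- cell_of(p1[1] + mid * d[1], p1[2] + mid * d[2], grid)
  data.frame(row = rc[, 1], col = rc[, 2], fraction = dt[keep])
}

#' Accumulate traffic and lethality-weighted distance on a grid
#'
#' Each transit segment is split across the grid cells it crosses; every
#' cell accumulates the distance steamed in it and that distance weighted by
#' the lethality probability of the segment speed. Speed through water is
#' the default basis (the encounter speed); speed over ground is available
#' for sensitivity runs.
#'
#' @param seg_by_transit Named list of segment tables ([segmentize()]).
#' @param grid A [grid_spec()] (shares the projection with all geometry).
#' @param m A [calibrate_lethality()] model.
#' @param speed_basis `"stw"` (segment `speed`) or `"sog"` (`speed_ltd`).
#' @return Object of class `traffic_surface`: list with matrices
#'   `distance_nm`, `weighted_nm`, integer `n_transits`, `grid`, and a `log`
#'   of skipped out-of-grid segments.
#' @export
traffic_surface <- function(seg_by_transit, grid, m,
                            speed_basis = c("stw", "sog")) {
  speed_basis <- match.arg(speed_basis)
  dist <- wt <- matrix(0, grid$nrows, grid$ncols)
  log <- character()
  proj <- grid$projection
  for (tid in names(seg_by_transit)) {
    seg <- seg_by_transit[[tid]]
    v <- if (speed_basis == "stw") seg$speed else seg$speed_ltd
    p1 <- proj$forward(seg$lon1, seg$lat1)
    p2 <- proj$forward(seg$lon2, seg$lat2)
    for (i in seq_len(nrow(seg))) {
      if (seg$length_nm[i] <= 0) next
      fr <- segment_cell_fractions(p1[i, ], p2[i, ], grid)
      out <- is.na(fr$row)
      if (any(out)) {
        log <- c(log, sprintf("transit %s segment %d: %.1f%% outside grid, skipped",
                              tid, i, 100 * sum(fr$fraction[out])))
        fr <- fr[!out, ]
      }
      if (!nrow(fr)) next
      # accumulate with duplicate cells merged (m[idx] <- m[idx] + x drops
      # repeated indices)
      agg <- rowsum(fr$fraction, paste(fr$row, fr$col))
      rc <- do.call(rbind, strsplit(rownames(agg), " "))
      idx <- cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))
      dl <- seg$length_nm[i] * agg[, 1]
      pv <- lethality_probability(m, max(v[i], 0))
      dist[idx] <- dist[idx] + dl
      wt[idx] <- wt[idx] + dl * pv
    }
  }
  structure(list(distance_nm = dist, weighted_nm = wt,
                 n_transits = length(seg_by_transit), grid = grid, log = log),
            class = "traffic_surface")
}

#' @export
print.traffic_surface <- function(x, ...) {
  cat(sprintf("<traffic_surface> %d transits, %.1f nm on %d x %d cells\n",
              x$n_transits, sum(x$distance_nm), x$grid$nrows, x$grid$ncols))
  invisible(x)
}

#' Per-cell lethal-collision risk map
#'
#' Cell risk is the pointwise product of the relative whale density and the
#' lethality-weighted distance. With `normalize_per_transit`, the traffic
#' term is divided by the number of transits so periods with different
#' traffic volumes are comparable (relative risk per transit).
#'
#' @param traffic A [traffic_surface()].
#' @param density A [whale_density()] on the same grid.
#' @param normalize_per_transit Logical (default TRUE).
#' @return Matrix of per-cell risk (class `risk_map` with `grid` attribute).
#' @export
risk_map <- function(traffic, density, normalize_per_transit = TRUE) {
  g1 <- traffic$grid; g2 <- density$grid
  if (g1$nrows != g2$nrows || g1$ncols != g2$ncols ||
      g1$cell_size != g2$cell_size)
    stop("traffic and density grids do not match")
  r <- density$values * traffic$weighted_nm
  if (normalize_per_transit) {
    if (traffic$n_transits == 0) stop("no transits in traffic surface")
    r <- r / traffic$n_transits
  }
  structure(r, grid = g1, class = c("risk_map", class(r)))
}

#' Percent risk reduction between two periods
#'
#' `100 * (1 - sum(after) / sum(before))` over the cells whose centres fall
#' in `region`. Invariant to any global rescaling of the density surface.
#'
#' @param before,after Risk maps from [risk_map()] on the same grid.
#' @param region Lon/lat polygon, or `NULL` for the whole grid.
#' @return Percent reduction (positive = risk decreased).
#' @export
effectiveness <- function(before, after, region = NULL) {
  grid <- attr(before, "grid")
  sel <- matrix(TRUE, grid$nrows, grid$ncols)
  if (!is.null(region)) {
    poly <- project_poly(close_ring(region), grid$projection)
    idx <- expand.grid(row = seq_len(grid$nrows), col = seq_len(grid$ncols))
    ctr <- cell_center(idx$row, idx$col, grid)
    sel[cbind(idx$row, idx$col)] <- point_in_polygon(ctr[, 1], ctr[, 2], poly)
  }
  tot_before <- sum(before[sel])
  if (tot_before <= 0) stop("zero baseline risk in region; reduction undefined")
  100 * (1 - sum(after[sel]) / tot_before)
}

#' Gate-to-gate transit times
#'
#' Elapsed minutes between the first crossings of two reference transects,
#' with each crossing instant interpolated linearly in time between the
#' straddling fixes. Transits missing either crossing are excluded and
#' logged.
#'
#' @param seg_by_transit Named list of segment tables.
#' @param transits Transit table (for direction/status grouping).
#' @param zones A [zone_set()]; gates `gate_esc` and `gate_sts` are used.
#' @return list: `per_transit` (data.frame `transit_id, direction, status,
#'   minutes`), `summary` (mean minutes by direction x status), `log`.
#' @export
transit_time_stats <- function(seg_by_transit, transits, zones) {
  proj <- zones$projection
  ga <- project_poly(zones$gate_esc, proj)
  gb <- project_poly(zones$gate_sts, proj)
  rows <- list(); log <- character()
  for (tid in names(seg_by_transit)) {
    seg <- seg_by_transit[[tid]]
    path <- rbind(proj$forward(seg$lon1, seg$lat1),
                  proj$forward(seg$lon2[nrow(seg)], seg$lat2[nrow(seg)]))
    xa <- path_gate_crossing(path, ga)
    xb <- path_gate_crossing(path, gb)
    if (is.null(xa) || is.null(xb)) {
      log <- c(log, sprintf("transit %s: missing a gate crossing, excluded", tid))
      next
    }
    t_of <- function(x) {
      as.numeric(seg$t1[x$seg]) +
        x$t * (as.numeric(seg$t2[x$seg]) - as.numeric(seg$t1[x$seg]))
    }
    i <- which(transits$transit_id == tid)
    rows[[tid]] <- data.frame(
      transit_id = tid,
      direction = if (length(i)) transits$direction[i] else NA_character_,
      status = if (length(i) && isTRUE(transits$measures_active[i]))
        "active" else "inactive",
      minutes = abs(t_of(xa) - t_of(xb)) / 60, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  smry <- if (!is.null(per))
    stats::aggregate(minutes ~ direction + status, per, mean) else NULL
  list(per_transit = per, summary = smry, log = log)
}
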