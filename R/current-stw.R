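# Surface-current interpolation and speed-over-ground -> speed-through-water
# conversion. The current field mirrors the operational product used for the
# slow-down zone: a regular grid (400 m in production, coarser in tests),
# hourly snapshots, values interpolated bilinearly in space and linearly in
# time. The stated uncertainty budget of the operational conversion is about
# 0.7 kn, dominated by the current model itself.

#' Gridded surface-current field
#'
#' @param u,v Arrays `[time, nrow, ncol]` of eastward/northward current (m/s).
#' @param times POSIXct snapshot times, uniform hourly spacing.
#' @param grid A [grid_spec()] describing the cell layout (values are taken
#'   at cell centres).
#' @return Object of class `current_field`.
#' @export
current_field <- function(u, v, times, grid) {
  stopifnot(length(dim(u)) == 3, identical(dim(u), dim(v)),
            dim(u)[1] == length(times), dim(u)[2] == grid$nrows,
            dim(u)[3] == grid$ncols)
  if (length(times) > 1) {
    dt <- diff(as.numeric(times))
    if (any(abs(dt - 3600) > 1e-6)) stop("time steps must be uniform at 3600 s")
  }
  if (max(abs(u), abs(v)) > 5) stop("|current| exceeds 5 m/s; implausible field")
  structure(list(u = u, v = v, times = times, grid = grid),
            class = "current_field")
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf("<current_field> %d hourly snapshots on %d x %d cells (%.0f m)\n",
              length(x$times), x$grid$nrows, x$grid$ncols, x$grid$cell_size))
  invisible(x)
}

# Bilinear interpolation among cell centres for one snapshot matrix [nrow, ncol].
bilinear_cells <- function(mat, gx, gy, grid) {
  # fractional cell-centre coordinates
  fc <- (gx - grid$origin_x) / grid$cell_size + 0.5
  fr <- (gy - grid$origin_y) / grid$cell_size + 0.5
  c0 <- pmin(pmax(floor(fc), 1), grid$ncols - 1L)
  r0 <- pmin(pmax(floor(fr), 1), grid$nrows - 1L)
  wx <- pmin(pmax(fc - c0, 0), 1)
  wy <- pmin(pmax(fr - r0, 0), 1)
  v00 <- mat[cbind(r0, c0)];       v01 <- mat[cbind(r0, c0 + 1L)]
  v10 <- mat[cbind(r0 + 1L, c0)];  v11 <- mat[cbind(r0 + 1L, c0 + 1L)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

#' Interpolate the current at points and times
#'
#' Bilinear in space between cell centres, linear in time between hourly
#' snapshots; result converted from m/s to knots.
#'
#' @param field A [current_field()].
#' @param lon,lat Positions (degrees), vectorised.
#' @param t POSIXct times, recycled against positions.
#' @return data.frame with columns `u`, `v` in knots.
#' @export
current_at <- function(field, lon, lat, t) {
  grid <- field$grid
  n <- max(length(lon), length(t))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  tt <- rep_len(as.numeric(t), n)
  xy <- grid$projection$forward(lon, lat)
  xmin <- grid$origin_x; xmax <- grid$origin_x + grid$ncols * grid$cell_size
  ymin <- grid$origin_y; ymax <- grid$origin_y + grid$nrows * grid$cell_size
  if (any(xy[, 1] < xmin | xy[, 1] > xmax | xy[, 2] < ymin | xy[, 2] > ymax))
    stop("position outside current-field extent [",
         round(xmin), ", ", round(xmax), "] x [", round(ymin), ", ", round(ymax), "] m")
  t0 <- as.numeric(field$times[1]); t1 <- as.numeric(field$times[length(field$times)])
  if (any(tt < t0 - 1e-6 | tt > t1 + 1e-6))
    stop("time outside current-field range [", format(field$times[1]), ", ",
         format(field$times[length(field$times)]), "]")
  fi <- pmin(pmax((tt - t0) / 3600, 0), length(field$times) - 1L)
  i0 <- pmin(floor(fi) + 1L, length(field$times) - 1L)
  if (length(field$times) == 1L) { i0 <- rep(1L, n); w <- rep(0, n) } else {
    w <- fi - (i0 - 1L)
  }
  u <- v <- numeric(n)
  for (idx in unique(i0)) {
    sel <- i0 == idx
    u0 <- bilinear_cells(field$u[idx, , , drop = TRUE], xy[sel, 1], xy[sel, 2], grid)
    v0 <- bilinear_cells(field$v[idx, , , drop = TRUE], xy[sel, 1], xy[sel, 2], grid)
    if (length(field$times) > 1L) {
      u1 <- bilinear_cells(field$u[idx + 1L, , , drop = TRUE], xy[sel, 1], xy[sel, 2], grid)
      v1 <- bilinear_cells(field$v[idx + 1L, , , drop = TRUE], xy[sel, 1], xy[sel, 2], grid)
    } else { u1 <- u0; v1 <- v0 }
    u[sel] <- (1 - w[sel]) * u0 + w[sel] * u1
    v[sel] <- (1 - w[sel]) * v0 + w[sel] * v1
  }
  data.frame(u = u / MS_PER_KN, v = v / MS_PER_KN)
}

#' Convert speed over ground to speed through water
#'
#' The ground-velocity vector is reconstructed from SOG and course over
#' ground, the current vector subtracted, and the water-speed magnitude
#' returned: `stw = |(sog sin cog, sog cos cog) - (u, v)|`. Course over
#' ground stands in for heading, so leeway/crab angle is attributed to the
#' water speed — the convention of the operational conversion module.
#'
#' @param sog Speed over ground, knots.
#' @param cog Course over ground, degrees true.
#' @param u,v Current components, knots.
#' @return Speed through water, knots (vectorised).
#' @export
sog_to_stw <- function(sog, cog, u, v) {
  stopifnot(all(sog >= 0))
  rad <- pi / 180
  gx <- sog * sin(cog * rad)
  gy <- sog * cos(cog * rad)
  sqrt((gx - u)^2 + (gy - v)^2)
}

#' Fill speed through water on a fix table
#'
#' @param fixes AIS fix data.frame (`lon`, `lat`, `t`, `sog`, `cog`).
#' @param current One of: a [current_field()]; a function
#'   `(lon, lat, t) -> data.frame(u, v)` in knots; or `NULL` for zero current
#'   (then `stw == sog`).
#' @return `fixes` with an `stw` column.
#' @export
add_stw <- function(fixes, current = NULL) {
  if (nrow(fixes) == 0) { fixes$stw <- numeric(0); return(fixes) }
  if (is.null(current)) {
    uv <- data.frame(u = 0, v = 0)
  } else if (inherits(current, "current_field")) {
    uv <- current_at(current, fixes$lon, fixes$lat, fixes$t)
  } else if (is.function(current)) {
    uv <- current(fixes$lon, fixes$lat, fixes$t)
  } else stop("unsupported current specification")
  fixes$stw <- sog_to_stw(fixes$sog, fixes$cog, uv$u, uv$v)
  fixes
}

#' Read a current field from long-format CSV
#'
#' Plain-text interchange format: one row per (time, row, col) with columns
#' `time` (ISO 8601 UTC), `row`, `col`, `u_ms`, `v_ms`, plus grid metadata in
#' `# key: value` header comments (`origin_x`, `origin_y`, `cell_size`,
#' `nrows`, `ncols`, `lon0`, `lat0`).
#'
#' @param path CSV path.
#' @return A [current_field()].
#' @export
read_current_csv <- function(path) {
  hdr <- readLines(path, n = 20)
  meta <- list()
  for (ln in hdr[startsWith(hdr, "#")]) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df_t <- as.POSIXct(df$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  times <- sort(unique(df_t))
  proj <- local_projection(meta$lon0, meta$lat0)
  grid <- grid_spec(meta$origin_x, meta$origin_y, meta$cell_size,
                    meta$nrows, meta$ncols, proj)
  u <- v <- array(0, c(length(times), grid$nrows, grid$ncols))
  ti <- match(df_t, times)
  u[cbind(ti, df$row, df$col)] <- df$u_ms
  v[cbind(ti, df$row, df$col)] <- df$v_ms
  current_field(u, v, times, grid)
}

#' Write a current field to long-format CSV
#'
#' @param field A [current_field()].
#' @param path Output path.
#' @export
write_current_csv <- function(field, path) {
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin_x: %.6f", g$origin_x),
               sprintf("# origin_y: %.6f", g$origin_y),
               sprintf("# cell_size: %.6f", g$cell_size),
               sprintf("# nrows: %d", g$nrows), sprintf("# ncols: %d", g$ncols),
               sprintf("# lon0: %.8f", g$projection$lon0),
               sprintf("# lat0: %.8f", g$projection$lat0)), con)
  idx <- expand.grid(row = seq_len(g$nrows), col = seq_len(g$ncols),
                     ti = seq_along(field$times))
  df <- data.frame(time = format(field$times[idx$ti], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   row = idx$row, col = idx$col,
                   u_ms = field$u[cbind(idx$ti, idx$row, idx$col)],
                   v_ms = field$v[cbind(idx$ti, idx$row, idx$col)])
  utils::write.csv(df, con, row.names = FALSE)
}
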