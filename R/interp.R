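#' Interpolate bottom velocity at positions and times
#'
#' Bilinear interpolation in space with wet-cell-only weight renormalization
#' (land corners contribute zero weight), and linear interpolation in time
#' between the bracketing snapshots. This is the velocity sampler used by the
#' particle tracker's Runge-Kutta stages.
#'
#' @param fields a [field_series()].
#' @param x,y position(s) in metres (vectorized).
#' @param time a `POSIXct` (or numeric seconds matching the series' time
#'   axis); a single time shared by all positions.
#' @return A list with numeric vectors `u` and `v` (m/s).
#'   Signals `"out of range"` if `time` lies outside the series span and
#'   `"out of water"` if a position is outside the domain or surrounded by
#'   land on all four grid corners.
#' @export
interp_velocity <- function(fields, x, y, time) {
  pre <- fields_precompute(fields)
  tnum <- as.numeric(time)
  if (tnum < pre$times[1] || tnum > pre$times[pre$nt]) {
    stop("interp_velocity: time out of range", call. = FALSE)
  }
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  if (any(x < pre$gx[1] | x > pre$gx[pre$nx] |
          y < pre$gy[1] | y > pre$gy[pre$ny])) {
    stop("interp_velocity: position out of water (outside domain)", call. = FALSE)
  }
  res <- interp_uv(pre, x, y, tnum)
  if (any(res$w0 == 0)) {
    stop("interp_velocity: position out of water (all neighbouring cells are land)",
         call. = FALSE)
  }
  list(u = res$u, v = res$v)
}

# Precompute flat arrays for fast repeated interpolation. Cached on the
# field_series via an environment attribute so advect() pays the cost once.
fields_precompute <- function(fields) {
  cache <- attr(fields, "precomputed")
  if (!is.null(cache)) return(cache)
  grid <- fields$grid
  wet <- !grid$land
  u0 <- fields$u; v0 <- fields$v
  u0[is.na(u0)] <- 0; v0[is.na(v0)] <- 0
  pre <- list(gx = grid$x, gy = grid$y,
              nx = length(grid$x), ny = length(grid$y),
              nt = length(fields$time),
              times = as.numeric(fields$time),
              wet = as.numeric(wet),        # flat [nx*ny]
              u = u0, v = v0,               # [nx, ny, nt], zeros on land
              depth = grid$depth,
              periodic_y = grid$periodic_y)
  pre
}

# Vectorized masked bilinear + linear-in-time sampler.
# Returns u, v and w0 (the spatial wet-weight total; 0 means all-land).
interp_uv <- function(pre, x, y, tnum) {
  nx <- pre$nx; ny <- pre$ny
  it <- findInterval(tnum, pre$times)
  it <- min(max(it, 1L), pre$nt - 1L)
  ft <- (tnum - pre$times[it]) / (pre$times[it + 1L] - pre$times[it])

  ix <- findInterval(x, pre$gx, rightmost.closed = TRUE)
  iy <- findInterval(y, pre$gy, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nx - 1L)
  iy <- pmin(pmax(iy, 1L), ny - 1L)
  fx <- (x - pre$gx[ix]) / (pre$gx[ix + 1L] - pre$gx[ix])
  fy <- (y - pre$gy[iy]) / (pre$gy[iy + 1L] - pre$gy[iy])

  i00 <- ix + (iy - 1L) * nx
  i10 <- i00 + 1L
  i01 <- i00 + nx
  i11 <- i01 + 1L
  w00 <- (1 - fx) * (1 - fy) * pre$wet[i00]
  w10 <- fx * (1 - fy) * pre$wet[i10]
  w01 <- (1 - fx) * fy * pre$wet[i01]
  w11 <- fx * fy * pre$wet[i11]
  w0 <- w00 + w10 + w01 + w11

  off1 <- (it - 1L) * nx * ny
  off2 <- it * nx * ny
  blend <- function(a) {
    s1 <- w00 * a[off1 + i00] + w10 * a[off1 + i10] +
          w01 * a[off1 + i01] + w11 * a[off1 + i11]
    s2 <- w00 * a[off2 + i00] + w10 * a[off2 + i10] +
          w01 * a[off2 + i01] + w11 * a[off2 + i11]
    ((1 - ft) * s1 + ft * s2) / w0
  }
  u <- blend(pre$u); v <- blend(pre$v)
  u[w0 == 0] <- NA_real_; v[w0 == 0] <- NA_real_
  list(u = u, v = v, w0 = w0)
}

#' Cross-shore transect of bottom density
#'
#' Samples every wet cell from the coast out to (but not including) the
#' shelf-edge contour along the cross-shore grid row nearest to
#' `y_along`, at the snapshot nearest to `time`. The returned distances are
#' the grid's offshore node coordinates, i.e. grid spacing times node index.
#'
#' @param fields a [field_series()].
#' @param bathy a [bathymetry_grid()] (normally `fields$grid`).
#' @param y_along alongshore position (m).
#' @param time `POSIXct` within the series span.
#' @param edge_depth depth (m) defining the shelf edge; default 200.
#' @return data.frame with columns `distance` (m from coast), `rho`
#'   (kg/m^3) and `depth` (m).
#' @export
cross_shore_transect <- function(fields, bathy, y_along, time, edge_depth = 200) {
  j <- which.min(abs(bathy$y - y_along))
  k <- which.min(abs(as.numeric(fields$time) - as.numeric(time)))
  sel <- !bathy$land[, j] & bathy$depth[, j] < edge_depth & bathy$depth[, j] > 0
  if (!any(sel)) stop("cross_shore_transect: row is fully land", call. = FALSE)
  data.frame(distance = bathy$x[sel],
             rho = fields$rho_bottom[sel, j, k],
             depth = bathy$depth[sel, j])
}
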