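#' Bathymetry grid
#'
#' A rectilinear raster of seabed depth with a land mask. Node coordinates are
#' metres in the scenario frame (x positive offshore from the coast at x = 0).
#' Depth is metres below datum (non-negative on wet cells).
#'
#' @param x,y strictly increasing node coordinate vectors (m).
#' @param depth `length(x) x length(y)` matrix of depths (m).
#' @param land logical matrix of the same shape; `TRUE` marks land.
#' @param periodic_y should the alongshore axis be treated as periodic
#'   (idealized channel)? Used by the particle tracker.
#' @return An object of class `bathymetry_grid`.
#' @export
bathymetry_grid <- function(x, y, depth, land = NULL, periodic_y = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2 || any(diff(x) <= 0) || any(diff(y) <= 0)) {
    stop("bathymetry_grid: node coordinates must be strictly increasing", call. = FALSE)
  }
  depth <- as.matrix(depth)
  if (!all(dim(depth) == c(length(x), length(y)))) {
    stop("bathymetry_grid: depth must be length(x) x length(y)", call. = FALSE)
  }
  if (is.null(land)) land <- matrix(FALSE, length(x), length(y))
  land <- matrix(as.logical(land), length(x), length(y))
  if (any(depth[!land] < 0)) {
    stop("bathymetry_grid: wet-cell depth must be non-negative", call. = FALSE)
  }
  structure(list(x = x, y = y, depth = depth, land = land,
                 periodic_y = isTRUE(periodic_y)),
            class = "bathymetry_grid")
}

#' @export
print.bathymetry_grid <- function(x, ...) {
  cat(sprintf("<bathymetry_grid> %d x %d nodes, depth %.0f..%.0f m, %d land cells\n",
              length(x$x), length(x$y), min(x$depth), max(x$depth), sum(x$land)))
  invisible(x)
}

#' Closed-form cross-shore depth profile
#'
#' Piecewise-linear depth as a function of offshore distance: 0 at the coast,
#' `depth_inner` at `x_inner`, `depth_edge` at `x_edge` (the shelf-edge
#' contour), and `depth_max` at the offshore boundary `Lx`. This is the single
#' source of truth for the synthetic bathymetry; [make_bathymetry()] evaluates
#' it at the grid nodes.
#'
#' @param x offshore distance(s) in metres.
#' @param cfg a [shelf_config()].
#' @return depth in metres (vectorized over `x`).
#' @export
shelf_depth_profile <- function(x, cfg) {
  validate_shelf_config(cfg)
  stats::approx(x = c(0, cfg$x_inner, cfg$x_edge, cfg$Lx),
                y = c(0, cfg$depth_inner, cfg$depth_edge, cfg$depth_max),
                xout = pmin(pmax(x, 0), cfg$Lx))$y
}

#' Generate the synthetic shelf bathymetry
#'
#' Evaluates [shelf_depth_profile()] on a rectilinear grid with spacing
#' `cfg$dx`. The coast column (x = 0) is land; depth increases monotonically
#' offshore, reaching exactly `depth_edge` at `x_edge` and `depth_max` at the
#' offshore boundary. The alongshore axis is periodic.
#'
#' @param cfg a [shelf_config()].
#' @return A [bathymetry_grid()].
#' @export
make_bathymetry <- function(cfg) {
  validate_shelf_config(cfg)
  x <- seq(0, cfg$Lx, by = cfg$dx)
  y <- seq(0, cfg$Ly, by = cfg$dx)
  depth <- matrix(shelf_depth_profile(x, cfg), length(x), length(y))
  land <- depth <= 0
  bathymetry_grid(x, y, depth, land, periodic_y = TRUE)
}

#' Interpolate depth at arbitrary positions
#'
#' Bilinear interpolation of the bathymetry raster. Used for shelf-edge
#' crossing detection: a particle has crossed the `level` contour when the
#' interpolated depth at its position first reaches `level`.
#'
#' @param bathy a [bathymetry_grid()].
#' @param x,y position(s) in metres (vectorized; recycled to common length).
#' @return depth in metres; positions outside the domain signal an error.
#' @export
depth_at <- function(bathy, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  out <- (x < bathy$x[1] | x > bathy$x[length(bathy$x)] |
          y < bathy$y[1] | y > bathy$y[length(bathy$y)])
  if (any(out & !is.na(x) & !is.na(y))) {
    stop("depth_at: position outside domain", call. = FALSE)
  }
  bilinear_eval(bathy$x, bathy$y, bathy$depth, x, y)
}

# plain bilinear interpolation of a node raster (no masking);
# assumes positions already inside the domain. NA positions give NA.
bilinear_eval <- function(gx, gy, z, x, y) {
  nx <- length(gx); ny <- length(gy)
  ix <- findInterval(x, gx, rightmost.closed = TRUE)
  iy <- findInterval(y, gy, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nx - 1L)
  iy <- pmin(pmax(iy, 1L), ny - 1L)
  fx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fy <- (y - gy[iy]) / (gy[iy + 1L] - gy[iy])
  i00 <- ix + (iy - 1L) * nx
  z00 <- z[i00]; z10 <- z[i00 + 1L]
  z01 <- z[i00 + nx]; z11 <- z[i00 + nx + 1L]
  (1 - fx) * (1 - fy) * z00 + fx * (1 - fy) * z10 +
    (1 - fx) * fy * z01 + fx * fy * z11
}

#' Kelp occurrence probability raster
#'
#' Probability of kelp presence per grid cell: an exponential decline with
#' depth (`exp(-depth / kelp_decline_scale)`), truncated to zero on land and
#' beyond the configured depth limit (default 50 m, the deepest reefs that
#' support kelp).
#'
#' @param bathy a [bathymetry_grid()].
#' @param cfg a [shelf_config()].
#' @return A matrix (same shape as `bathy$depth`) with values in `[0, 1]`.
#' @export
make_kelp_probability <- function(bathy, cfg) {
  validate_shelf_config(cfg)
  p <- exp(-bathy$depth / cfg$kelp_decline_scale)
  p[bathy$land] <- 0
  p[bathy$depth > cfg$kelp_depth_limit] <- 0
  p
}
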