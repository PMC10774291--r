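# Shared fixtures: analytic field series on all-wet grids, tiny scenario
# configurations, and hand-built trajectory sets with known crossing ages.

# all-wet rectilinear grid with a depth raster supplied as a function of (x, y)
wet_grid <- function(Lx = 10e3, Ly = 10e3, dx = 1e3,
                     depth_fun = function(x, y) 50 + 0 * x,
                     periodic_y = FALSE) {
  x <- seq(0, Lx, by = dx)
  y <- seq(0, Ly, by = dx)
  depth <- outer(x, y, depth_fun)
  bathymetry_grid(x, y, depth, land = matrix(FALSE, length(x), length(y)),
                  periodic_y = periodic_y)
}

# field series from velocity functions of (x, y, time-index); two or more
# snapshots, constant density/wind
analytic_fields <- function(grid, u_fun, v_fun = function(x, y, k) 0 * x,
                            times = as.POSIXct("2017-06-01", tz = "UTC") +
                              c(0, 86400 * 30)) {
  nx <- length(grid$x); ny <- length(grid$y); nt <- length(times)
  u <- array(0, c(nx, ny, nt)); v <- array(0, c(nx, ny, nt))
  for (k in seq_len(nt)) {
    u[, , k] <- outer(grid$x, grid$y, function(x, y) u_fun(x, y, k))
    v[, , k] <- outer(grid$x, grid$y, function(x, y) v_fun(x, y, k))
  }
  rho <- array(1025, c(nx, ny, nt))
  field_series(times, u, v, rho, rho,
               wind_speed = rep(5, nt), wind_dir = rep(180, nt), grid = grid)
}

# small, fast scenario: four months spanning a transition and the cold season
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(start = "2017-04-01", end = "2017-07-31",
                                 seed = 7L), list(...))
  do.call(shelf_config, args)
}

# hand-built trajectory set: particles sit at given offshore distances per
# record on a linear-depth ramp (depth = slope * x), so crossing ages are
# dictated exactly by the supplied position matrix
fabricated_traj <- function(x_records, release_times, record_times,
                            slope = 200 / 86400, Lx = 2e6,
                            cell_i = NULL, cell_j = NULL,
                            fate = NULL) {
  n <- nrow(x_records)
  grid <- bathymetry_grid(x = c(0, Lx), y = c(0, 1e4),
                          depth = matrix(c(0, slope * Lx), 2, 2),
                          land = matrix(FALSE, 2, 2))
  y_records <- matrix(5e3, n, ncol(x_records))
  y_records[is.na(x_records)] <- NA
  if (is.null(cell_i)) cell_i <- rep(1L, n)
  if (is.null(cell_j)) cell_j <- rep(1L, n)
  if (is.null(fate)) fate <- rep("active", n)
  last <- apply(x_records, 1, function(r) max(which(!is.na(r))))
  structure(list(
    time = record_times,
    x = x_records, y = y_records,
    release = data.frame(date = as.Date(release_times),
                         x0 = x_records[cbind(seq_len(n), 1L)],
                         y0 = rep(5e3, n),
                         cell_i = cell_i, cell_j = cell_j,
                         t_release = release_times),
    fate = fate,
    fate_time = record_times[last],
    fate_x = x_records[cbind(seq_len(n), last)],
    fate_y = rep(5e3, n),
    options = tracker_options(),
    grid = grid), class = "trajectory_set")
}

# cache for the shared full-year acceptance run (built lazily, reused by the
# end-to-end acceptance blocks)
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function() {
  if (is.null(.acceptance_cache$run)) {
    .acceptance_cache$run <- run_pipeline(n_particles = 10000, seed = 42L,
                                          verbose = FALSE)
  }
  .acceptance_cache$run
}
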