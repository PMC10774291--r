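test_that("NetCDF scenario files round-trip bit-identically", {
  cfg <- shelf_config(start = "2017-05-01", end = "2017-05-10", seed = 3L)
  b <- make_bathymetry(cfg)
  f <- make_forcing(cfg, b)
  kelp <- make_kelp_probability(b, cfg)
  path <- withr::local_tempfile(fileext = ".nc")
  write_fields_nc(f, path, kelp_prob = kelp)
  f2 <- load_fields(path)
  expect_identical(f2$u, f$u)
  expect_identical(f2$v, f$v)
  expect_identical(f2$rho_bottom, f$rho_bottom)
  expect_identical(f2$rho_surface, f$rho_surface)
  expect_identical(f2$wind_speed, f$wind_speed)
  expect_identical(as.numeric(f2$time), as.numeric(f$time))
  expect_identical(f2$grid$depth, b$depth)
  expect_identical(f2$grid$land, b$land)
  expect_true(f2$grid$periodic_y)
  expect_identical(attr(f2, "kelp_prob"), kelp)
})

test_that("validation failures name the offending variable", {
  # build a file lacking v_bottom
  path <- withr::local_tempfile(fileext = ".nc")
  dx <- ncdf4::ncdim_def("x", "m", c(0, 1000))
  dy <- ncdf4::ncdim_def("y", "m", c(0, 1000))
  dt <- ncdf4::ncdim_def("time", "hours since 2017-01-01 00:00:00 UTC", c(0, 3))
  v3 <- list(dx, dy, dt)
  vars <- list(ncdf4::ncvar_def("depth", "m", list(dx, dy), prec = "double"),
               ncdf4::ncvar_def("land_mask", "1", list(dx, dy), prec = "integer"),
               ncdf4::ncvar_def("u_bottom", "m s-1", v3, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  ncdf4::ncvar_put(nc, "depth", matrix(50, 2, 2))
  ncdf4::ncvar_put(nc, "land_mask", matrix(0L, 2, 2))
  ncdf4::ncvar_put(nc, "u_bottom", array(0.1, c(2, 2, 2)))
  ncdf4::nc_close(nc)
  expect_error(load_fields(path), "v_bottom")
})

test_that("sigma-layer velocity files reduce to the deepest layer", {
  path <- withr::local_tempfile(fileext = ".nc")
  nx <- 3; ny <- 2; nt <- 2; nl <- 3
  dx <- ncdf4::ncdim_def("x", "m", seq(0, 2000, by = 1000))
  dy <- ncdf4::ncdim_def("y", "m", c(0, 1000))
  dl <- ncdf4::ncdim_def("layer", "1", seq_len(nl))
  dt <- ncdf4::ncdim_def("time", "hours since 2017-01-01 00:00:00 UTC", c(0, 3))
  v4 <- list(dx, dy, dl, dt)
  v3 <- list(dx, dy, dt)
  mkv <- function(nm, d) ncdf4::ncvar_def(nm, "1", d, prec = "double")
  vars <- list(mkv("depth", list(dx, dy)),
               ncdf4::ncvar_def("land_mask", "1", list(dx, dy), prec = "integer"),
               mkv("u_bottom", v4), mkv("v_bottom", v4),
               mkv("rho_bottom", v3), mkv("rho_surface", v3),
               mkv("wind_speed", list(dt)), mkv("wind_dir", list(dt)),
               mkv("layer_depth", list(dl)))
  nc <- ncdf4::nc_create(path, vars)
  u4 <- array(seq_len(nx * ny * nl * nt), c(nx, ny, nl, nt))
  ncdf4::ncvar_put(nc, "depth", matrix(50, nx, ny))
  ncdf4::ncvar_put(nc, "land_mask", matrix(0L, nx, ny))
  ncdf4::ncvar_put(nc, "u_bottom", u4)
  ncdf4::ncvar_put(nc, "v_bottom", -u4)
  ncdf4::ncvar_put(nc, "rho_bottom", array(1025, c(nx, ny, nt)))
  ncdf4::ncvar_put(nc, "rho_surface", array(1024, c(nx, ny, nt)))
  ncdf4::ncvar_put(nc, "wind_speed", c(5, 5))
  ncdf4::ncvar_put(nc, "wind_dir", c(180, 180))
  ncdf4::ncvar_put(nc, "layer_depth", c(5, 25, 45))  # layer 3 is deepest
  ncdf4::nc_close(nc)
  f <- load_fields(path)
  manual <- u4[, , 3, ]                               # manual slice oracle
  expect_equal(f$u, array(manual, c(nx, ny, nt)))
  expect_equal(f$v, -array(manual, c(nx, ny, nt)))
})

test_that("velocity interpolation is exact for constant and linear fields", {
  g <- wet_grid()
  f_const <- analytic_fields(g, function(x, y, k) 0.1 + 0 * x)
  t_mid <- f_const$time[1] + 3600
  r <- interp_velocity(f_const, c(1234, 5678), c(2345, 6789), t_mid)
  expect_equal(r$u, c(0.1, 0.1))
  expect_equal(r$v, c(0, 0))

  # time-linear: u = 0.1 at t0, 0.3 at t1 -> 0.2 midway
  f_time <- analytic_fields(g, function(x, y, k) (0.1 + 0.2 * (k - 1)) + 0 * x)
  half <- f_time$time[1] + as.numeric(diff(as.numeric(f_time$time))) / 2
  expect_equal(interp_velocity(f_time, 5000, 5000, half)$u, 0.2)

  # plane field: u = a x + b y + c reproduced to 1e-12 relative
  a <- 3e-5; bb <- -2e-5; cc <- 0.05
  f_plane <- analytic_fields(g, function(x, y, k) a * x + bb * y + cc)
  set.seed(1)
  xs <- runif(50, 0, 10e3); ys <- runif(50, 0, 10e3)
  r <- interp_velocity(f_plane, xs, ys, t_mid)
  expect_equal(r$u, a * xs + bb * ys + cc, tolerance = 1e-12)
})

test_that("wet-weight renormalization preserves constants next to land", {
  x <- seq(0, 4000, by = 1000); y <- seq(0, 3000, by = 1000)
  depth <- matrix(50, 5, 4); depth[1, ] <- 0
  land <- depth == 0
  g <- bathymetry_grid(x, y, depth, land)
  times <- as.POSIXct("2017-06-01", tz = "UTC") + c(0, 3600)
  u <- array(0.1, c(5, 4, 2)); u[1, , ] <- NA
  v <- array(0, c(5, 4, 2)); v[1, , ] <- NA
  rho <- array(1025, c(5, 4, 2))
  f <- field_series(times, u, v, rho, rho, c(5, 5), c(180, 180), g)
  r <- interp_velocity(f, 500, 1500, times[1])   # between land and wet columns
  expect_equal(r$u, 0.1)
  expect_error(interp_velocity(f, 500, 1500, times[2] + 10), "out of range")
})

test_that("depth interpolation matches an independent bilinear evaluation", {
  g <- wet_grid(depth_fun = function(x, y) 10 + 0.01 * x + 0.002 * y)
  expect_equal(depth_at(g, g$x[4], g$y[3]), g$depth[4, 3])
  # midpoint of two nodes along a row: average of the node depths
  expect_equal(depth_at(g, (g$x[2] + g$x[3]) / 2, g$y[1]),
               (g$depth[2, 1] + g$depth[3, 1]) / 2)
  # reimplemented formula oracle at random interior points
  set.seed(2)
  xs <- runif(20, 0, 10e3); ys <- runif(20, 0, 10e3)
  oracle <- vapply(seq_along(xs), function(i) {
    ix <- findInterval(xs[i], g$x); iy <- findInterval(ys[i], g$y)
    fx <- (xs[i] - g$x[ix]) / diff(g$x[ix + 0:1])
    fy <- (ys[i] - g$y[iy]) / diff(g$y[iy + 0:1])
    (1 - fx) * (1 - fy) * g$depth[ix, iy] + fx * (1 - fy) * g$depth[ix + 1, iy] +
      (1 - fx) * fy * g$depth[ix, iy + 1] + fx * fy * g$depth[ix + 1, iy + 1]
  }, numeric(1))
  expect_equal(depth_at(g, xs, ys), oracle)
  expect_error(depth_at(g, -5, 0), "outside domain")
})

test_that("cross-shore transects sample coast-to-edge wet cells", {
  cfg <- tiny_cfg(noise_rho = 0, noise_u = 0)
  b <- make_bathymetry(cfg)
  f <- make_forcing(cfg, b)
  ev <- attr(f, "events")
  t_ev <- ev$start[1] + 3600 * 6
  tr <- cross_shore_transect(f, b, y_along = 10e3, time = t_ev)
  # cold season: density decreases offshore
  expect_true(all(diff(tr$rho) < 0))
  # one sample per wet cell shallower than the shelf edge
  j <- which.min(abs(b$y - 10e3))
  expect_equal(nrow(tr), sum(!b$land[, j] & b$depth[, j] < 200 & b$depth[, j] > 0))
  # distances are node coordinates: grid spacing times index
  expect_equal(tr$distance, cfg$dx * seq_len(nrow(tr)))
})
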