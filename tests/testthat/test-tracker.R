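test_that("RK4 is exact for constant and shear fields", {
  g <- wet_grid(Lx = 20e3, Ly = 20e3, dx = 1e3)
  f <- analytic_fields(g, function(x, y, k) 0.1 + 0 * x)
  r <- rk4_step(f, 1000, 1000, f$time[1], 600)
  expect_equal(r$x, 1000 + 60, tolerance = 1e-13)   # exact at machine precision
  expect_equal(r$y, 1000, tolerance = 1e-13)

  # linear shear u = a y: y stays constant, so the step is exact too
  a <- 2e-5
  fs <- analytic_fields(g, function(x, y, k) a * y)
  x0 <- 2000; y0 <- 7000; t <- 0
  pos <- list(x = x0, y = y0)
  for (i in 1:50) pos <- rk4_step(fs, pos$x, pos$y, fs$time[1] + t + (i - 1) * 600, 600)
  expect_equal(pos$y, y0)
  expect_equal(pos$x, x0 + a * y0 * 50 * 600, tolerance = 1e-14)
})

test_that("RK4 solid-body rotation converges at fourth order", {
  omega <- 1e-4; r0 <- 1000
  Lx <- 10e3; cx <- 5e3; cy <- 5e3
  g <- wet_grid(Lx = Lx, Ly = Lx, dx = 500)
  f <- analytic_fields(g, u_fun = function(x, y, k) -omega * (y - cy),
                       v_fun = function(x, y, k) omega * (x - cx),
                       times = as.POSIXct("2017-06-01", tz = "UTC") + c(0, 1e6))
  # integrate to a fixed total time divisible by every dt used and compare
  # against the analytic orbit point (position error is phase-dominated and
  # scales as dt^4)
  Ttot <- 62400
  orbit_error <- function(dt) {
    n <- Ttot / dt
    pos <- list(x = cx + r0, y = cy)
    t <- as.numeric(f$time[1])
    for (i in seq_len(n)) {
      pos <- rk4_step(f, pos$x, pos$y, t, dt)
      t <- t + dt
    }
    th <- omega * Ttot
    sqrt((pos$x - (cx + r0 * cos(th)))^2 + (pos$y - (cy + r0 * sin(th)))^2)
  }
  e60 <- orbit_error(60)
  expect_lt(e60, 1e-3)
  # halving dt divides the endpoint error by ~16 (fourth order)
  e600 <- orbit_error(600); e300 <- orbit_error(300)
  expect_gt(e600 / e300, 10)
  expect_lt(e600 / e300, 24)
})

test_that("Brownian steps satisfy the Einstein relation", {
  expect_equal(brownian_step(5, 0, 100), matrix(0, 5, 2))
  set.seed(6)
  b <- brownian_step(1e5, 10, 180)
  expect_equal(sd(b[, 1]), sqrt(2 * 10 * 180), tolerance = 0.01)
  expect_equal(sd(b[, 2]), 60, tolerance = 0.01)
  # mean-square displacement after 20 accumulated steps ~ 4 K t
  disp <- matrix(0, 2e4, 2)
  for (i in 1:20) disp <- disp + brownian_step(2e4, 10, 180)
  msd <- mean(rowSums(disp^2))
  expect_equal(msd, 4 * 10 * 20 * 180, tolerance = 0.03)
})

test_that("log-profile correction scales speeds as expected", {
  expect_equal(log_profile_correction(c(0.1, -0.2), 10, 5, 0.001), c(0.1, -0.2))
  fac <- kelpDSWT:::log_profile_factor(10, 1, 0.001)
  expect_equal(fac, log(1000) / log(5000), tolerance = 1e-12)
  expect_equal(fac, 0.8110, tolerance = 1e-3)
  expect_lt(kelpDSWT:::log_profile_factor(10, 2, 0.001), 1)
  expect_error(log_profile_correction(0.1, 10, 0.0005, 0.001), "z0")
})

test_that("advection handles rest, uniform drift and the velocity threshold", {
  # linear ramp bathymetry: depth = 200 m at x = 86.4 km
  slope <- 200 / 86400
  g <- wet_grid(Lx = 120e3, Ly = 10e3, dx = 2e3,
                depth_fun = function(x, y) slope * x)
  t0 <- as.POSIXct("2017-03-01", tz = "UTC")
  times <- t0 + seq(0, 15 * 86400, by = 3 * 3600)

  mkfields <- function(u0) {
    nx <- length(g$x); ny <- length(g$y); nt <- length(times)
    field_series(times, array(u0, c(nx, ny, nt)), array(0, c(nx, ny, nt)),
                 array(1025, c(nx, ny, nt)), array(1025, c(nx, ny, nt)),
                 rep(5, nt), rep(180, nt), g)
  }
  sch <- list(positions = data.frame(date = as.Date("2017-03-01"),
                                     x = c(0, 1000), y = c(3000, 6000),
                                     cell_i = c(1L, 1L), cell_j = c(2L, 4L)),
              total = 2L)
  class(sch) <- "release_schedule"

  # zero flow, no diffusion: particles stay put
  tr0 <- advect(sch, mkfields(0), options = tracker_options(K_h = 0))
  expect_equal(tr0$x[, ncol(tr0$x)], c(0, 1000))
  expect_true(all(tr0$fate == "active"))

  # uniform 0.1 m/s offshore: the particle released at the coast crosses the
  # 200 m contour after 86,400 m / 0.1 m/s = 10.0 days
  tr <- advect(sch, mkfields(0.1),
               options = tracker_options(K_h = 0, record_dt = 8640))
  cr <- first_crossing(tr, 200)
  expect_true(cr$crossed[1])
  # crossing ages are resolved to the record interval (~0.1 d)
  expect_equal(cr$age_days[1], 10.0, tolerance = 0.012)
  expect_equal(cr$age_days[2], (86400 - 1000) / 0.1 / 86400, tolerance = 0.012)

  # sub-threshold flow with the gate on: nobody moves
  trv <- advect(sch, mkfields(0.03),
                options = tracker_options(K_h = 0, v_crit = 0.045))
  expect_equal(trv$x[, ncol(trv$x)], c(0, 1000))

  # same speed without the gate: everybody moves
  trf <- advect(sch, mkfields(0.03), options = tracker_options(K_h = 0))
  expect_true(all(trf$x[, ncol(trf$x)] > c(0, 1000)))
})

test_that("onshore flow beaches particles at their last wet position", {
  g <- wet_grid(Lx = 20e3, Ly = 10e3, dx = 2e3,
                depth_fun = function(x, y) pmax(0.01, 0.01 * x))
  g$land[1, ] <- TRUE   # coast column
  t0 <- as.POSIXct("2017-03-01", tz = "UTC")
  times <- t0 + seq(0, 5 * 86400, by = 3 * 3600)
  nx <- length(g$x); ny <- length(g$y); nt <- length(times)
  u <- array(-0.05, c(nx, ny, nt)); u[1, , ] <- NA
  v <- array(0, c(nx, ny, nt)); v[1, , ] <- NA
  rho <- array(1025, c(nx, ny, nt))
  f <- field_series(times, u, v, rho, rho, rep(5, nt), rep(180, nt), g)
  sch <- list(positions = data.frame(date = as.Date("2017-03-01"),
                                     x = 10e3, y = 5e3,
                                     cell_i = 6L, cell_j = 3L), total = 1L)
  class(sch) <- "release_schedule"
  tr <- advect(sch, f, options = tracker_options(K_h = 0))
  expect_equal(tr$fate, "beached")
  expect_gte(tr$fate_x, 0)
  # beaching happened roughly when the drift reached the coast
  hours_to_coast <- 10e3 / 0.05 / 3600
  expect_equal(as.numeric(tr$fate_time - t0, units = "hours"), hours_to_coast,
               tolerance = 0.15)
})

test_that("trajectories conserve particle counts and are seed-reproducible", {
  cfg <- shelf_config(start = "2017-05-01", end = "2017-06-15", seed = 2L)
  b <- make_bathymetry(cfg)
  f <- make_forcing(cfg, b)
  kelp <- make_kelp_probability(b, cfg)
  sch <- build_schedule(kelp, b, 400, year = 2017, from = cfg$start,
                        to = as.Date("2017-06-01"), seed = 3L)

  tr1 <- advect(sch, f, options = tracker_options(seed = 5L))
  tr2 <- advect(sch, f, options = tracker_options(seed = 5L))
  expect_identical(tr1$x, tr2$x)
  expect_identical(tr1$fate, tr2$fate)

  # conservation: every released particle has exactly one fate
  n_rel <- nrow(sch$positions)
  expect_equal(sum(table(tr1$fate)), n_rel)
  expect_true(all(tr1$fate %in% c("active", "beached", "exported",
                                  "out_of_domain")))

  # K_h = 0 runs are independent of the seed
  tr3 <- advect(sch, f, options = tracker_options(K_h = 0, seed = 1L))
  tr4 <- advect(sch, f, options = tracker_options(K_h = 0, seed = 99L))
  expect_identical(tr3$x, tr4$x)
})
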