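#' Options for the particle tracker
#'
#' @param dt advection timestep (s).
#' @param K_h horizontal diffusivity (m^2/s) of the Brownian random walk.
#' @param v_crit threshold current speed (m/s) below which detritus rests on
#'   the seabed; 0 disables the gate. The sensitivity value for small kelp
#'   fragments is 0.045 m/s.
#' @param gate_diffusion when the threshold gate holds a particle, suppress
#'   the Brownian step too (a resting particle does not random-walk); set
#'   `FALSE` to gate advection only.
#' @param log_profile apply a logarithmic bottom-boundary-layer correction,
#'   rescaling the bottom-layer velocity from mid-layer height to
#'   `target_height`.
#' @param layer_thickness nominal bottom-layer thickness (m) for the
#'   log-profile correction.
#' @param target_height height above the bed (m) the corrected velocity
#'   applies at.
#' @param z0 seabed roughness length (m).
#' @param record_dt interval (s) at which particle positions are recorded;
#'   rounded to a multiple of `dt`.
#' @param stop_depth seabed depth (m) past which a particle is deactivated
#'   as exported (beyond the deepest depth level of interest).
#' @param seed integer seed for the diffusion random walk.
#' @return An object of class `tracker_options`.
#' @export
tracker_options <- function(dt = 900, K_h = 10, v_crit = 0,
                            gate_diffusion = TRUE,
                            log_profile = FALSE, layer_thickness = 10,
                            target_height = 1, z0 = 0.001,
                            record_dt = 86400, stop_depth = 1100,
                            seed = 1L) {
  stopifnot(dt > 0, K_h >= 0, v_crit >= 0, stop_depth > 0)
  record_dt <- max(dt, round(record_dt / dt) * dt)
  structure(list(dt = dt, K_h = K_h, v_crit = v_crit,
                 gate_diffusion = isTRUE(gate_diffusion),
                 log_profile = isTRUE(log_profile),
                 layer_thickness = layer_thickness,
                 target_height = target_height, z0 = z0,
                 record_dt = record_dt, stop_depth = stop_depth,
                 seed = as.integer(seed)),
            class = "tracker_options")
}

#' Classical fourth-order Runge-Kutta advection step
#'
#' Advances positions by one step of length `dt`, sampling the bottom
#' velocity with [interp_velocity()] semantics at the four stage points and
#' times. Stage points are clamped to the domain (and wrapped alongshore on
#' periodic grids); fate handling for steps that leave the water is the
#' caller's ([advect()]) responsibility.
#'
#' @param fields a [field_series()].
#' @param x,y current positions (m), vectorized.
#' @param time `POSIXct` or numeric seconds; start of the step.
#' @param dt step length (s).
#' @return list with new positions `x`, `y`.
#' @export
rk4_step <- function(fields, x, y, time, dt) {
  pre <- fields_precompute(fields)
  tnum <- as.numeric(time)
  d <- rk4_displacement(pre, x, y, tnum, dt)
  list(x = x + d$dx, y = y + d$dy)
}

# stage sampler: clamp x, wrap or clamp y, velocities NA -> 0
stage_velocity <- function(pre, x, y, tnum) {
  x <- pmin(pmax(x, pre$gx[1]), pre$gx[pre$nx])
  if (pre$periodic_y) {
    L <- pre$gy[pre$ny] - pre$gy[1]
    y <- pre$gy[1] + (y - pre$gy[1]) %% L
  } else {
    y <- pmin(pmax(y, pre$gy[1]), pre$gy[pre$ny])
  }
  r <- interp_uv(pre, x, y, tnum)
  r$u[is.na(r$u)] <- 0; r$v[is.na(r$v)] <- 0
  r
}

rk4_displacement <- function(pre, x, y, tnum, dt, k1 = NULL, vscale = 1) {
  if (is.null(k1)) k1 <- stage_velocity(pre, x, y, tnum)
  h2 <- dt / 2
  k2 <- stage_velocity(pre, x + h2 * vscale * k1$u, y + h2 * vscale * k1$v, tnum + h2)
  k3 <- stage_velocity(pre, x + h2 * vscale * k2$u, y + h2 * vscale * k2$v, tnum + h2)
  k4 <- stage_velocity(pre, x + dt * vscale * k3$u, y + dt * vscale * k3$v, tnum + dt)
  list(dx = vscale * dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u),
       dy = vscale * dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v))
}

#' Brownian diffusion step
#'
#' Independent Gaussian displacements with per-axis standard deviation
#' `sqrt(2 K_h dt)`, so an ensemble satisfies the two-dimensional Einstein
#' relation (mean-square displacement `4 K_h t`). Draws from R's global RNG
#' stream.
#'
#' @param n number of particles.
#' @param K_h horizontal diffusivity (m^2/s).
#' @param dt step length (s).
#' @return `n x 2` matrix of displacements (m).
#' @export
brownian_step <- function(n, K_h, dt) {
  if (K_h < 0) stop("brownian_step: K_h must be >= 0", call. = FALSE)
  if (K_h == 0) return(matrix(0, n, 2))
  sd <- sqrt(2 * K_h * dt)
  matrix(stats::rnorm(2 * n, 0, sd), n, 2)
}

#' Logarithmic bottom-profile velocity correction
#'
#' Rescales a bottom-layer velocity, nominally valid at mid-layer height,
#' to a target height above the bed assuming a logarithmic boundary-layer
#' profile: the speed scales by
#' `ln(target_height / z0) / ln(mid_height / z0)` with
#' `mid_height = layer_thickness / 2`; direction is preserved. The factor is
#' 1 when the target equals mid-layer height and < 1 below it.
#'
#' @param velocity numeric vector/matrix of velocity components (m/s).
#' @param layer_thickness bottom-layer thickness (m).
#' @param target_height height above the bed (m) to correct to.
#' @param z0 roughness length (m), `0 < z0 < heights`.
#' @return velocity scaled by the log-profile factor (same shape).
#' @export
log_profile_correction <- function(velocity, layer_thickness, target_height, z0) {
  velocity * log_profile_factor(layer_thickness, target_height, z0)
}

log_profile_factor <- function(layer_thickness, target_height, z0) {
  mid <- layer_thickness / 2
  if (z0 <= 0 || target_height <= z0 || mid <= z0) {
    stop("log_profile_correction: require 0 < z0 < target_height and z0 < layer_thickness/2",
         call. = FALSE)
  }
  log(target_height / z0) / log(mid / z0)
}

#' Track released particles with bottom currents
#'
#' Advances every scheduled particle from its release time with
#' [rk4_step()] advection plus [brownian_step()] diffusion until the end of
#' the forcing series. A particle whose step would land on land (or cross
#' the coast) is beached at its last wet position and frozen; a particle
#' carried past `stop_depth` is deactivated as exported; a particle leaving
#' the open offshore boundary is deactivated as out-of-domain. With
#' `v_crit > 0`, a particle holds position whenever the local current speed
#' is below the threshold. Positions are recorded every `record_dt` seconds;
#' each particle's final position and deactivation time are kept exactly.
#'
#' @param schedule a [build_schedule()] release schedule.
#' @param fields a [field_series()] spanning the schedule.
#' @param bathy bathymetry (defaults to `fields$grid`).
#' @param options a [tracker_options()].
#' @return An object of class `trajectory_set`: record `time` axis, `x` and
#'   `y` position matrices (particle x record, `NA` while unreleased or
#'   after deactivation), the `release` table, per-particle `fate`
#'   (`"active"`, `"beached"`, `"exported"`, `"out_of_domain"`), `fate_time`,
#'   `fate_x`, `fate_y`, and the options used.
#' @export
advect <- function(schedule, fields, bathy = fields$grid,
                   options = tracker_options()) {
  pre <- fields_precompute(fields)
  pos <- schedule$positions
  n <- nrow(pos)
  t_release <- as.numeric(as.POSIXct(paste(pos$date, "00:00:00"), tz = "UTC"))
  t_start <- min(t_release)
  t_end <- pre$times[pre$nt]
  if (t_start < pre$times[1] || max(t_release) > t_end) {
    stop("advect: release schedule lies outside the forcing time span", call. = FALSE)
  }
  dt <- options$dt
  n_steps <- floor((t_end - t_start) / dt)
  rec_every <- max(1L, as.integer(round(options$record_dt / dt)))
  rec_steps <- seq(0L, n_steps, by = rec_every)
  rec_times <- t_start + rec_steps * dt
  n_rec <- length(rec_steps)

  px <- pos$x; py <- pos$y
  state <- integer(n)                   # 0 unreleased, 1 active, 2 beached,
                                        # 3 exported, 4 out of domain
  rel_step <- pmax(0L, as.integer(ceiling((t_release - t_start) / dt)))
  fate_time <- rep(NA_real_, n); fate_x <- rep(NA_real_, n); fate_y <- rep(NA_real_, n)
  X <- matrix(NA_real_, n, n_rec); Y <- matrix(NA_real_, n, n_rec)

  vscale <- if (options$log_profile) {
    log_profile_factor(options$layer_thickness, options$target_height, options$z0)
  } else 1
  x_min <- pre$gx[1]; x_max <- pre$gx[pre$nx]
  y_min <- pre$gy[1]; y_max <- pre$gy[pre$ny]
  Lp <- y_max - y_min

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(options$seed)
  rec_ptr <- 1L
  for (k in 0:n_steps) {
    t_now <- t_start + k * dt
    state[state == 0L & rel_step == k] <- 1L
    if (rec_ptr <= n_rec && rec_steps[rec_ptr] == k) {
      act <- state == 1L
      X[act, rec_ptr] <- px[act]; Y[act, rec_ptr] <- py[act]
      rec_ptr <- rec_ptr + 1L
    }
    if (k == n_steps) break
    idx <- which(state == 1L)
    if (!length(idx)) next
    x0 <- px[idx]; y0 <- py[idx]
    k1 <- stage_velocity(pre, x0, y0, t_now)
    move <- rep(TRUE, length(idx))
    if (options$v_crit > 0) {
      move <- sqrt((vscale * k1$u)^2 + (vscale * k1$v)^2) >= options$v_crit
    }
    dx <- numeric(length(idx)); dy <- numeric(length(idx))
    if (any(move)) {
      mi <- which(move)
      d <- rk4_displacement(pre, x0[mi], y0[mi], t_now, dt,
                            k1 = list(u = k1$u[mi], v = k1$v[mi]), vscale = vscale)
      dx[mi] <- d$dx; dy[mi] <- d$dy
    }
    if (options$K_h > 0) {
      diffuse <- if (options$gate_diffusion) move else rep(TRUE, length(idx))
      if (any(diffuse)) {
        b <- brownian_step(sum(diffuse), options$K_h, dt)
        dx[diffuse] <- dx[diffuse] + b[, 1]
        dy[diffuse] <- dy[diffuse] + b[, 2]
      }
    }
    xn <- x0 + dx; yn <- y0 + dy
    if (pre$periodic_y) {
      yn <- y_min + (yn - y_min) %% Lp
    } else {
      yn <- pmin(pmax(yn, y_min), y_max)
    }
    # fate resolution
    beach <- xn < x_min
    exit <- xn > x_max
    xn_c <- pmin(pmax(xn, x_min), x_max)
    w <- interp_uv(pre, xn_c, yn, t_now + dt)
    beach <- beach | (w$w0 == 0)
    exit <- exit & !beach
    dep <- bilinear_eval(pre$gx, pre$gy, pre$depth, xn_c, yn)
    export <- !beach & !exit & dep >= options$stop_depth

    ok <- !(beach | exit | export)
    px[idx[ok]] <- xn[ok]; py[idx[ok]] <- yn[ok]
    if (any(beach)) {
      j <- idx[beach]
      state[j] <- 2L
      fate_time[j] <- t_now + dt; fate_x[j] <- px[j]; fate_y[j] <- py[j]
    }
    if (any(exit)) {
      j <- idx[exit]
      state[j] <- 4L
      fate_time[j] <- t_now + dt; fate_x[j] <- xn_c[exit]; fate_y[j] <- yn[exit]
    }
    if (any(export)) {
      j <- idx[export]
      state[j] <- 3L
      fate_time[j] <- t_now + dt; fate_x[j] <- xn[export]; fate_y[j] <- yn[export]
    }
  }
  # particles still active at the end keep their last position as fate point
  act <- state == 1L
  fate_time[act] <- t_end; fate_x[act] <- px[act]; fate_y[act] <- py[act]

  fate <- c("active", "beached", "exported", "out_of_domain")[pmax(state, 1L)]
  release <- data.frame(date = pos$date, x0 = pos$x, y0 = pos$y,
                        cell_i = pos$cell_i, cell_j = pos$cell_j,
                        t_release = as.POSIXct(t_release, origin = "1970-01-01",
                                               tz = "UTC"))
  structure(list(time = as.POSIXct(rec_times, origin = "1970-01-01", tz = "UTC"),
                 x = X, y = Y,
                 release = release,
                 fate = fate,
                 fate_time = as.POSIXct(fate_time, origin = "1970-01-01", tz = "UTC"),
                 fate_x = fate_x, fate_y = fate_y,
                 options = options, grid = bathy),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d particles, %d records (%s .. %s)\n",
              nrow(x$x), ncol(x$x), format(min(x$time)), format(max(x$time))))
  print(table(x$fate))
  invisible(x)
}

#' Write trajectories to NetCDF
#'
#' Particle-by-record layout: coordinates `time` (record axis) and
#' `particle`; variables `x`, `y` (recorded positions), release metadata and
#' per-particle fate (as integer code with a legend attribute).
#'
#' @param traj a [advect()] result.
#' @param path output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_trajectories_nc <- function(traj, path) {
  n <- nrow(traj$x); nr <- ncol(traj$x)
  t0 <- traj$time[1]
  dim_p <- ncdf4::ncdim_def("particle", "1", seq_len(n))
  dim_t <- ncdf4::ncdim_def("time",
                            paste("hours since", format(t0, "%Y-%m-%d %H:%M:%S",
                                                        tz = "UTC"), "UTC"),
                            as.numeric(traj$time - t0, units = "hours"))
  dpt <- list(dim_p, dim_t)
  vars <- list(
    ncdf4::ncvar_def("x", "m", dpt, missval = 1e30, prec = "double"),
    ncdf4::ncvar_def("y", "m", dpt, missval = 1e30, prec = "double"),
    ncdf4::ncvar_def("release_x", "m", list(dim_p), prec = "double"),
    ncdf4::ncvar_def("release_y", "m", list(dim_p), prec = "double"),
    ncdf4::ncvar_def("release_time", "hours", list(dim_p), prec = "double"),
    ncdf4::ncvar_def("fate", "1", list(dim_p), prec = "integer"),
    ncdf4::ncvar_def("fate_time", "hours", list(dim_p), missval = -1e30, prec = "double"),
    ncdf4::ncvar_def("fate_x", "m", list(dim_p), missval = 1e30, prec = "double"),
    ncdf4::ncvar_def("fate_y", "m", list(dim_p), missval = 1e30, prec = "double"),
    ncdf4::ncvar_def("release_date", "days since 1970-01-01", list(dim_p),
                     prec = "double"),
    ncdf4::ncvar_def("release_cell_i", "1", list(dim_p), prec = "integer"),
    ncdf4::ncvar_def("release_cell_j", "1", list(dim_p), prec = "integer"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  # fresh copies: ncvar_put writes the missing value over NA in place
  ncdf4::ncvar_put(nc, "x", traj$x + 0)
  ncdf4::ncvar_put(nc, "y", traj$y + 0)
  ncdf4::ncvar_put(nc, "release_x", traj$release$x0)
  ncdf4::ncvar_put(nc, "release_y", traj$release$y0)
  ncdf4::ncvar_put(nc, "release_time",
                   as.numeric(traj$release$t_release - t0, units = "hours"))
  fate_code <- match(traj$fate, c("active", "beached", "exported", "out_of_domain"))
  ncdf4::ncvar_put(nc, "fate", fate_code)
  ncdf4::ncatt_put(nc, "fate", "legend",
                   "1=active 2=beached 3=exported 4=out_of_domain")
  ncdf4::ncvar_put(nc, "fate_time", as.numeric(traj$fate_time - t0, units = "hours"))
  ncdf4::ncvar_put(nc, "fate_x", traj$fate_x + 0)
  ncdf4::ncvar_put(nc, "fate_y", traj$fate_y + 0)
  ncdf4::ncvar_put(nc, "release_date",
                   as.numeric(as.Date(traj$release$date)))
  ncdf4::ncvar_put(nc, "release_cell_i", traj$release$cell_i)
  ncdf4::ncvar_put(nc, "release_cell_j", traj$release$cell_j)
  invisible(path)
}

#' Read trajectories written by [write_trajectories_nc()]
#'
#' @param path `.nc` trajectory file.
#' @param grid the [bathymetry_grid()] the particles were tracked on (the
#'   trajectory file stores positions only).
#' @return A `trajectory_set`.
#' @export
read_trajectories_nc <- function(path, grid) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  origin <- sub(" UTC$", "", sub("^hours since ", "", nc$dim$time$units))
  t0 <- as.POSIXct(origin, tz = "UTC")
  time <- t0 + nc$dim$time$vals * 3600
  n <- nc$dim$particle$len
  grab <- function(v) ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
  fate_code <- as.integer(grab("fate"))
  release <- data.frame(
    date = as.Date(as.numeric(grab("release_date")), origin = "1970-01-01"),
    x0 = as.numeric(grab("release_x")), y0 = as.numeric(grab("release_y")),
    cell_i = as.integer(grab("release_cell_i")),
    cell_j = as.integer(grab("release_cell_j")),
    t_release = t0 + as.numeric(grab("release_time")) * 3600)
  structure(list(time = time,
                 x = matrix(grab("x"), n), y = matrix(grab("y"), n),
                 release = release,
                 fate = c("active", "beached", "exported",
                          "out_of_domain")[fate_code],
                 fate_time = t0 + as.numeric(grab("fate_time")) * 3600,
                 fate_x = as.numeric(grab("fate_x")),
                 fate_y = as.numeric(grab("fate_y")),
                 options = NULL, grid = grid),
            class = "trajectory_set")
}
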