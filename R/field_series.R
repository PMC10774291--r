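#' Time series of gridded bottom forcing
#'
#' Container for the forcing consumed by the DSWT classifier and the particle
#' tracker: bottom-layer velocity, bottom and surface density (the water
#' column in between is linearly stratified; profiles are expanded to
#' `n_layers` samples where a vertical integral is needed), and wind.
#' Velocity and density are `NA`-masked on land. Wind is spatially uniform
#' (one speed and direction-from per timestep), which is adequate at shelf
#' scale where the classifier uses a region mean anyway.
#'
#' @param time strictly increasing `POSIXct` (UTC) snapshot times.
#' @param u,v bottom velocity arrays `[nx, ny, nt]` (m/s); `u` positive
#'   offshore, `v` positive alongshore.
#' @param rho_bottom,rho_surface density arrays `[nx, ny, nt]` (kg/m^3).
#' @param wind_speed,wind_dir numeric vectors of length `nt`: wind speed at
#'   10 m (m/s) and meteorological direction-from (degrees clockwise from
#'   north).
#' @param grid the [bathymetry_grid()] the rasters live on.
#' @param n_layers vertical layers used when density profiles are expanded.
#' @return An object of class `field_series`.
#' @export
field_series <- function(time, u, v, rho_bottom, rho_surface,
                         wind_speed, wind_dir, grid, n_layers = 10L) {
  if (!inherits(time, "POSIXct")) stop("field_series: time must be POSIXct", call. = FALSE)
  if (length(time) < 2 || any(diff(as.numeric(time)) <= 0)) {
    stop("field_series: time axis must be strictly increasing", call. = FALSE)
  }
  nt <- length(time)
  shp <- c(length(grid$x), length(grid$y), nt)
  for (nm in c("u", "v", "rho_bottom", "rho_surface")) {
    a <- get(nm)
    if (!is.array(a) || !all(dim(a) == shp)) {
      stop("field_series: '", nm, "' must be an [nx, ny, nt] array matching ",
           "the grid and time axis", call. = FALSE)
    }
  }
  if (length(wind_speed) != nt || length(wind_dir) != nt) {
    stop("field_series: wind series must have one value per timestep", call. = FALSE)
  }
  structure(list(time = time, u = u, v = v,
                 rho_bottom = rho_bottom, rho_surface = rho_surface,
                 wind_speed = as.numeric(wind_speed),
                 wind_dir = as.numeric(wind_dir),
                 grid = grid, n_layers = as.integer(n_layers)),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series> %d snapshots (%s .. %s), grid %d x %d\n",
              length(x$time), format(min(x$time)), format(max(x$time)),
              length(x$grid$x), length(x$grid$y)))
  invisible(x)
}

#' DSWT pulse windows of a synthetic scenario
#'
#' Generates the square-wave schedule of dense-shelf-water pulse events:
#' within cold-season windows pulses of mean duration `pulse_duration_days`
#' alternate with gaps of mean `pulse_gap_days`; transition windows use the
#' sparser `transition_gap_days`. Durations and gaps are jittered by +/-20%
#' so events do not lock to the calendar, but the schedule is fully
#' determined by `cfg$seed`. Warm-season windows contain no events.
#'
#' @param cfg a [shelf_config()].
#' @return data.frame with `POSIXct` columns `start`, `end`.
#' @export
dswt_event_windows <- function(cfg) {
  validate_shelf_config(cfg)
  days <- seq(cfg$start, cfg$end, by = "day")
  tag <- season_of_month(cfg, as.POSIXlt(days)$mon + 1L)
  eventful <- tag %in% c("cold", "transition")
  runs <- rle(eventful)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  day_s <- 86400
  starts <- ends <- numeric(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    lo <- (run_start[r] - 1L) * day_s   # seconds since t0 at run start
    hi <- run_end[r] * day_s
    cursor <- lo
    repeat {
      # gap length follows the season at the cursor
      cur_tag <- tag[min(length(tag), floor(cursor / day_s) + 1L)]
      gap_days <- if (cur_tag == "cold") cfg$pulse_gap_days else cfg$transition_gap_days
      gap <- gap_days * stats::runif(1, 0.8, 1.2) * day_s
      dur <- cfg$pulse_duration_days * stats::runif(1, 0.8, 1.2) * day_s
      ev_start <- cursor + gap
      if (ev_start >= hi) break
      ev_end <- min(ev_start + dur, hi)
      starts <- c(starts, ev_start)
      ends <- c(ends, ev_end)
      cursor <- ev_end
    }
  }
  data.frame(start = t0 + starts, end = t0 + ends)
}

# save/restore the global RNG state so generator functions are pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate synthetic shelf forcing
#'
#' Builds the full forcing series for a scenario. Cold and transition season:
#' bottom density is higher at the coast (cross-shore gradient `grad_cold`),
#' and during pulse windows (see [dswt_event_windows()]) the water column is
#' stratified (`strat_drho_event`) and an offshore bottom-velocity pulse of
#' `pulse_speed` is applied over shelf cells (scaled by `offshore_factor`
#' seaward of the shelf edge); between pulses the column is near-mixed and
#' cross-shore flow is weak, with onshore storms occupying part of each gap.
#' Warm season: the density gradient is positive, cross-shore bottom flow is
#' onshore (`-onshore_speed`), the column is near-mixed, and winds follow an
#' afternoon seabreeze cycle. An alongshore current flows year-round.
#' Per-cell Gaussian noise (`noise_u`, `noise_rho`) is added on wet cells.
#' Everything is reproducible from `cfg$seed`.
#'
#' @param cfg a [shelf_config()].
#' @param bathy the matching [make_bathymetry()] output.
#' @return A [field_series()] with the event table attached as
#'   `attr(, "events")` and the config as `attr(, "config")`.
#' @export
make_forcing <- function(cfg, bathy) {
  validate_shelf_config(cfg)
  events <- dswt_event_windows(cfg)
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(cfg$end, "00:00:00"), tz = "UTC") + (86400 - cfg$dt_out)
  time <- seq(t0, t1, by = cfg$dt_out)
  nt <- length(time)
  nx <- length(bathy$x); ny <- length(bathy$y)
  lt <- as.POSIXlt(time)
  month <- lt$mon + 1L
  hod <- lt$hour + lt$min / 60
  tag <- season_of_month(cfg, month)

  # pulse activity in [0, 1] per snapshot (square wave, optional linear ramp)
  act <- pulse_activity(time, events, cfg$pulse_ramp_hours)

  # cross-shore velocity profile shape vs depth (per column of the grid)
  shape <- ifelse(bathy$depth <= cfg$depth_edge, 1, cfg$offshore_factor)

  u <- array(0, c(nx, ny, nt)); v <- array(0, c(nx, ny, nt))
  rho_b <- array(0, c(nx, ny, nt)); rho_s <- array(0, c(nx, ny, nt))
  grad <- ifelse(tag == "warm", cfg$grad_warm, cfg$grad_cold)
  drho <- ifelse(tag == "warm" | act <= 0, cfg$strat_drho_mixed,
                 cfg$strat_drho_mixed +
                   act * (cfg$strat_drho_event - cfg$strat_drho_mixed))
  xrel <- bathy$x - cfg$x_edge
  for (k in seq_len(nt)) {
    uk <- if (tag[k] == "warm") {
      matrix(-cfg$onshore_speed, nx, ny)
    } else {
      act[k] * cfg$pulse_speed * shape
    }
    u[, , k] <- uk
    v[, , k] <- cfg$alongshore_speed
    rho_b[, , k] <- matrix(cfg$rho0 + grad[k] * xrel, nx, ny)
    rho_s[, , k] <- rho_b[, , k] - drho[k]
  }

  # wind regimes: warm-season diurnal seabreeze; cold/transition storms in
  # the first storm_fraction of each inter-pulse gap, calm otherwise
  wind_speed <- numeric(nt); wind_dir <- numeric(nt)
  warm <- tag == "warm"
  wind_speed[warm] <- cfg$seabreeze_speed *
    pmax(0.2, sin(2 * pi * (hod[warm] - 9) / 24))
  wind_dir[warm] <- cfg$seabreeze_dir
  stormy <- !warm & storm_mask(time, events, cfg, tag)
  calm <- !warm & !stormy
  wind_speed[stormy] <- cfg$storm_speed
  wind_dir[stormy] <- cfg$storm_dir
  wind_speed[calm] <- cfg$calm_speed
  wind_dir[calm] <- cfg$calm_dir

  # seeded per-cell noise on wet cells
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1017L)
  wet <- !bathy$land
  nwet <- sum(wet)
  if (cfg$noise_u > 0 || cfg$noise_rho > 0) {
    for (k in seq_len(nt)) {
      if (cfg$noise_u > 0) {
        u[, , k][wet] <- u[, , k][wet] + stats::rnorm(nwet, 0, cfg$noise_u)
        v[, , k][wet] <- v[, , k][wet] + stats::rnorm(nwet, 0, cfg$noise_u)
      }
      if (cfg$noise_rho > 0) {
        e <- stats::rnorm(nwet, 0, cfg$noise_rho)
        rho_b[, , k][wet] <- rho_b[, , k][wet] + e
        rho_s[, , k][wet] <- rho_s[, , k][wet] + e
      }
    }
  }
  for (k in seq_len(nt)) {
    u[, , k][bathy$land] <- NA_real_
    v[, , k][bathy$land] <- NA_real_
    rho_b[, , k][bathy$land] <- NA_real_
    rho_s[, , k][bathy$land] <- NA_real_
  }

  fs <- field_series(time, u, v, rho_b, rho_s, wind_speed, wind_dir,
                     bathy, n_layers = cfg$n_layers)
  attr(fs, "events") <- events
  attr(fs, "config") <- cfg
  fs
}

# fraction of full pulse strength at each time (1 inside an event, 0 outside,
# linear ramps of `ramp_hours` at the edges)
pulse_activity <- function(time, events, ramp_hours = 0) {
  act <- numeric(length(time))
  if (nrow(events) == 0) return(act)
  tn <- as.numeric(time)
  ramp <- ramp_hours * 3600
  for (i in seq_len(nrow(events))) {
    s <- as.numeric(events$start[i]); e <- as.numeric(events$end[i])
    inside <- tn >= s & tn < e
    if (ramp <= 0) {
      act[inside] <- 1
    } else {
      a <- pmin(1, (tn - s) / ramp, (e - tn) / ramp)
      act[inside] <- pmax(act[inside], a[inside])
    }
  }
  act
}

# TRUE where a cold/transition snapshot falls in the leading storm_fraction
# of the gap following each pulse (and of the interval before the first pulse)
storm_mask <- function(time, events, cfg, tag) {
  tn <- as.numeric(time)
  mask <- rep(FALSE, length(tn))
  if (nrow(events) == 0) return(mask)
  bounds <- c(min(tn) - 1, as.numeric(events$end))
  next_start <- c(as.numeric(events$start), max(tn) + 1)
  for (i in seq_along(bounds)) {
    gap_lo <- bounds[i]; gap_hi <- next_start[i]
    if (gap_hi <= gap_lo) next
    cut <- gap_lo + cfg$storm_fraction * (gap_hi - gap_lo)
    mask <- mask | (tn >= gap_lo & tn < cut)
  }
  mask & tag != "warm"
}
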