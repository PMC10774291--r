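#' Configuration for an idealized shelf scenario
#'
#' Defines the geometry, forcing and seasonal structure of a synthetic
#' mid-latitude continental shelf in a local Cartesian frame
#' (x = cross-shore in metres, positive offshore from the coast at x = 0;
#' y = alongshore in metres, treated as a periodic channel). The defaults
#' describe a shelf that slopes gently to ~50 m over the inner shelf, steepens
#' to the 200 m shelf edge, and then drops towards the open ocean, with a
#' cold-season cross-shore density gradient that turns negative (denser water
#' at the coast), episodic offshore bottom-flow pulses during stratified
#' low-wind periods, a year-round alongshore current, seabreeze/storm wind
#' regimes, and kelp restricted to reefs shallower than ~50 m.
#'
#' @param Lx,Ly domain extent (m): cross-shore and alongshore lengths.
#' @param dx grid spacing (m), shared by both axes.
#' @param x_inner,x_edge distance from the coast (m) of the inner-shelf break
#'   and of the continental shelf edge.
#' @param depth_inner,depth_edge,depth_max depth (m) at `x_inner`, at
#'   `x_edge` (the shelf-edge contour used for export), and at the offshore
#'   boundary. Must be strictly increasing.
#' @param start,end first and last day of the generated forcing (`Date` or
#'   string). The default spans a full release year plus a one-month tail so
#'   late releases can still be transported.
#' @param dt_out forcing output interval (s); default 3 h.
#' @param season_months named list tagging calendar months 1..12 as
#'   `warm`, `transition` or `cold`.
#' @param pulse_speed offshore bottom speed (m/s) during a DSWT pulse.
#' @param pulse_duration_days,pulse_gap_days mean duration of a pulse and mean
#'   gap between pulses (days) inside cold-season windows.
#' @param transition_gap_days mean gap between pulses (days) in transition
#'   windows (sparser events than in the cold season).
#' @param pulse_ramp_hours linear ramp applied to each square pulse edge
#'   (h); 0 gives a pure square wave with unambiguous ground truth.
#' @param offshore_factor fraction of `pulse_speed` retained seaward of the
#'   shelf edge (the cascade continuing downslope).
#' @param onshore_speed warm-season onshore bottom speed (m/s, applied as
#'   negative cross-shore velocity over the shelf).
#' @param alongshore_speed background alongshore bottom current (m/s).
#' @param rho0 reference bottom density (kg/m^3) at the shelf edge.
#' @param grad_cold,grad_warm cross-shore bottom density gradient (kg/m^4)
#'   in cold/transition windows (negative: denser at the coast) and in warm
#'   windows (positive).
#' @param strat_drho_event,strat_drho_mixed surface-to-bottom density excess
#'   (kg/m^3) during pulses (stratified) and otherwise (near-mixed).
#' @param seabreeze_speed,seabreeze_dir warm-season afternoon seabreeze peak
#'   speed (m/s) and direction-from (degrees clockwise from north).
#' @param storm_speed,storm_dir cold-season storm wind speed and
#'   direction-from; the default direction is onshore (within 225-315 deg).
#' @param storm_fraction fraction of each inter-pulse gap occupied by a storm.
#' @param calm_speed,calm_dir background wind between storms and during
#'   pulses.
#' @param kelp_depth_limit maximum depth (m) at which kelp occurs.
#' @param kelp_decline_scale e-folding depth scale (m) of the kelp
#'   probability decline.
#' @param noise_u,noise_rho per-cell Gaussian noise s.d. added to bottom
#'   velocity (m/s) and bottom density (kg/m^3).
#' @param n_layers number of uniform vertical layers used when density
#'   profiles are expanded for stratification integrals.
#' @param seed integer seed; fully determines the generated scenario.
#'
#' @return An object of class `shelf_config` (a validated list).
#' @export
shelf_config <- function(Lx = 60e3, Ly = 30e3, dx = 2e3,
                         x_inner = 20e3, x_edge = 40e3,
                         depth_inner = 50, depth_edge = 200, depth_max = 1200,
                         start = "2017-01-01", end = "2018-01-31",
                         dt_out = 3 * 3600,
                         season_months = list(warm = c(11, 12, 1, 2, 3),
                                              transition = c(4, 9, 10),
                                              cold = c(5, 6, 7, 8)),
                         pulse_speed = 0.15,
                         pulse_duration_days = 3,
                         pulse_gap_days = 2,
                         transition_gap_days = 12,
                         pulse_ramp_hours = 0,
                         offshore_factor = 0.7,
                         onshore_speed = 0.02,
                         alongshore_speed = 0.1,
                         rho0 = 1025.5,
                         grad_cold = -1e-5, grad_warm = 1e-5,
                         strat_drho_event = 0.3, strat_drho_mixed = 0.05,
                         seabreeze_speed = 12, seabreeze_dir = 180,
                         storm_speed = 15, storm_dir = 270,
                         storm_fraction = 0.5,
                         calm_speed = 7, calm_dir = 200,
                         kelp_depth_limit = 50, kelp_decline_scale = 30,
                         noise_u = 0.005, noise_rho = 0.002,
                         n_layers = 10,
                         seed = 1L) {
  cfg <- list(Lx = Lx, Ly = Ly, dx = dx,
              x_inner = x_inner, x_edge = x_edge,
              depth_inner = depth_inner, depth_edge = depth_edge,
              depth_max = depth_max,
              start = as.Date(start), end = as.Date(end),
              dt_out = dt_out,
              season_months = season_months,
              pulse_speed = pulse_speed,
              pulse_duration_days = pulse_duration_days,
              pulse_gap_days = pulse_gap_days,
              transition_gap_days = transition_gap_days,
              pulse_ramp_hours = pulse_ramp_hours,
              offshore_factor = offshore_factor,
              onshore_speed = onshore_speed,
              alongshore_speed = alongshore_speed,
              rho0 = rho0,
              grad_cold = grad_cold, grad_warm = grad_warm,
              strat_drho_event = strat_drho_event,
              strat_drho_mixed = strat_drho_mixed,
              seabreeze_speed = seabreeze_speed, seabreeze_dir = seabreeze_dir,
              storm_speed = storm_speed, storm_dir = storm_dir,
              storm_fraction = storm_fraction,
              calm_speed = calm_speed, calm_dir = calm_dir,
              kelp_depth_limit = kelp_depth_limit,
              kelp_decline_scale = kelp_decline_scale,
              noise_u = noise_u, noise_rho = noise_rho,
              n_layers = as.integer(n_layers),
              seed = as.integer(seed))
  class(cfg) <- "shelf_config"
  validate_shelf_config(cfg)
  cfg
}

validate_shelf_config <- function(cfg) {
  stopifnot(inherits(cfg, "shelf_config"))
  pos <- c("Lx", "Ly", "dx", "x_inner", "x_edge", "depth_inner", "depth_edge",
           "depth_max", "dt_out", "pulse_speed", "pulse_duration_days",
           "pulse_gap_days", "transition_gap_days", "alongshore_speed",
           "kelp_depth_limit", "kelp_decline_scale", "n_layers")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("shelf_config: '", f, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (cfg$x_inner >= cfg$x_edge || cfg$x_edge >= cfg$Lx) {
    stop("shelf_config: require 0 < x_inner < x_edge < Lx", call. = FALSE)
  }
  if (!(cfg$depth_inner < cfg$depth_edge && cfg$depth_edge < cfg$depth_max)) {
    stop("shelf_config: depth profile must be monotone ",
         "(depth_inner < depth_edge < depth_max)", call. = FALSE)
  }
  if (cfg$end <= cfg$start) stop("shelf_config: end must be after start", call. = FALSE)
  tags <- sort(unlist(cfg$season_months, use.names = FALSE))
  if (!identical(as.integer(tags), 1:12)) {
    stop("shelf_config: season_months must partition months 1..12", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.shelf_config <- function(x, ...) {
  cat("<shelf_config>\n")
  cat(sprintf("  domain: %.0f x %.0f km, dx = %.1f km\n",
              x$Lx / 1e3, x$Ly / 1e3, x$dx / 1e3))
  cat(sprintf("  shelf edge (%.0f m) at %.0f km; offshore max %.0f m\n",
              x$depth_edge, x$x_edge / 1e3, x$depth_max))
  cat(sprintf("  forcing: %s .. %s every %.0f h, seed %d\n",
              format(x$start), format(x$end), x$dt_out / 3600, x$seed))
  cat(sprintf("  DSWT pulses: %.2f m/s, ~%.1f d on / ~%.1f d off (cold)\n",
              x$pulse_speed, x$pulse_duration_days, x$pulse_gap_days))
  invisible(x)
}

# season tag ("warm"/"transition"/"cold") for a vector of month numbers
season_of_month <- function(cfg, month) {
  tag <- character(length(month))
  for (s in names(cfg$season_months)) {
    tag[month %in% cfg$season_months[[s]]] <- s
  }
  tag
}

#' Read or write a scenario configuration as plain-text key/value pairs
#'
#' The file holds one `key = value` pair per line; vectors are comma-separated
#' and the season schedule is encoded as `season.warm`, `season.transition`,
#' `season.cold`. Any key omitted from the file keeps its [shelf_config()]
#' default.
#'
#' @param path file path.
#' @param cfg a `shelf_config` (for writing).
#' @return `read_shelf_config()` returns a `shelf_config`;
#'   `write_shelf_config()` returns `path` invisibly.
#' @export
read_shelf_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  args <- list()
  season <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "season.")) {
      season[[sub("^season\\.", "", k)]] <- as.numeric(strsplit(v, ",")[[1]])
    } else if (k %in% c("start", "end")) {
      args[[k]] <- v
    } else {
      num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      args[[k]] <- if (anyNA(num)) v else num
    }
  }
  if (length(season)) args$season_months <- season
  unknown <- setdiff(names(args), names(formals(shelf_config)))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(shelf_config, args)
}

#' @rdname read_shelf_config
#' @export
write_shelf_config <- function(cfg, path) {
  validate_shelf_config(cfg)
  fmt <- function(v) paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
  keys <- setdiff(names(cfg), "season_months")
  lines <- vapply(keys, function(k) paste(k, "=", fmt(cfg[[k]])), "")
  lines <- c(lines, vapply(names(cfg$season_months), function(s) {
    paste0("season.", s, " = ", fmt(cfg$season_months[[s]]))
  }, ""))
  writeLines(lines, path)
  invisible(path)
}
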