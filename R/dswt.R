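#' Physical constants and thresholds for DSWT classification
#'
#' Bundles the constants of the three-condition suitability test:
#' gravitational acceleration `g`, vertical eddy diffusivity `K_mz`, wind
#' mixing efficiency `delta`, air density `rho_a`, the potential energy
#' anomaly threshold above which the region-mean water column counts as
#' stratified, and the inclusive direction-from sector (degrees) within which
#' wind counts as onshore.
#'
#' @param g gravitational acceleration (m/s^2).
#' @param K_mz vertical eddy diffusivity (m^2/s).
#' @param delta wind mixing efficiency (dimensionless).
#' @param rho_a air density (kg/m^3).
#' @param phi_threshold stratification threshold for the region-mean
#'   potential energy anomaly (J/m^3).
#' @param onshore_sector inclusive `[lo, hi]` direction-from sector (deg).
#' @return An object of class `dswt_constants`.
#' @export
dswt_constants <- function(g = 9.81, K_mz = 1e-2, delta = 3e-3, rho_a = 1.2,
                           phi_threshold = 5, onshore_sector = c(225, 315)) {
  stopifnot(g > 0, K_mz > 0, delta > 0, rho_a > 0,
            length(onshore_sector) == 2, onshore_sector[1] <= onshore_sector[2])
  structure(list(g = g, K_mz = K_mz, delta = delta, rho_a = rho_a,
                 phi_threshold = phi_threshold,
                 onshore_sector = as.numeric(onshore_sector)),
            class = "dswt_constants")
}

#' Potential energy anomaly of a density profile
#'
#' The energy per unit volume required to fully mix a stratified water
#' column: `phi = (1/h) * integral over [-h, 0] of (rho_bar - rho) g z dz`,
#' where `rho_bar` is the depth-averaged density. The supplied samples are
#' treated as a piecewise-linear density profile and the integral is
#' evaluated exactly per segment (the integrand is quadratic on each
#' segment, so a three-point rule closes it); `phi = 0` for a
#' density-uniform column and positive for stable stratification.
#'
#' @param z layer sample depths (m, negative downward; spanning `[-h, 0]` in
#'   any order; duplicated `z` values may encode a density step).
#' @param rho layer densities (kg/m^3), matching `z`.
#' @param h water depth (m); defaults to `-min(z)`.
#' @param g gravitational acceleration (m/s^2).
#' @return phi in J/m^3.
#' @export
potential_energy_anomaly <- function(z, rho, h = -min(z), g = 9.81) {
  if (length(z) != length(rho) || length(z) < 2) {
    stop("potential_energy_anomaly: need matching z and rho samples", call. = FALSE)
  }
  if (!is.finite(h) || h <= 0) {
    stop("potential_energy_anomaly: water depth h must be positive", call. = FALSE)
  }
  ord <- order(z)
  z <- z[ord]; rho <- rho[ord]
  dz <- diff(z)
  # depth-mean density: trapezoid, exact for a piecewise-linear profile
  rho_bar <- sum(dz * (rho[-1] + rho[-length(rho)]) / 2) / h
  # segment-exact integral of f(z) = (rho_bar - rho) g z: f is quadratic on
  # each linear-density segment, closed by the three-point Simpson rule
  f <- (rho_bar - rho) * g * z
  zm <- (z[-1] + z[-length(z)]) / 2
  rhom <- (rho[-1] + rho[-length(rho)]) / 2
  fm <- (rho_bar - rhom) * g * zm
  sum(dz / 6 * (f[-length(f)] + 4 * fm + f[-1])) / h
}

# vectorized PEA for linearly stratified columns (surface density rho_s,
# bottom density rho_b, depth h): the segment-exact integral of a single
# linear profile is g (rho_b - rho_s) h / 12 at any layer count, so the
# layer expansion drops out analytically
pea_linear_cells <- function(rho_s, rho_b, h, n_layers, g = 9.81) {
  g * (rho_b - rho_s) * h / 12
}

#' Horizontal density gradient along a cross-shore transect
#'
#' Ordinary least-squares slope of bottom density against offshore distance.
#' With x increasing offshore, denser water at the coast gives a negative
#' slope — the sign convention of the DSWT gradient condition
#' (`d rho / dx < 0`).
#'
#' @param transect data.frame with columns `distance` (m) and `rho`
#'   (kg/m^3), as returned by [cross_shore_transect()]; alternatively pass
#'   `distance` and `rho` directly.
#' @param distance,rho optional explicit vectors (override `transect`).
#' @return slope in kg/m^4.
#' @export
horizontal_density_gradient <- function(transect = NULL, distance = transect$distance,
                                        rho = transect$rho) {
  if (length(distance) < 2 || length(distance) != length(rho)) {
    stop("horizontal_density_gradient: need >= 2 (distance, rho) samples", call. = FALSE)
  }
  dx <- distance - mean(distance)
  sum(dx * (rho - mean(rho))) / sum(dx^2)
}

#' Wind-stress drag coefficient
#'
#' `kappa_s = 0.03 (0.63 + 0.066 W^(1/3)) / 1000` for 10 m wind speed `W`.
#'
#' @param W wind speed (m/s), vectorized; negative values are rejected.
#' @return dimensionless drag coefficient.
#' @export
drag_coefficient <- function(W) {
  if (any(W < 0)) stop("drag_coefficient: wind speed must be >= 0", call. = FALSE)
  0.03 * (0.63 + 0.066 * W^(1 / 3)) / 1000
}

#' Gravitational-circulation vs wind-mixing criterion
#'
#' Compares the stratifying tendency of the gravitational circulation,
#' `(1/320) g^2 h^4 / (rho K_mz) (d rho/dx)^2`, against the destratifying
#' tendency of wind mixing, `delta kappa_s rho_a W^3 / h` (both in J/m^3/s).
#' The criterion holds when the gravitational term is larger.
#'
#' @param h water depth (m).
#' @param rho water density (kg/m^3).
#' @param drhodx horizontal density gradient (kg/m^4).
#' @param W wind speed (m/s).
#' @param constants a [dswt_constants()].
#' @return list with `gravitational`, `wind` (J/m^3/s) and logical `flag`
#'   (gravitational > wind). All vectorized.
#' @export
mixing_criterion <- function(h, rho, drhodx, W, constants = dswt_constants()) {
  if (any(h <= 0) || any(rho <= 0)) {
    stop("mixing_criterion: h and rho must be positive", call. = FALSE)
  }
  cs <- constants
  gravitational <- (1 / 320) * cs$g^2 * h^4 / (rho * cs$K_mz) * drhodx^2
  wind <- cs$delta * drag_coefficient(W) * cs$rho_a * W^3 / h
  list(gravitational = gravitational, wind = wind, flag = gravitational > wind)
}

#' Is the wind onshore?
#'
#' @param direction_from meteorological wind direction (degrees clockwise
#'   from north, the direction the wind comes from), in `[0, 360)`.
#' @param sector inclusive `[lo, hi]` onshore sector (degrees); the default
#'   225-315 spans northwesterly through southwesterly winds.
#' @return logical, vectorized.
#' @export
is_onshore_wind <- function(direction_from, sector = c(225, 315)) {
  direction_from >= sector[1] & direction_from <= sector[2]
}

#' Classify per-timestep suitability for dense shelf water transport
#'
#' Applies the three-condition test to every snapshot of a forcing series:
#' (1) the cross-shore bottom density gradient — the mean over alongshore
#' rows of per-row OLS transect slopes — must be negative; (2) the
#' region-mean potential energy anomaly must exceed `phi_threshold`;
#' (3) the gravitational term of [mixing_criterion()] (evaluated with
#' region-mean depth, density and wind) must exceed the wind-mixing term,
#' unless the wind is onshore. Conditions combine as
#' `suitable = gradient & stratified & (mixing | onshore)`.
#'
#' @param fields a [field_series()].
#' @param bathy bathymetry (defaults to `fields$grid`).
#' @param region logical matrix selecting the analysis cells; default: wet
#'   cells with `0 < depth <= edge_depth`.
#' @param constants a [dswt_constants()].
#' @param edge_depth shelf-edge depth (m) bounding transects and the default
#'   region.
#' @return A data.frame of class `dswt_series`: `time`, `gradient`, `phi`,
#'   `grav_term`, `wind_term`, the three condition flags, `onshore`, and
#'   `suitable`.
#' @export
classify_dswt <- function(fields, bathy = fields$grid, region = NULL,
                          constants = dswt_constants(), edge_depth = 200) {
  wet <- !bathy$land & bathy$depth > 0
  if (is.null(region)) region <- wet & bathy$depth <= edge_depth
  if (!any(region)) stop("classify_dswt: empty analysis region", call. = FALSE)
  nt <- length(fields$time)
  nx <- length(bathy$x)

  # per-row OLS slopes for all timesteps at once: slope_t = w' rho_t
  grad_rows <- matrix(NA_real_, 0, nt)
  for (j in seq_along(bathy$y)) {
    sel <- wet[, j] & bathy$depth[, j] < edge_depth
    if (sum(sel) < 2) next
    xs <- bathy$x[sel]
    w <- (xs - mean(xs)) / sum((xs - mean(xs))^2)
    rows <- fields$rho_bottom[sel, j, , drop = FALSE]   # m x 1 x nt
    slopes <- as.numeric(crossprod(w, matrix(rows, nrow = sum(sel))))
    grad_rows <- rbind(grad_rows, slopes)
  }
  if (nrow(grad_rows) == 0) {
    stop("classify_dswt: no transect with >= 2 wet shelf cells", call. = FALSE)
  }
  gradient <- colMeans(grad_rows)

  # region-mean PEA per timestep from per-cell linear profiles
  idx <- which(region)
  h_cells <- bathy$depth[idx]
  ncell <- nx * length(bathy$y)
  phi <- vapply(seq_len(nt), function(k) {
    off <- (k - 1L) * ncell
    mean(pea_linear_cells(fields$rho_surface[off + idx],
                          fields$rho_bottom[off + idx],
                          h_cells, fields$n_layers, constants$g))
  }, numeric(1))

  h_bar <- mean(h_cells)
  rho_bar <- vapply(seq_len(nt), function(k) {
    mean(fields$rho_bottom[(k - 1L) * ncell + idx])
  }, numeric(1))
  mix <- mixing_criterion(h_bar, rho_bar, gradient, fields$wind_speed, constants)
  onshore <- is_onshore_wind(fields$wind_dir, constants$onshore_sector)

  out <- data.frame(time = fields$time,
                    gradient = gradient,
                    phi = phi,
                    grav_term = mix$gravitational,
                    wind_term = mix$wind,
                    gradient_ok = gradient < 0,
                    stratified_ok = phi > constants$phi_threshold,
                    mixing_ok = mix$flag,
                    onshore = onshore)
  out$suitable <- combine_dswt_flags(out$gradient_ok, out$stratified_ok,
                                     out$mixing_ok, out$onshore)
  class(out) <- c("dswt_series", "data.frame")
  out
}

#' Combine the three DSWT condition flags
#'
#' `suitable = gradient & stratified & (mixing | onshore)`: a negative
#' cross-shore density gradient and a stratified column are both required;
#' the wind-mixing criterion may be overridden by onshore wind.
#'
#' @param gradient_ok,stratified_ok,mixing_ok,onshore logical vectors.
#' @return logical vector of combined suitability.
#' @export
combine_dswt_flags <- function(gradient_ok, stratified_ok, mixing_ok, onshore) {
  gradient_ok & stratified_ok & (mixing_ok | onshore)
}

#' Monthly percentage of time with conditions suitable for DSWT
#'
#' @param states a `dswt_series` from [classify_dswt()].
#' @return data.frame with `month` (`"YYYY-MM"`), `n_steps`, and
#'   `percent_suitable` (100 x suitable steps / steps in month).
#' @export
monthly_suitability <- function(states) {
  if (nrow(states) == 0) stop("monthly_suitability: empty series", call. = FALSE)
  month <- format(states$time, "%Y-%m")
  agg <- stats::aggregate(states$suitable, by = list(month = month),
                   FUN = function(s) c(n = length(s), pct = 100 * mean(s)))
  data.frame(month = agg$month,
             n_steps = agg$x[, "n"],
             percent_suitable = agg$x[, "pct"])
}
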