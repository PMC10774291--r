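#' Exponential decay model for kelp detritus
#'
#' Remaining mass fraction of a detrital particle after `t` days adrift:
#' `P(t) = P0 exp(-k t)`. The decay rate is entered as a positive magnitude
#' and applied as a decay. Defaults are the in-situ rate for golden kelp
#' (`k = 0.075 +/- 0.031` per day, half-life ~9.2 days).
#'
#' @param k decay rate magnitude (per day), > 0.
#' @param sigma_k one standard deviation of `k` (per day), >= 0.
#' @param P0 initial mass fraction.
#' @return An object of class `decay_model`.
#' @export
decay_model <- function(k = 0.075, sigma_k = 0.031, P0 = 1) {
  stopifnot(k > 0, sigma_k >= 0, P0 > 0)
  structure(list(k = k, sigma_k = sigma_k, P0 = P0), class = "decay_model")
}

#' Remaining mass fraction at a given particle age
#'
#' @param age_days particle age in days (>= 0, vectorized).
#' @param model a [decay_model()].
#' @param k override the decay rate (used for the uncertainty band).
#' @return fraction(s) in `(0, P0]`.
#' @export
decay_weight <- function(age_days, model = decay_model(), k = model$k) {
  if (any(age_days < 0)) stop("decay_weight: age must be >= 0", call. = FALSE)
  model$P0 * exp(-k * age_days)
}

#' First crossing of a depth level per particle
#'
#' A particle crosses a depth level when the bathymetry depth interpolated
#' at its position first reaches the level. Crossings are detected on the
#' recorded positions plus each particle's exactly-kept final position.
#'
#' @param traj a [advect()] trajectory set.
#' @param level depth level (m), > 0; 200 is the continental shelf edge.
#' @param bathy bathymetry (defaults to the trajectory set's grid).
#' @return data.frame with one row per particle: `crossed` (logical),
#'   crossing `time` (`POSIXct`, `NA` if never), `x`, `y`, and `age_days`
#'   (age at crossing since release).
#' @export
first_crossing <- function(traj, level, bathy = traj$grid) {
  if (level <= 0) stop("first_crossing: level must be positive", call. = FALSE)
  n <- nrow(traj$x)
  D <- matrix(bilinear_eval(bathy$x, bathy$y, bathy$depth,
                            as.numeric(traj$x), as.numeric(traj$y)),
              n, ncol(traj$x))
  M <- !is.na(D) & D >= level
  first <- max.col(M, ties.method = "first")
  hit <- M[cbind(seq_len(n), first)]
  time <- rep(as.POSIXct(NA, tz = "UTC"), n)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  time[hit] <- traj$time[first[hit]]
  x[hit] <- traj$x[cbind(which(hit), first[hit])]
  y[hit] <- traj$y[cbind(which(hit), first[hit])]
  # fall back to the final position for particles with no recorded crossing
  dep_fate <- bilinear_eval(bathy$x, bathy$y, bathy$depth, traj$fate_x, traj$fate_y)
  late <- !hit & !is.na(dep_fate) & dep_fate >= level
  time[late] <- traj$fate_time[late]
  x[late] <- traj$fate_x[late]; y[late] <- traj$fate_y[late]
  crossed <- hit | late
  age <- as.numeric(time) - as.numeric(traj$release$t_release)
  data.frame(crossed = crossed, time = time, x = x, y = y,
             age_days = ifelse(crossed, age / 86400, NA_real_))
}

#' Cumulative export fraction by depth level and particle age
#'
#' For each depth level, the fraction of all released particles whose first
#' crossing of that level occurred at or before each age.
#'
#' @param traj a trajectory set.
#' @param levels depth levels (m); default 200 to 1000 m.
#' @param ages ages (days) at which the curves are evaluated; defaults to
#'   daily steps up to the span of the simulation.
#' @return data.frame with columns `level`, `age_days`, `fraction`.
#' @export
export_fraction_vs_age <- function(traj, levels = seq(200, 1000, by = 200),
                                   ages = NULL) {
  if (is.null(ages)) {
    span <- as.numeric(max(traj$time) - min(traj$time), units = "days")
    ages <- seq(0, ceiling(span), by = 1)
  }
  n <- nrow(traj$x)
  out <- lapply(levels, function(lv) {
    cr <- first_crossing(traj, lv)
    a <- cr$age_days[cr$crossed]
    data.frame(level = lv, age_days = ages,
               fraction = vapply(ages, function(t) sum(a <= t) / n, numeric(1)))
  })
  do.call(rbind, out)
}

#' Decay-weighted export fraction past a depth level
#'
#' Each exported particle contributes `exp(-k * age_at_crossing)` of its
#' released mass; the decayed export fraction is the sum of those weights
#' over all released particles. The uncertainty band evaluates the weights
#' at `k - sigma_k` (upper) and `k + sigma_k` (lower).
#'
#' @param traj a trajectory set.
#' @param model a [decay_model()].
#' @param level depth level (m); default the 200 m shelf edge.
#' @return list with `undecayed` (plain export fraction), `decayed`,
#'   `decayed_lower`, `decayed_upper`, `n_exported`, `n_released`.
#' @export
decayed_export <- function(traj, model = decay_model(), level = 200) {
  cr <- first_crossing(traj, level)
  n <- nrow(traj$x)
  a <- cr$age_days[cr$crossed]
  list(undecayed = length(a) / n,
       decayed = sum(decay_weight(a, model)) / n,
       decayed_lower = sum(decay_weight(a, model, k = model$k + model$sigma_k)) / n,
       decayed_upper = sum(decay_weight(a, model, k = max(model$k - model$sigma_k, 0))) / n,
       n_exported = length(a), n_released = n)
}

#' Monthly decomposition of the decayed export
#'
#' Decayed export mass attributed to the calendar month of each particle's
#' first crossing (release-month attribution available as a toggle). The
#' monthly percentages sum exactly to the annual decayed export percentage.
#'
#' @param traj a trajectory set.
#' @param model a [decay_model()].
#' @param level depth level (m).
#' @param by attribute mass to the `"crossing"` (default) or `"release"`
#'   month.
#' @return data.frame with `month` (`"YYYY-MM"`) and `percent` (of total
#'   released mass).
#' @export
monthly_export <- function(traj, model = decay_model(), level = 200,
                           by = c("crossing", "release")) {
  by <- match.arg(by)
  cr <- first_crossing(traj, level)
  n <- nrow(traj$x)
  sel <- cr$crossed
  w <- decay_weight(cr$age_days[sel], model)
  month <- if (by == "crossing") format(cr$time[sel], "%Y-%m")
           else format(traj$release$t_release[sel], "%Y-%m")
  if (!length(w)) return(data.frame(month = character(), percent = numeric()))
  agg <- stats::aggregate(w, by = list(month = month), FUN = sum)
  data.frame(month = agg$month, percent = 100 * agg$x / n)
}

#' Per-pixel contribution of kelp reefs to the decayed export
#'
#' Decayed exported mass grouped by release grid cell, expressed per mille
#' of the total released mass; the raster total equals
#' `1000 x` the annual decayed export fraction.
#'
#' @param traj a trajectory set.
#' @param model a [decay_model()].
#' @param level depth level (m).
#' @return data.frame with `cell_i`, `cell_j`, cell-centre `x`, `y` (m),
#'   `n_released`, and `per_mille`.
#' @export
pixel_contribution <- function(traj, model = decay_model(), level = 200) {
  cr <- first_crossing(traj, level)
  n <- nrow(traj$x)
  w <- numeric(n)
  w[cr$crossed] <- decay_weight(cr$age_days[cr$crossed], model)
  agg <- stats::aggregate(data.frame(per_mille = 1000 * w / n, n_released = 1L),
                   by = list(cell_i = traj$release$cell_i,
                             cell_j = traj$release$cell_j),
                   FUN = sum)
  agg$x <- traj$grid$x[agg$cell_i]
  agg$y <- traj$grid$y[agg$cell_j]
  agg[order(agg$cell_j, agg$cell_i),
      c("cell_i", "cell_j", "x", "y", "n_released", "per_mille")]
}

#' Pearson correlation between monthly export and DSWT suitability
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t-transform with `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param monthly_export numeric vector (e.g. percent exported per month).
#' @param monthly_suitability numeric vector of the same length (percent of
#'   time suitable per month).
#' @return list with `r` and `p_value`.
#' @export
export_suitability_correlation <- function(monthly_export, monthly_suitability) {
  if (length(monthly_export) != length(monthly_suitability) ||
      length(monthly_export) < 3) {
    stop("export_suitability_correlation: need >= 3 paired monthly values",
         call. = FALSE)
  }
  if (stats::var(monthly_export) == 0 || stats::var(monthly_suitability) == 0) {
    stop("export_suitability_correlation: zero variance, correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(monthly_export, monthly_suitability, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
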