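#' Daily release weights from a monthly detrital-production curve
#'
#' Spreads relative monthly detrital production onto days: every day of a
#' month carries that month's value, and the daily weights are normalized to
#' sum to one over the year. The default curve approximates the seasonal
#' cycle of golden kelp detrital production: elevated from March to August
#' with a March-May peak, low over the austral summer.
#'
#' @param monthly 12 non-negative relative production values (Jan..Dec).
#' @param year calendar year the weights apply to.
#' @return numeric vector with one weight per day of `year`, summing to 1,
#'   with the dates as names.
#' @export
seasonal_weights <- function(monthly = default_production_curve(), year = 2017) {
  if (length(monthly) != 12 || any(monthly < 0) || all(monthly == 0)) {
    stop("seasonal_weights: need 12 non-negative monthly values, not all zero",
         call. = FALSE)
  }
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  w <- monthly[as.POSIXlt(days)$mon + 1L]
  w <- w / sum(w)
  names(w) <- format(days)
  w
}

#' @rdname seasonal_weights
#' @export
default_production_curve <- function() {
  c(0.3, 0.35, 1.0, 1.0, 1.0, 0.8, 0.8, 0.7, 0.45, 0.35, 0.3, 0.3)
}

#' Sample release positions from a kelp probability raster
#'
#' Cells are drawn with probability proportional to their kelp probability
#' (with replacement); positions are then uniform within the chosen cell
#' (each grid node owns a `dx` x `dx` cell centred on it, clipped to the
#' domain). Reproducible from `seed`.
#'
#' @param prob kelp probability matrix on the grid of `bathy`.
#' @param bathy the [bathymetry_grid()] the raster lives on.
#' @param n number of positions to draw.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return data.frame with `x`, `y` (m) and the source cell indices
#'   `cell_i`, `cell_j`.
#' @export
sample_positions <- function(prob, bathy, n, seed = NULL) {
  p <- as.numeric(prob)
  if (all(p <= 0)) stop("sample_positions: probability raster has no positive mass",
                        call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  nx <- length(bathy$x)
  dx <- diff(bathy$x[1:2]); dy <- diff(bathy$y[1:2])
  cells <- sample.int(length(p), n, replace = TRUE, prob = p)
  ci <- ((cells - 1L) %% nx) + 1L
  cj <- ((cells - 1L) %/% nx) + 1L
  x <- bathy$x[ci] + stats::runif(n, -dx / 2, dx / 2)
  y <- bathy$y[cj] + stats::runif(n, -dy / 2, dy / 2)
  x <- pmin(pmax(x, bathy$x[1]), bathy$x[nx])
  y <- pmin(pmax(y, bathy$y[1]), bathy$y[length(bathy$y)])
  data.frame(x = x, y = y, cell_i = ci, cell_j = cj)
}

#' Build a daily particle-release schedule
#'
#' Converts a kelp probability raster and a monthly production curve into a
#' daily release schedule: daily counts apportion the total particle budget
#' over [seasonal_weights()] by the largest-remainder method (counts sum to
#' the budget exactly; ties broken by earliest date), and positions are
#' sampled per day with [sample_positions()].
#'
#' @param prob kelp probability matrix.
#' @param bathy the [bathymetry_grid()].
#' @param total total particle budget (> 0).
#' @param monthly monthly production curve (see [seasonal_weights()]).
#' @param year release year.
#' @param from,to optional release window (`Date`); weights outside the
#'   window are zeroed and the remainder renormalized, so the full budget is
#'   still released.
#' @param seed integer seed.
#' @return An object of class `release_schedule`: list with `days`
#'   (data.frame `date`, `count`), `positions` (data.frame `date`, `x`, `y`,
#'   `cell_i`, `cell_j`), `total` and `seed`.
#' @export
build_schedule <- function(prob, bathy, total,
                           monthly = default_production_curve(),
                           year = 2017, from = NULL, to = NULL, seed = 1L) {
  if (total <= 0) stop("build_schedule: total must be positive", call. = FALSE)
  w <- seasonal_weights(monthly, year)
  if (!is.null(from) || !is.null(to)) {
    dates <- as.Date(names(w))
    if (!is.null(from)) w[dates < as.Date(from)] <- 0
    if (!is.null(to)) w[dates > as.Date(to)] <- 0
    if (all(w == 0)) stop("build_schedule: release window excludes all days",
                          call. = FALSE)
    w <- w / sum(w)
  }
  counts <- largest_remainder(total * w)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pos_list <- vector("list", length(w))
  for (d in which(counts > 0)) {
    pts <- sample_positions(prob, bathy, counts[d], seed = NULL)
    pts$date <- as.Date(names(w)[d])
    pos_list[[d]] <- pts
  }
  positions <- do.call(rbind, pos_list[!vapply(pos_list, is.null, TRUE)])
  rownames(positions) <- NULL
  structure(list(days = data.frame(date = as.Date(names(w)), count = counts),
                 positions = positions[, c("date", "x", "y", "cell_i", "cell_j")],
                 total = as.integer(total), seed = as.integer(seed)),
            class = "release_schedule")
}

#' @export
print.release_schedule <- function(x, ...) {
  cat(sprintf("<release_schedule> %d particles over %d days (%s .. %s)\n",
              x$total, sum(x$days$count > 0),
              format(min(x$days$date)), format(max(x$days$date))))
  invisible(x)
}

# integer apportionment: floor everything, then hand out the remaining units
# in order of decreasing fractional remainder (earliest index wins ties)
largest_remainder <- function(target) {
  base <- floor(target)
  shortfall <- round(sum(target)) - sum(base)
  if (shortfall > 0) {
    extra <- order(target - base, seq_along(target) * -1, decreasing = TRUE)[seq_len(shortfall)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
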