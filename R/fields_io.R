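#' Write a forcing series to CF-style NetCDF
#'
#' Layout: dimensions `x`, `y`, `time` (plus `layer` if full sigma-layer
#' velocity is supplied elsewhere); variables `depth(x,y)`, `land_mask(x,y)`,
#' `u_bottom`, `v_bottom`, `rho_bottom`, `rho_surface` on `(x,y,time)`, and
#' `wind_speed(time)`, `wind_dir(time)`, `kelp_prob(x,y)` (optional). Time is
#' stored as hours since the first snapshot. All floating-point variables are
#' stored as doubles so a write/read cycle is bit-identical.
#'
#' @param fields a [field_series()].
#' @param path output file path (`.nc`).
#' @param kelp_prob optional kelp probability raster to store alongside.
#' @return `path`, invisibly.
#' @export
write_fields_nc <- function(fields, path, kelp_prob = NULL) {
  grid <- fields$grid
  t0 <- fields$time[1]
  tunits <- paste("hours since", format(t0, "%Y-%m-%d %H:%M:%S", tz = "UTC"), "UTC")
  dim_x <- ncdf4::ncdim_def("x", "m", grid$x)
  dim_y <- ncdf4::ncdim_def("y", "m", grid$y)
  dim_t <- ncdf4::ncdim_def("time", tunits,
                            as.numeric(fields$time - t0, units = "hours"),
                            unlim = TRUE)
  d2 <- list(dim_x, dim_y); d3 <- list(dim_x, dim_y, dim_t)
  vars <- list(
    ncdf4::ncvar_def("depth", "m", d2, prec = "double"),
    ncdf4::ncvar_def("land_mask", "1", d2, prec = "integer"),
    ncdf4::ncvar_def("u_bottom", "m s-1", d3, missval = 1e30, prec = "double"),
    ncdf4::ncvar_def("v_bottom", "m s-1", d3, missval = 1e30, prec = "double"),
    ncdf4::ncvar_def("rho_bottom", "kg m-3", d3, missval = 1e30, prec = "double"),
    ncdf4::ncvar_def("rho_surface", "kg m-3", d3, missval = 1e30, prec = "double"),
    ncdf4::ncvar_def("wind_speed", "m s-1", list(dim_t), prec = "double"),
    ncdf4::ncvar_def("wind_dir", "degrees", list(dim_t), prec = "double"))
  if (!is.null(kelp_prob)) {
    vars <- c(vars, list(ncdf4::ncvar_def("kelp_prob", "1", d2, prec = "double")))
  }
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, "depth", grid$depth)
  ncdf4::ncvar_put(nc, "land_mask", grid$land + 0L)
  # `+ 0` passes fresh copies: ncvar_put substitutes the missing value for
  # NA in place, which must not corrupt the in-memory series
  ncdf4::ncvar_put(nc, "u_bottom", fields$u + 0)
  ncdf4::ncvar_put(nc, "v_bottom", fields$v + 0)
  ncdf4::ncvar_put(nc, "rho_bottom", fields$rho_bottom + 0)
  ncdf4::ncvar_put(nc, "rho_surface", fields$rho_surface + 0)
  ncdf4::ncvar_put(nc, "wind_speed", fields$wind_speed)
  ncdf4::ncvar_put(nc, "wind_dir", fields$wind_dir)
  ncdf4::ncatt_put(nc, "wind_dir", "convention",
                   "meteorological direction-from, degrees clockwise from north")
  ncdf4::ncatt_put(nc, 0, "periodic_y", grid$periodic_y + 0L)
  if (!is.null(kelp_prob)) ncdf4::ncvar_put(nc, "kelp_prob", kelp_prob)
  invisible(path)
}

#' Load a forcing series from a CF-style NetCDF file
#'
#' Reads files written by [write_fields_nc()], or foreign files after
#' renaming through `var_map`. If the velocity variables carry a fourth
#' (sigma-layer) dimension, the deepest layer is extracted as the bottom
#' layer: layers are assumed ordered surface to bed unless a `layer_depth`
#' variable identifies the deepest one.
#'
#' @param path NetCDF file path.
#' @param var_map named character vector mapping the expected variable names
#'   (names) to the names used in the file (values), e.g.
#'   `c(u_bottom = "uo")`.
#' @return A [field_series()] (with `kelp_prob` attached as an attribute when
#'   the file carries it).
#' @export
load_fields <- function(path, var_map = character()) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  name_of <- function(v) if (v %in% names(var_map)) var_map[[v]] else v
  need <- c("depth", "land_mask", "u_bottom", "v_bottom",
            "rho_bottom", "rho_surface", "wind_speed", "wind_dir")
  have <- names(nc$var)
  for (v in need) {
    if (!name_of(v) %in% have) {
      stop("load_fields: required variable '", name_of(v), "' missing from ",
           path, call. = FALSE)
    }
  }
  gx <- nc$dim$x$vals; gy <- nc$dim$y$vals
  if (is.null(gx) || is.null(gy)) stop("load_fields: x/y dimensions missing", call. = FALSE)
  tvals <- nc$dim$time$vals
  if (any(diff(tvals) <= 0)) stop("load_fields: non-monotone time axis", call. = FALSE)
  tunits <- nc$dim$time$units
  origin <- sub("^hours since ", "", tunits)
  origin <- sub(" UTC$", "", origin)
  time <- as.POSIXct(origin, tz = "UTC") + tvals * 3600

  depth <- ncdf4::ncvar_get(nc, name_of("depth"), collapse_degen = FALSE)[, , drop = TRUE]
  land <- ncdf4::ncvar_get(nc, name_of("land_mask"), collapse_degen = FALSE)[, , drop = TRUE] > 0
  periodic <- ncdf4::ncatt_get(nc, 0, "periodic_y")
  grid <- bathymetry_grid(gx, gy, depth, land,
                          periodic_y = isTRUE(periodic$hasatt) && periodic$value > 0)

  get3 <- function(v) {
    a <- ncdf4::ncvar_get(nc, name_of(v), collapse_degen = FALSE)
    if (length(dim(a)) == 4L) a <- extract_bottom_layer(nc, name_of(v), a)
    dim(a) <- c(length(gx), length(gy), length(tvals))
    a
  }
  u <- get3("u_bottom"); v <- get3("v_bottom")
  rb <- get3("rho_bottom"); rs <- get3("rho_surface")
  shape_ok <- function(a) all(dim(a) == c(length(gx), length(gy), length(time)))
  for (nm in c("u", "v", "rb", "rs")) {
    if (!shape_ok(get(nm))) stop("load_fields: shape mismatch in gridded variable", call. = FALSE)
  }
  fs <- field_series(time, u, v, rb, rs,
                     ncdf4::ncvar_get(nc, name_of("wind_speed")),
                     ncdf4::ncvar_get(nc, name_of("wind_dir")),
                     grid)
  if (name_of("kelp_prob") %in% have) {
    kp <- ncdf4::ncvar_get(nc, name_of("kelp_prob"), collapse_degen = FALSE)[, , drop = TRUE]
    attr(fs, "kelp_prob") <- matrix(kp, length(gx), length(gy))
  }
  fs
}

# pick the deepest sigma layer from an [x, y, layer, time] (or
# [x, y, time, layer]) velocity array
extract_bottom_layer <- function(nc, varname, a) {
  dims <- nc$var[[varname]]$dim
  dn <- vapply(dims, `[[`, "", "name")
  li <- which(dn == "layer")
  if (length(li) != 1L) stop("load_fields: cannot identify layer dimension", call. = FALSE)
  nl <- dim(a)[li]
  bottom <- nl
  if ("layer_depth" %in% names(nc$var)) {
    bottom <- which.max(ncdf4::ncvar_get(nc, "layer_depth"))
  }
  idx <- lapply(dim(a), seq_len)
  idx[[li]] <- bottom
  out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  d <- dim(out)
  array(out, d[-li])
}
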