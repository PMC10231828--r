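#' Monthly gridded ocean field
#'
#' In-memory container for a single-depth, monthly field on a regular
#' latitude/longitude grid, the substrate from which otolith-oxygen
#' isoscapes are built. Values are stored as a 3-d array indexed
#' `[lat, lon, time]`; invalid (land) cells are `NA` and must be `NA`
#' consistently across all time slices.
#'
#' @param lat Numeric vector of cell-center latitudes, degrees North,
#'   strictly ascending and regularly spaced.
#' @param lon Numeric vector of cell-center longitudes, degrees East in
#'   `[-180, 180)`, strictly ascending and regularly spaced.
#' @param time Data frame with integer columns `year` and `month`
#'   identifying each time slice.
#' @param values Numeric array of dimension
#'   `c(length(lat), length(lon), nrow(time))`.
#' @param variable One of `"temperature"`, `"salinity"`,
#'   `"d18o_seawater"`, `"d18o_otolith"`.
#'
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(lat, lon, time, values,
                          variable = c("temperature", "salinity",
                                       "d18o_seawater", "d18o_otolith")) {
  variable <- match.arg(variable)
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  check_regular_axis(lat, "lat")
  check_regular_axis(lon, "lon")
  if (any(lon < -180 | lon >= 180))
    stop("`lon` must lie in [-180, 180)", call. = FALSE)
  if (!is.data.frame(time) || !all(c("year", "month") %in% names(time)))
    stop("`time` must be a data frame with columns year, month", call. = FALSE)
  if (any(time$month < 1 | time$month > 12))
    stop("months must be in 1..12", call. = FALSE)
  values <- as.array(values)
  expected <- c(length(lat), length(lon), nrow(time))
  if (!identical(dim(values), as.integer(expected)))
    stop(sprintf("`values` must have dim [%s], got [%s]",
                 paste(expected, collapse = " x "),
                 paste(dim(values), collapse = " x ")), call. = FALSE)
  structure(
    list(lat = lat, lon = lon, time = time,
         values = values, variable = variable),
    class = "gridded_field"
  )
}

check_regular_axis <- function(x, name) {
  if (length(x) < 2) stop(sprintf("`%s` needs >= 2 cells", name), call. = FALSE)
  d <- diff(x)
  if (any(d <= 0)) stop(sprintf("`%s` must be strictly ascending", name), call. = FALSE)
  if (diff(range(d)) > 1e-6 * mean(d))
    stop(sprintf("`%s` must be regularly spaced", name), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %s: %d lat x %d lon x %d months (%d-%02d .. %d-%02d)\n",
              x$variable, length(x$lat), length(x$lon), nrow(x$time),
              x$time$year[1], x$time$month[1],
              x$time$year[nrow(x$time)], x$time$month[nrow(x$time)]))
  valid <- sum(!is.na(x$values[, , 1]))
  cat(sprintf("  valid cells per slice: %d / %d\n",
              valid, length(x$lat) * length(x$lon)))
  invisible(x)
}

#' Test whether two grids share lat/lon axes
#' @param a,b `gridded_field`, `isoscape`, or objects with `lat`/`lon`.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

stop_grid_mismatch <- function(what) {
  stop(sprintf("grid mismatch between %s: inputs must be pre-aligned, no regridding is performed",
               what), call. = FALSE)
}

#' Region mask on a gridded-field lat/lon grid
#'
#' @param lat,lon Grid axes (as in [gridded_field()]).
#' @param mask Logical matrix `[lat, lon]`; `TRUE` marks cells inside
#'   the region.
#' @param name Optional region name.
#' @return A `region_mask` object.
#' @export
region_mask <- function(lat, lon, mask, name = NULL) {
  mask <- as.matrix(mask)
  if (!identical(dim(mask), c(length(lat), length(lon))))
    stop("`mask` must be [length(lat) x length(lon)]", call. = FALSE)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 mask = mask, name = name),
            class = "region_mask")
}

#' Rectangular (lat/lon box) region mask
#'
#' Convenience constructor marking all cells whose centers fall inside a
#' box, used e.g. for the freshwater-plume mixing-line domain and for
#' simple subregion partitions.
#'
#' @inheritParams region_mask
#' @param lat_range,lon_range Length-2 numeric, inclusive bounds.
#' @return A `region_mask`.
#' @export
box_mask <- function(lat, lon, lat_range, lon_range, name = NULL) {
  m <- outer(lat >= lat_range[1] & lat <= lat_range[2],
             lon >= lon_range[1] & lon <= lon_range[2], `&`)
  region_mask(lat, lon, m, name = name)
}

#' Complement of a region mask within an optional domain
#' @param x A `region_mask`.
#' @param within Optional `region_mask` restricting the complement.
#' @return A `region_mask`.
#' @export
mask_complement <- function(x, within = NULL) {
  m <- !x$mask
  if (!is.null(within)) {
    if (!same_grid(x, within)) stop_grid_mismatch("mask and domain")
    m <- m & within$mask
  }
  region_mask(x$lat, x$lon, m,
              name = if (!is.null(x$name)) paste0("not_", x$name))
}

#' Intersection of region masks
#' @param ... Two or more `region_mask` objects on the same grid.
#' @return A `region_mask`.
#' @export
mask_intersect <- function(...) {
  ms <- list(...)
  out <- ms[[1]]$mask
  for (m in ms[-1]) {
    if (!same_grid(ms[[1]], m)) stop_grid_mismatch("masks")
    out <- out & m$mask
  }
  region_mask(ms[[1]]$lat, ms[[1]]$lon, out)
}

#' Read a monthly T/S field from a netCDF file
#'
#' Expects dimensions named `lat`/`latitude`, `lon`/`longitude`, and
#' `time` with time units `"months since <year>-01"` or explicit
#' `year`/`month` auxiliary variables as written by
#' [write_field_ncdf()]. Units are checked: temperature must be declared
#' in degrees Celsius, salinity as PSU (or unitless `1`).
#'
#' @param path Path to a netCDF file.
#' @param variable Variable name in the file (also the field type).
#' @return A [gridded_field()].
#' @export
read_field_ncdf <- function(path, variable) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  dimnames_nc <- names(nc$dim)
  latname <- intersect(c("lat", "latitude"), dimnames_nc)[1]
  lonname <- intersect(c("lon", "longitude"), dimnames_nc)[1]
  if (is.na(latname) || is.na(lonname))
    stop("netCDF file lacks lat/lon dimensions", call. = FALSE)
  lat <- as.numeric(nc$dim[[latname]]$vals)
  lon <- as.numeric(nc$dim[[lonname]]$vals)
  year <- as.integer(ncdf4::ncvar_get(nc, "year"))
  month <- as.integer(ncdf4::ncvar_get(nc, "month"))
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  units <- ncdf4::ncatt_get(nc, variable, "units")$value
  if (variable == "temperature" &&
      !units %in% c("degC", "degrees_Celsius", "celsius"))
    stop(sprintf("temperature units must be degC, got '%s'", units),
         call. = FALSE)
  if (variable == "salinity" && !units %in% c("PSU", "psu", "1"))
    stop(sprintf("salinity units must be PSU, got '%s'", units),
         call. = FALSE)
  # file layout is [lon, lat, time]; internal layout is [lat, lon, time]
  vals <- aperm(vals, c(2, 1, 3))
  gridded_field(lat, lon, data.frame(year = year, month = month),
                vals, variable = variable)
}

#' Write a gridded field to netCDF
#'
#' @param field A [gridded_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_ncdf <- function(field, path) {
  units <- switch(field$variable,
                  temperature = "degC",
                  salinity = "PSU",
                  d18o_seawater = "permil_VSMOW",
                  d18o_otolith = "permil_VPDB")
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dtime <- ncdf4::ncdim_def("time", "month_index",
                            seq_len(nrow(field$time)), unlim = TRUE)
  vvar <- ncdf4::ncvar_def(field$variable, units, list(dlon, dlat, dtime),
                           missval = NA_real_, prec = "double")
  vyear <- ncdf4::ncvar_def("year", "year", dtime, prec = "integer")
  vmonth <- ncdf4::ncvar_def("month", "month", dtime, prec = "integer")
  nc <- ncdf4::nc_create(path, list(vvar, vyear, vmonth))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vvar, aperm(field$values, c(2, 1, 3)))
  ncdf4::ncvar_put(nc, vyear, field$time$year)
  ncdf4::ncvar_put(nc, vmonth, field$time$month)
  invisible(path)
}
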