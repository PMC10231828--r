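#' Salinity-to-seawater-oxygen mixing line
#'
#' Empirical linear relation between salinity and seawater oxygen
#' isotope ratio for one water mass, applied only inside its region
#' mask. The shipped defaults are the open Northwest Atlantic relation
#' (slope 0.55, intercept -18.98) and the Gulf of St. Lawrence relation
#' (slope 0.27, intercept -10.3), where the St. Lawrence freshwater flux
#' produces a distinct mixing behaviour.
#'
#' @param slope Per-mil VSMOW per salinity unit.
#' @param intercept Per-mil VSMOW.
#' @param region_mask A [region_mask()] delimiting where the line holds.
#' @param name Optional label.
#' @return A `mixing_line`.
#' @export
mixing_line <- function(slope, intercept, region_mask, name = NULL) {
  stopifnot(is.finite(slope), is.finite(intercept),
            inherits(region_mask, "region_mask"))
  structure(list(slope = slope, intercept = intercept,
                 region_mask = region_mask, name = name),
            class = "mixing_line")
}

#' Default mixing-line coefficients
#'
#' @return Named list of slope/intercept pairs for the open North
#'   Atlantic and the Gulf of St. Lawrence water masses.
#' @export
default_mixing_coefficients <- function() {
  list(north_atlantic = list(slope = 0.55, intercept = -18.98),
       gulf_st_lawrence = list(slope = 0.27, intercept = -10.3))
}

#' Linear aragonite oxygen fractionation model
#'
#' Relates otolith aragonite oxygen isotope ratio (VPDB) to ambient
#' temperature and seawater ratio (VSMOW):
#' `d18o_oto = gamma * T + beta + d18o_seawater`. The default
#' coefficients are the chub mackerel (*Scomber japonicus*) calibration,
#' gamma = -0.25 permil/degC, beta = 4.46 permil; the additive VSMOW/
#' VPDB convention is taken as the calibration defines it, with no
#' further scale conversion.
#'
#' @param gamma Per-mil per degree Celsius (negative: warmer water
#'   lowers the otolith ratio).
#' @param beta Per-mil intercept.
#' @param species Label for provenance.
#' @return A `fractionation_model`.
#' @export
fractionation_model <- function(gamma = -0.25, beta = 4.46,
                                species = "chub_mackerel") {
  stopifnot(is.finite(gamma), is.finite(beta))
  structure(list(gamma = gamma, beta = beta, species = species),
            class = "fractionation_model")
}

#' Seawater oxygen isotope field from salinity
#'
#' Applies each mixing line inside its region mask. The masks must
#' partition the valid (non-missing) salinity cells: any valid cell
#' covered by zero or by two or more lines is an error. Missing salinity
#' stays missing.
#'
#' @param salinity A salinity [gridded_field()].
#' @param lines List of [mixing_line()]s on the same grid.
#' @return A `d18o_seawater` [gridded_field()].
#' @export
seawater_d18o <- function(salinity, lines) {
  stopifnot(inherits(salinity, "gridded_field"),
            salinity$variable == "salinity", length(lines) >= 1)
  cover <- matrix(0L, length(salinity$lat), length(salinity$lon))
  for (ln in lines) {
    if (!same_grid(salinity, ln$region_mask))
      stop_grid_mismatch("salinity and mixing-line mask")
    cover <- cover + ln$region_mask$mask
  }
  valid <- !is.na(salinity$values[, , 1])
  bad <- valid & cover != 1L
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    shown <- utils::head(sprintf("(%.1f, %.1f)x%d",
                                 salinity$lat[idx[, 1]],
                                 salinity$lon[idx[, 2]],
                                 cover[bad]), 5)
    stop("mixing-line masks must cover each valid cell exactly once; offending cells (lat, lon)xcover: ",
         paste(shown, collapse = ", "), call. = FALSE)
  }
  out <- salinity$values
  slope <- matrix(NA_real_, length(salinity$lat), length(salinity$lon))
  icept <- slope
  for (ln in lines) {
    slope[ln$region_mask$mask] <- ln$slope
    icept[ln$region_mask$mask] <- ln$intercept
  }
  for (t in seq_len(dim(out)[3])) {
    out[, , t] <- slope * salinity$values[, , t] + icept
  }
  gridded_field(salinity$lat, salinity$lon, salinity$time, out,
                variable = "d18o_seawater")
}

#' Otolith oxygen isotope field from temperature and seawater field
#'
#' Applies the linear fractionation equation cell-wise:
#' `gamma * T + beta + d18o_seawater`.
#'
#' @param temperature Temperature [gridded_field()] (degC).
#' @param d18o_sw Seawater field from [seawater_d18o()].
#' @param frac A [fractionation_model()].
#' @return A `d18o_otolith` [gridded_field()].
#' @export
otolith_d18o <- function(temperature, d18o_sw, frac = fractionation_model()) {
  stopifnot(inherits(temperature, "gridded_field"),
            temperature$variable == "temperature",
            d18o_sw$variable == "d18o_seawater",
            inherits(frac, "fractionation_model"))
  if (!same_grid(temperature, d18o_sw) ||
      !identical(dim(temperature$values), dim(d18o_sw$values)))
    stop_grid_mismatch("temperature and seawater fields")
  vals <- frac$gamma * temperature$values + frac$beta + d18o_sw$values
  gridded_field(temperature$lat, temperature$lon, temperature$time, vals,
                variable = "d18o_otolith")
}

#' Seasonal (multi-month) average of a gridded field
#'
#' Arithmetic mean over `n_months` consecutive calendar months of one
#' year. In strict mode a cell missing in any requested month is missing
#' in the mean; in lenient mode the mean of the available months is
#' used.
#'
#' @param field A [gridded_field()].
#' @param year Calendar year.
#' @param start_month First month of the season (1-12).
#' @param n_months Number of consecutive months (default 3).
#' @param strict Missing-month handling (default `TRUE`).
#' @return Numeric matrix `[lat, lon]` of seasonal means.
#' @export
seasonal_average <- function(field, year, start_month, n_months = 3,
                             strict = TRUE) {
  stopifnot(inherits(field, "gridded_field"))
  months <- start_month + seq_len(n_months) - 1L
  if (any(months > 12))
    stop("season must stay within one calendar year", call. = FALSE)
  slabs <- lapply(months, function(m) {
    t <- which(field$time$year == year & field$time$month == m)
    if (!length(t))
      stop(sprintf("missing month slab %d-%02d in %s field",
                   year, m, field$variable), call. = FALSE)
    field$values[, , t[1]]
  })
  arr <- simplify2array(slabs)
  if (strict) {
    apply(arr, c(1, 2), function(v) if (anyNA(v)) NA_real_ else mean(v))
  } else {
    m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_
    m
  }
}

#' Contingent growing seasons
#'
#' Three consecutive months from each contingent's peak spawning date:
#' May-July for the southern contingent, June-August for the northern.
#'
#' @param contingent `"northern"` or `"southern"`.
#' @return Integer vector of three months.
#' @export
contingent_season <- function(contingent = c("southern", "northern")) {
  contingent <- match.arg(contingent)
  if (contingent == "southern") 5:7 else 6:8
}

#' Build a per-year, per-contingent otolith-oxygen isoscape
#'
#' Temperature and seawater oxygen ratio are first averaged over the
#' contingent's three-month growing season, then the fractionation
#' equation is applied to the seasonal means (equivalent to per-month
#' application, since the equation is linear). The isoscape domain is
#' the intersection of the contingent's region mask, the
#' continental-shelf mask, and cells with valid data.
#'
#' @param temperature,salinity Monthly [gridded_field()]s for the year.
#' @param year Calendar year of the isoscape.
#' @param contingent `"northern"` or `"southern"`.
#' @param lines List of [mixing_line()]s (see [seawater_d18o()]).
#' @param frac A [fractionation_model()].
#' @param domain_mask Contingent region [region_mask()].
#' @param shelf_mask Continental-shelf [region_mask()].
#' @param strict Missing-month handling for [seasonal_average()].
#' @return An `isoscape`: `year`, `contingent`, `months`, `values`
#'   matrix `[lat, lon]` (NA outside the domain), logical `mask`,
#'   `lat`, `lon`.
#' @export
build_isoscape <- function(temperature, salinity, year,
                           contingent = c("southern", "northern"),
                           lines, frac = fractionation_model(),
                           domain_mask, shelf_mask, strict = TRUE) {
  contingent <- match.arg(contingent)
  if (!same_grid(temperature, salinity))
    stop_grid_mismatch("temperature and salinity")
  if (!same_grid(temperature, domain_mask) ||
      !same_grid(temperature, shelf_mask))
    stop_grid_mismatch("fields and masks")
  months <- contingent_season(contingent)
  d18o_sw <- seawater_d18o(salinity, lines)
  t_bar <- seasonal_average(temperature, year, months[1], length(months),
                            strict = strict)
  sw_bar <- seasonal_average(d18o_sw, year, months[1], length(months),
                             strict = strict)
  vals <- frac$gamma * t_bar + frac$beta + sw_bar
  mask <- domain_mask$mask & shelf_mask$mask & !is.na(vals)
  if (!any(mask))
    stop("empty isoscape domain: no valid cells inside domain and shelf masks",
         call. = FALSE)
  vals[!mask] <- NA_real_
  structure(list(year = as.integer(year), contingent = contingent,
                 months = months, values = vals, mask = mask,
                 lat = temperature$lat, lon = temperature$lon),
            class = "isoscape")
}

#' @export
print.isoscape <- function(x, ...) {
  rng <- range(x$values[x$mask])
  cat(sprintf("<isoscape> %s %d (months %s): %d defined cells, range %.2f .. %.2f permil VPDB\n",
              x$contingent, x$year, paste(x$months, collapse = "-"),
              sum(x$mask), rng[1], rng[2]))
  invisible(x)
}

#' Write an isoscape raster to netCDF
#' @param iso An `isoscape`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isoscape_ncdf <- function(iso, path) {
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", iso$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", iso$lat)
  v <- ncdf4::ncvar_def("d18o_otolith", "permil_VPDB", list(dlon, dlat),
                        missval = NA_real_, prec = "double")
  vm <- ncdf4::ncvar_def("domain_mask", "1", list(dlon, dlat),
                         prec = "integer")
  nc <- ncdf4::nc_create(path, list(v, vm))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, t(iso$values))
  ncdf4::ncvar_put(nc, vm, t(iso$mask * 1L))
  ncdf4::ncatt_put(nc, 0, "year", iso$year)
  ncdf4::ncatt_put(nc, 0, "contingent", iso$contingent)
  ncdf4::ncatt_put(nc, 0, "months", paste(iso$months, collapse = ","))
  invisible(path)
}

#' Read an isoscape raster written by [write_isoscape_ncdf()]
#' @param path netCDF path.
#' @return An `isoscape`.
#' @export
read_isoscape_ncdf <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(nc$dim$lat$vals)
  lon <- as.numeric(nc$dim$lon$vals)
  vals <- t(ncdf4::ncvar_get(nc, "d18o_otolith"))
  mask <- t(ncdf4::ncvar_get(nc, "domain_mask")) == 1L
  year <- ncdf4::ncatt_get(nc, 0, "year")$value
  contingent <- ncdf4::ncatt_get(nc, 0, "contingent")$value
  months <- as.integer(strsplit(ncdf4::ncatt_get(nc, 0, "months")$value,
                                ",")[[1]])
  vals[!mask] <- NA_real_
  structure(list(year = as.integer(year), contingent = contingent,
                 months = months, values = vals, mask = mask,
                 lat = lat, lon = lon),
            class = "isoscape")
}
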