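#' Configuration for the synthetic study system
#'
#' Defines a two-contingent study system with the statistical structure
#' the framework assumes: bivariate-normal otolith isotope baselines per
#' contingent and year-class (northern lower in oxygen, higher in
#' carbon), a 1-degree monthly ocean grid with a latitudinal temperature
#' gradient, a seasonal cycle, seeded interannual anomalies, and a
#' low-salinity plume region governed by its own mixing line. Contingent
#' mean separation is scalable per year-class to emulate weakly
#' separated cohorts.
#'
#' @param seed Master seed; all generators are pure functions of
#'   (config, seed).
#' @param year_classes Integer cohort years.
#' @param n_southern,n_northern Baseline sample size per year-class and
#'   contingent (unequal by default, so oversampling has work to do).
#' @param mean_southern,mean_northern Baseline isotope means
#'   `c(d18o, d13c)`, per-mil.
#' @param sd_d18o,sd_d13c Within-cell SDs, per-mil.
#' @param isotope_cor Within-cell correlation between the two isotopes.
#' @param separation Named numeric: per-year-class multiplier on the
#'   contingent mean difference (1 = full separation, 0 = none).
#'   Unnamed scalar applies to all year-classes.
#' @param year_class_jitter_sd SD of the shared per-year-class mean
#'   shift, per-mil.
#' @param lat,lon Grid cell centers (1-degree default, a Northwest
#'   Atlantic shelf analogue).
#' @param t_base Summer-free baseline temperature at the southern grid
#'   edge, degC.
#' @param t_lat_gradient Temperature decrease per degree latitude
#'   northward, degC.
#' @param t_seasonal_amp Seasonal cycle amplitude, degC (peak in
#'   August).
#' @param t_anomaly_sd SD of the seeded per-year temperature anomaly,
#'   degC.
#' @param s_base Salinity at the southern grid edge, PSU.
#' @param s_lat_gradient Salinity change per degree latitude northward.
#' @param plume_lat,plume_lon Bounds of the low-salinity plume box (the
#'   estuarine-influenced region with its own mixing line).
#' @param plume_salinity Salinity inside the plume box, PSU.
#' @param sigma_analytical,sigma_within_pop Measurement variance
#'   components, per-mil.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 20260101,
    year_classes = c(1973, 1974, 1998:2000, 2011:2016),
    n_southern = 30, n_northern = 18,
    mean_southern = c(d18o = 1.15, d13c = -7.35),
    mean_northern = c(d18o = 0.65, d13c = -6.60),
    sd_d18o = 0.35, sd_d13c = 0.50, isotope_cor = 0,
    separation = c(`1974` = 0.3, `2016` = 0.3),
    year_class_jitter_sd = 0.15,
    lat = 36:47, lon = -76:-55,
    t_base = 22, t_lat_gradient = 1.5, t_seasonal_amp = 4,
    t_anomaly_sd = 0.5,
    s_base = 33, s_lat_gradient = -0.1,
    plume_lat = c(45, 47), plume_lon = c(-66, -60),
    plume_salinity = 28,
    sigma_analytical = 0.1, sigma_within_pop = 0.29) {
  if (length(lat) < 8 || length(lon) < 8)
    stop("synthetic grid must be at least 8 x 8", call. = FALSE)
  if (plume_lat[1] < min(lat) || plume_lat[2] > max(lat) ||
      plume_lon[1] < min(lon) || plume_lon[2] > max(lon))
    stop("plume box must lie inside the grid", call. = FALSE)
  sep <- rep(1, length(year_classes))
  names(sep) <- as.character(year_classes)
  if (!is.null(names(separation)) && any(nzchar(names(separation)))) {
    sep[names(separation)] <- separation
  } else if (length(separation) == 1) {
    sep[] <- separation
  } else {
    stop("separation must be a named vector or a scalar", call. = FALSE)
  }
  cov <- matrix(c(sd_d18o^2, isotope_cor * sd_d18o * sd_d13c,
                  isotope_cor * sd_d18o * sd_d13c, sd_d13c^2), 2)
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("isotope covariance must be positive-definite", call. = FALSE)
  structure(list(
    seed = as.integer(seed), year_classes = as.integer(year_classes),
    n_southern = n_southern, n_northern = n_northern,
    mean_southern = mean_southern, mean_northern = mean_northern,
    cov = cov, separation = sep,
    year_class_jitter_sd = year_class_jitter_sd,
    lat = as.numeric(lat), lon = as.numeric(lon),
    t_base = t_base, t_lat_gradient = t_lat_gradient,
    t_seasonal_amp = t_seasonal_amp, t_anomaly_sd = t_anomaly_sd,
    s_base = s_base, s_lat_gradient = s_lat_gradient,
    plume_lat = plume_lat, plume_lon = plume_lon,
    plume_salinity = plume_salinity,
    sigma_analytical = sigma_analytical,
    sigma_within_pop = sigma_within_pop
  ), class = "synthetic_config")
}

#' Generate a known-origin baseline
#'
#' Bivariate-normal isotope draws per contingent x year-class around the
#' configured means, with a shared per-year-class mean shift (seeded)
#' and a per-year-class separation multiplier applied to the contingent
#' difference around their midpoint.
#'
#' @param cfg A [synthetic_config()].
#' @return Otolith record data frame (age 1, known contingent).
#' @export
gen_baseline <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mid <- (cfg$mean_southern + cfg$mean_northern) / 2
  withr::with_seed(cfg$seed, {
    rows <- list()
    for (yc in cfg$year_classes) {
      jitter <- stats::rnorm(2, 0, cfg$year_class_jitter_sd)
      s <- cfg$separation[as.character(yc)]
      for (ct in c("southern", "northern")) {
        base_mean <- if (ct == "southern") cfg$mean_southern else cfg$mean_northern
        mu <- mid + s * (base_mean - mid) + jitter
        n <- if (ct == "southern") cfg$n_southern else cfg$n_northern
        xy <- MASS::mvrnorm(n, mu, cfg$cov)
        rows[[length(rows) + 1L]] <- data.frame(
          fish_id = sprintf("%s_%d_%03d", substr(ct, 1, 1), yc, seq_len(n)),
          d18o = xy[, 1], d13c = xy[, 2],
          year_class = yc, age = 1L, contingent = ct,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate unknown-origin adults
#'
#' Adults are drawn from the same per-year-class isotope distributions
#' as the baseline with a latent true contingent (kept in
#' `true_contingent` for benchmarking); their `contingent` column is
#' `"unknown"` and `collection_year = year_class + age`.
#'
#' @param cfg A [synthetic_config()].
#' @param n_per_year_class Adults per year-class.
#' @param p_northern Mixture proportion of true northern fish.
#' @return Otolith record data frame.
#' @export
gen_adults <- function(cfg, n_per_year_class = 20, p_northern = 0.4) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mid <- (cfg$mean_southern + cfg$mean_northern) / 2
  withr::with_seed(cfg$seed + 1L, {
    rows <- list()
    for (yc in cfg$year_classes) {
      jitter <- stats::rnorm(2, 0, cfg$year_class_jitter_sd)
      s <- cfg$separation[as.character(yc)]
      true_ct <- ifelse(stats::runif(n_per_year_class) < p_northern,
                        "northern", "southern")
      age <- sample(2:5, n_per_year_class, replace = TRUE)
      xy <- t(vapply(true_ct, function(ct) {
        base_mean <- if (ct == "southern") cfg$mean_southern else cfg$mean_northern
        MASS::mvrnorm(1, mid + s * (base_mean - mid) + jitter, cfg$cov)
      }, numeric(2)))
      rows[[length(rows) + 1L]] <- data.frame(
        fish_id = sprintf("a_%d_%03d", yc, seq_len(n_per_year_class)),
        d18o = xy[, 1], d13c = xy[, 2],
        year_class = yc, age = age, contingent = "unknown",
        collection_year = yc + age, true_contingent = true_ct,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

# seeded per-year temperature anomaly, stable across calls
year_anomaly <- function(cfg, year) {
  withr::with_seed(cfg$seed + 100000L + as.integer(year) %% 100000L,
                   stats::rnorm(1, 0, cfg$t_anomaly_sd))
}

synthetic_land <- function(cfg) {
  outer(cfg$lat >= 43, cfg$lon <= -70, `&`)
}

#' Generate monthly temperature and salinity fields for one year
#'
#' Temperature decreases poleward, follows a cosine seasonal cycle
#' peaking in August, and carries one seeded anomaly per year. Salinity
#' follows a weak latitudinal gradient with a fresher plume box; a
#' landmass block in the northwest corner is masked in both fields.
#'
#' @param cfg A [synthetic_config()].
#' @param year Calendar year.
#' @return List with `temperature` and `salinity` [gridded_field()]s
#'   (12 months).
#' @export
gen_ocean <- function(cfg, year) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nlat <- length(cfg$lat); nlon <- length(cfg$lon)
  land <- synthetic_land(cfg)
  anom <- year_anomaly(cfg, year)
  tvals <- array(NA_real_, c(nlat, nlon, 12))
  svals <- array(NA_real_, c(nlat, nlon, 12))
  lat_off <- cfg$lat - min(cfg$lat)
  s_field <- matrix(rep(cfg$s_base + cfg$s_lat_gradient * lat_off, nlon),
                    nlat, nlon)
  plume <- outer(cfg$lat >= cfg$plume_lat[1] & cfg$lat <= cfg$plume_lat[2],
                 cfg$lon >= cfg$plume_lon[1] & cfg$lon <= cfg$plume_lon[2],
                 `&`)
  s_field[plume] <- cfg$plume_salinity
  s_field[land] <- NA_real_
  for (m in 1:12) {
    tm <- cfg$t_base - cfg$t_lat_gradient * lat_off +
      anom + cfg$t_seasonal_amp * cos(2 * pi * (m - 8) / 12)
    tmat <- matrix(rep(tm, nlon), nlat, nlon)
    tmat[land] <- NA_real_
    tvals[, , m] <- tmat
    svals[, , m] <- s_field
  }
  time <- data.frame(year = as.integer(year), month = 1:12)
  list(temperature = gridded_field(cfg$lat, cfg$lon, time, tvals,
                                   "temperature"),
       salinity = gridded_field(cfg$lat, cfg$lon, time, svals, "salinity"))
}

#' Generate the mask set for the synthetic domain
#'
#' @param cfg A [synthetic_config()].
#' @return List of [region_mask()]s: `ocean`, `shelf`, `full` (ocean and
#'   shelf), contingent domains `southern`/`northern`, `plume`,
#'   `mixing_lines` (ready-to-use [mixing_line()] list), and
#'   `subregions` (2 x 2 block partition of the full domain, coded MAB /
#'   SNE / GOM / GB).
#' @export
gen_masks <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lat <- cfg$lat; lon <- cfg$lon
  ocean <- region_mask(lat, lon, !synthetic_land(cfg), name = "ocean")
  shelf <- region_mask(lat, lon,
                       ocean$mask & outer(rep(TRUE, length(lat)),
                                          lon <= max(lon) - 3, `&`),
                       name = "shelf")
  full <- region_mask(lat, lon, ocean$mask & shelf$mask, name = "full")
  lat_split <- stats::median(lat)
  southern <- region_mask(lat, lon,
                          full$mask & outer(lat < lat_split,
                                            rep(TRUE, length(lon)), `&`),
                          name = "southern")
  northern <- region_mask(lat, lon,
                          full$mask & outer(lat >= lat_split,
                                            rep(TRUE, length(lon)), `&`),
                          name = "northern")
  plume <- box_mask(lat, lon, cfg$plume_lat, cfg$plume_lon, name = "plume")
  coefs <- default_mixing_coefficients()
  lines <- list(
    mixing_line(coefs$gulf_st_lawrence$slope, coefs$gulf_st_lawrence$intercept,
                region_mask(lat, lon, plume$mask & ocean$mask),
                name = "plume"),
    mixing_line(coefs$north_atlantic$slope, coefs$north_atlantic$intercept,
                region_mask(lat, lon, ocean$mask & !plume$mask),
                name = "open_shelf")
  )
  lon_split <- stats::median(lon)
  quad <- function(latf, lonf, name) {
    region_mask(lat, lon,
                full$mask & outer(latf(lat), lonf(lon), `&`), name = name)
  }
  subregions <- list(
    MAB = quad(function(x) x < lat_split, function(x) x < lon_split, "MAB"),
    SNE = quad(function(x) x < lat_split, function(x) x >= lon_split, "SNE"),
    GOM = quad(function(x) x >= lat_split, function(x) x < lon_split, "GOM"),
    GB = quad(function(x) x >= lat_split, function(x) x >= lon_split, "GB")
  )
  list(ocean = ocean, shelf = shelf, full = full,
       southern = southern, northern = northern, plume = plume,
       mixing_lines = lines, subregions = subregions)
}

#' Generate known-origin validation fish from an isoscape
#'
#' True natal cells are sampled uniformly from the isoscape domain
#' (restricted to cells covered by a subregion mask); observed otolith
#' oxygen is the cell's isoscape value plus normal noise with the
#' combined measurement SD. The fish's subregion is the one containing
#' its true cell.
#'
#' @param cfg A [synthetic_config()].
#' @param iso An `isoscape`.
#' @param n Number of fish.
#' @param subregion_masks Named list of [region_mask()]s.
#' @param cells Optional integer matrix `[n, 2]` of (lat, lon) indices
#'   fixing the true cells.
#' @return Data frame `fish_id`, `d18o`, `year`, `subregion`,
#'   `true_lat_idx`, `true_lon_idx`, `mu_true`.
#' @export
gen_known_origin_fish <- function(cfg, iso, n, subregion_masks,
                                  cells = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(iso, "isoscape"),
            n >= 1)
  covered <- Reduce(`|`, lapply(subregion_masks, function(m) m$mask))
  eligible <- which(iso$mask & covered, arr.ind = TRUE)
  if (!nrow(eligible))
    stop("no isoscape cell is covered by a subregion mask", call. = FALSE)
  sigma <- combined_sigma(variance_model(cfg$sigma_analytical,
                                         cfg$sigma_within_pop))
  withr::with_seed(cfg$seed + 2L, {
    if (is.null(cells)) {
      cells <- eligible[sample.int(nrow(eligible), n, replace = TRUE), ,
                        drop = FALSE]
    }
    mu <- iso$values[cells]
    sub <- vapply(seq_len(n), function(i) {
      hits <- names(Filter(function(m) m$mask[cells[i, 1], cells[i, 2]],
                           subregion_masks))
      hits[1]
    }, character(1))
    data.frame(fish_id = sprintf("v_%d_%04d", iso$year, seq_len(n)),
               d18o = stats::rnorm(n, mu, sigma),
               year = iso$year, subregion = sub,
               true_lat_idx = cells[, 1], true_lon_idx = cells[, 2],
               mu_true = mu, stringsAsFactors = FALSE)
  })
}
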