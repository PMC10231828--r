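# Shared fixtures, built in code. Expensive objects (the fitted
# ensemble) are memoized so the suite fits its runtime budget.

.fixtures <- new.env()

tiny_config <- function(...) {
  args <- list(seed = 424242, year_classes = 2014:2016,
               n_southern = 30, n_northern = 18)
  user <- list(...)
  args[names(user)] <- user
  do.call(synthetic_config, args)
}

tiny_baseline_ds <- function() {
  if (is.null(.fixtures$ds)) {
    bl <- gen_baseline(tiny_config())
    .fixtures$ds <- standardize_baseline(oversample_balance(bl, seed = 7))
  }
  .fixtures$ds
}

tiny_ensemble <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- fit_ensemble(tiny_baseline_ds(), seed = 11,
                                    rule = list(top_k = 5))
  }
  .fixtures$model
}

tiny_world <- function() {
  if (is.null(.fixtures$world)) {
    cfg <- tiny_config()
    masks <- gen_masks(cfg)
    ocean <- gen_ocean(cfg, 2016)
    iso <- build_isoscape(ocean$temperature, ocean$salinity, 2016,
                          "southern", lines = masks$mixing_lines,
                          domain_mask = masks$full,
                          shelf_mask = masks$shelf)
    .fixtures$world <- list(cfg = cfg, masks = masks, ocean = ocean,
                            iso = iso)
  }
  .fixtures$world
}

# hand-built 1-slice field on a small grid
toy_field <- function(values, variable = "temperature",
                      lat = NULL, lon = NULL, months = 1) {
  values <- as.array(values)
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1))
  if (is.null(lat)) lat <- seq(40, by = 1, length.out = dim(values)[1])
  if (is.null(lon)) lon <- seq(-70, by = 1, length.out = dim(values)[2])
  gridded_field(lat, lon, data.frame(year = 2000L, month = months),
                values, variable = variable)
}

# minimal record table
make_records <- function(n, contingent = "southern", year_class = 2000,
                         d18o = NULL, d13c = NULL, age = 1) {
  data.frame(
    fish_id = sprintf("%s%04d", substr(contingent[1], 1, 1), seq_len(n)),
    d18o = if (is.null(d18o)) stats::rnorm(n) else d18o,
    d13c = if (is.null(d13c)) stats::rnorm(n) else d13c,
    year_class = year_class, age = age, contingent = contingent,
    stringsAsFactors = FALSE)
}

# surface with prescribed posterior values for binarization tests
surface_from_values <- function(vals_matrix, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(vals_matrix)
  p <- vals_matrix
  p[!mask] <- NA_real_
  p[mask] <- p[mask] / sum(p[mask])
  structure(list(fish_id = "toy", y = 0, posterior = p,
                 scaled = p / max(p, na.rm = TRUE), mask = mask,
                 lat = seq_len(nrow(p)), lon = seq_len(ncol(p)),
                 isoscape = list(year = 2000L, contingent = "southern")),
            class = "probability_surface")
}
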