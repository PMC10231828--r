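#' Default pipeline configuration
#'
#' One nested list mirroring the YAML schema, with the framework
#' defaults: assignment threshold tau = 0.7, binarization quantile
#' q = 0.75, 10 cross-validation folds, member accuracy cutoff 0.76,
#' May-July / June-August contingent seasons, and measurement SDs
#' 0.1 / 0.29 per-mil.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 20260101,
    baseline = list(
      max_age = list(northern = 2, southern = 1),
      equalize_year_classes = FALSE,
      strict_year_class_match = TRUE
    ),
    ensemble = list(
      folds = 10,
      rule = list(accuracy_cutoff = 0.76),
      tau = 0.7,
      classifiers = classifier_names()
    ),
    isoscape = list(
      gamma = -0.25, beta = 4.46,
      season = list(southern = 5, northern = 6)
    ),
    assignment = list(
      q = 0.75,
      sigma_analytical = 0.1,
      sigma_within_pop = 0.29,
      accuracy_floor = 0.7
    ),
    synthetic = list(
      year_classes = NULL,
      n_southern = 30, n_northern = 18,
      n_adults_per_year_class = 20,
      n_validation_fish = 100
    )
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_config()].
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_section <- function(base, upd, prefix) {
    bad <- setdiff(names(upd), names(base))
    if (length(bad))
      stop("unknown config key(s): ",
           paste(paste0(prefix, bad), collapse = ", "), call. = FALSE)
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge_section(base[[k]], upd[[k]], paste0(prefix, k, "."))
      } else upd[[k]]
    }
    base
  }
  merge_section(cfg, user, "")
}

stage_timer <- function() {
  env <- new.env()
  env$timings <- list()
  env$warnings <- character(0)
  env$run <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(expr, warning = function(w) {
      env$warnings <<- c(env$warnings,
                         sprintf("[%s] %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    env$timings[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  env
}

file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full natal-origin workflow on synthetic data
#'
#' Executes the whole chain: baseline generation, oversampling balance,
#' standardization, ensemble cross-validation and model averaging, adult
#' classification with abstention, per-year isoscape construction for
#' both contingents, per-fish posterior surfaces, binarization,
#' per-year-class summary maps, and known-origin validation with the
#' accuracy-precision sweep. Writes CSV/JSON/netCDF outputs plus a run
#' manifest with seeds, timings, warnings, and output digests.
#'
#' @param config Configuration list (see [read_config()]) or a YAML
#'   path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tm <- stage_timer()

  scfg_args <- list(
    seed = config$seed,
    n_southern = config$synthetic$n_southern,
    n_northern = config$synthetic$n_northern,
    sigma_analytical = config$assignment$sigma_analytical,
    sigma_within_pop = config$assignment$sigma_within_pop)
  if (!is.null(config$synthetic$year_classes))
    scfg_args$year_classes <- config$synthetic$year_classes
  scfg <- do.call(synthetic_config, scfg_args)

  dat <- tm$run("simulate", {
    baseline <- gen_baseline(scfg)
    adults <- gen_adults(scfg, config$synthetic$n_adults_per_year_class)
    masks <- gen_masks(scfg)
    write_otolith_csv(baseline, file.path(out_dir, "baseline.csv"))
    write_otolith_csv(adults, file.path(out_dir, "adults.csv"))
    list(baseline = baseline, adults = adults, masks = masks)
  })

  model <- tm$run("classify_fit", {
    ds <- baseline_filter(dat$baseline,
                          max_age = unlist(config$baseline$max_age))
    ds <- oversample_balance(ds, seed = config$seed,
                             equalize_year_classes =
                               config$baseline$equalize_year_classes)
    ds <- standardize_baseline(ds)
    m <- fit_ensemble(ds, classifier_registry(config$ensemble$classifiers),
                      folds = config$ensemble$folds, seed = config$seed,
                      rule = config$ensemble$rule,
                      tau = config$ensemble$tau)
    save_ensemble(m, file.path(out_dir, "model"))
    list(ds = ds, model = m)
  })

  assignments <- tm$run("classify_predict", {
    adults <- prepare_adults(model$ds, dat$adults,
                             strict = config$baseline$strict_year_class_match)
    out <- classify_adults(model$model, adults)
    out$d18o <- adults$d18o
    utils::write.csv(out[c("fish_id", "p_northern", "decision",
                           "year_class")],
                     file.path(out_dir, "assignments.csv"),
                     row.names = FALSE)
    comp <- composition_report(out)
    utils::write.csv(comp, file.path(out_dir, "composition.csv"),
                     row.names = FALSE)
    list(assignments = out, composition = comp)
  })

  frac <- fractionation_model(config$isoscape$gamma, config$isoscape$beta)
  vm <- variance_model(config$assignment$sigma_analytical,
                       config$assignment$sigma_within_pop)

  isoscapes <- tm$run("isoscape_build", {
    iso_dir <- file.path(out_dir, "isoscapes")
    dir.create(iso_dir, showWarnings = FALSE)
    out <- list(southern = list(), northern = list())
    for (yr in scfg$year_classes) {
      ocean <- gen_ocean(scfg, yr)
      for (ct in c("southern", "northern")) {
        iso <- build_isoscape(ocean$temperature, ocean$salinity, yr, ct,
                              lines = dat$masks$mixing_lines, frac = frac,
                              domain_mask = dat$masks[[ct]],
                              shelf_mask = dat$masks$shelf)
        out[[ct]][[as.character(yr)]] <- iso
        write_isoscape_ncdf(iso, file.path(iso_dir,
                                           sprintf("iso_%d_%s.nc", yr, ct)))
      }
    }
    out
  })

  geo <- tm$run("assign", {
    res <- assign_geographic(assignments$assignments, isoscapes, vm,
                             q = config$assignment$q)
    idx <- do.call(rbind, lapply(names(res$summaries), function(k) {
      s <- res$summaries[[k]]
      data.frame(year_class = s$year_class, contingent = s$contingent,
                 n_fish = s$n_fish,
                 file = sprintf("summary_%s_%s.csv", s$year_class,
                                s$contingent))
    }))
    sm_dir <- file.path(out_dir, "summaries")
    dir.create(sm_dir, showWarnings = FALSE)
    for (s in res$summaries) {
      utils::write.csv(s$values,
                       file.path(sm_dir, sprintf("summary_%s_%s.csv",
                                                 s$year_class,
                                                 s$contingent)),
                       row.names = FALSE)
    }
    utils::write.csv(idx, file.path(out_dir, "summary_index.csv"),
                     row.names = FALSE)
    res
  })

  validation <- tm$run("validate", {
    yr <- scfg$year_classes[length(scfg$year_classes)]
    ocean <- gen_ocean(scfg, yr)
    iso_full <- build_isoscape(ocean$temperature, ocean$salinity, yr,
                               "southern", lines = dat$masks$mixing_lines,
                               frac = frac,
                               domain_mask = dat$masks$full,
                               shelf_mask = dat$masks$shelf)
    fish <- gen_known_origin_fish(scfg, iso_full,
                                  config$synthetic$n_validation_fish,
                                  dat$masks$subregions)
    curve <- threshold_sweep(fish, stats::setNames(list(iso_full),
                                                   as.character(yr)),
                             vm, dat$masks$subregions,
                             accuracy_floor = config$assignment$accuracy_floor)
    utils::write.csv(curve$curve, file.path(out_dir, "validation_curve.csv"),
                     row.names = FALSE)
    list(curve = curve, fish = fish)
  })

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("natalscape")),
    r_version = R.version.string,
    config = config,
    seeds = list(master = config$seed,
                 oversampling = config$seed,
                 folds = config$seed,
                 synthetic = scfg$seed),
    timings_seconds = tm$timings,
    warnings = tm$warnings,
    outputs = file_digests(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(model = model$model, baseline = model$ds,
                 assignments = assignments$assignments,
                 composition = assignments$composition,
                 isoscapes = isoscapes, geographic = geo,
                 validation = validation, manifest = manifest))
}
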