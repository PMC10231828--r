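#' Variance model for a single otolith oxygen measurement
#'
#' Two independent normal error components: analytical error of the
#' isotope-ratio mass spectrometer (SD of repeated carbonate-standard
#' measurements) and within-population variability of otolith oxygen
#' among same-site age-0 fish. Combined as
#' `sigma = sqrt(sigma_analytical^2 + sigma_within_pop^2)`.
#' Defaults: 0.1 and 0.29 per-mil.
#'
#' @param sigma_analytical Analytical SD, per-mil (>= 0).
#' @param sigma_within_pop Within-population SD, per-mil (>= 0).
#' @return A `variance_model` with a `sigma_combined` field.
#' @export
variance_model <- function(sigma_analytical = 0.1, sigma_within_pop = 0.29) {
  if (sigma_analytical < 0 || sigma_within_pop < 0)
    stop("variance components must be >= 0", call. = FALSE)
  structure(list(sigma_analytical = sigma_analytical,
                 sigma_within_pop = sigma_within_pop,
                 sigma_combined = sqrt(sigma_analytical^2 +
                                         sigma_within_pop^2)),
            class = "variance_model")
}

#' Combined measurement SD
#' @param vm A [variance_model()].
#' @return `sqrt(sigma_analytical^2 + sigma_within_pop^2)`, per-mil.
#' @export
combined_sigma <- function(vm) {
  stopifnot(inherits(vm, "variance_model"))
  vm$sigma_combined
}

#' Probability-of-origin surface for one fish
#'
#' Per defined isoscape cell, the likelihood of the observed otolith
#' oxygen value is a normal density centred on the cell's isoscape
#' prediction with the combined SD; multiplied by the prior (uniform
#' inside the domain by default) and normalized so the defined cells sum
#' to 1. Likelihoods are computed in log space with max-subtraction, so
#' a fish far outside the isoscape range still yields a proper
#' (non-degenerate) posterior. A max-scaled copy (maximum exactly 1) is
#' kept for comparison across individuals.
#'
#' @param y Observed otolith oxygen value, per-mil VPDB.
#' @param iso An `isoscape`.
#' @param vm A [variance_model()] with positive combined SD.
#' @param prior Optional non-negative matrix `[lat, lon]`; cells with
#'   prior 0 (or outside the isoscape mask) are excluded.
#' @param fish_id Identifier carried through to outputs.
#' @return A `probability_surface` with `posterior` and `scaled`
#'   matrices (NA outside the domain).
#' @export
posterior_surface <- function(y, iso, vm = variance_model(), prior = NULL,
                              fish_id = NA_character_) {
  stopifnot(inherits(iso, "isoscape"), inherits(vm, "variance_model"))
  if (!is.finite(y)) stop("observed value must be finite", call. = FALSE)
  sigma <- combined_sigma(vm)
  if (sigma <= 0) stop("combined SD must be > 0", call. = FALSE)
  mask <- iso$mask
  if (!is.null(prior)) {
    if (!identical(dim(prior), dim(mask)))
      stop_grid_mismatch("prior and isoscape")
    if (any(prior[mask] < 0)) stop("prior must be non-negative", call. = FALSE)
    mask <- mask & prior > 0
    if (!any(mask)) stop("prior excludes every defined cell", call. = FALSE)
  }
  mu <- iso$values[mask]
  loglik <- stats::dnorm(y, mean = mu, sd = sigma, log = TRUE)
  logpost <- loglik + if (is.null(prior)) 0 else log(prior[mask])
  logpost <- logpost - max(logpost)
  w <- exp(logpost)
  p <- w / sum(w)
  posterior <- matrix(NA_real_, nrow(mask), ncol(mask))
  posterior[mask] <- p
  structure(list(fish_id = fish_id, y = y,
                 posterior = posterior, scaled = posterior / max(p),
                 mask = mask, lat = iso$lat, lon = iso$lon,
                 isoscape = list(year = iso$year,
                                 contingent = iso$contingent)),
            class = "probability_surface")
}

# deterministic ranking of defined cells: posterior descending, ties by
# (lat index, lon index) ascending
rank_cells <- function(ps) {
  idx <- which(ps$mask, arr.ind = TRUE)
  vals <- ps$posterior[ps$mask]
  ord <- order(-vals, idx[, 1], idx[, 2])
  idx[ord, , drop = FALSE]
}

#' Binary likely/unlikely transformation of a posterior surface
#'
#' Cells are ranked by posterior probability; the top
#' `ceiling((1 - q) * m)` of the `m` defined cells are marked likely
#' (q = 0.75 marks the upper 25%). Ties at the cut are broken
#' deterministically by ascending (lat, lon) index so the likely count
#' is exact and reproducible.
#'
#' @param ps A `probability_surface`.
#' @param q Threshold quantile in (0, 1), default 0.75.
#' @return A `binary_surface` with logical matrix `likely`.
#' @export
binarize <- function(ps, q = 0.75) {
  stopifnot(inherits(ps, "probability_surface"))
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  m <- sum(ps$mask)
  if (m < 4) stop("need >= 4 defined cells to binarize", call. = FALSE)
  n_likely <- as.integer(ceiling((1 - q) * m))
  ranked <- rank_cells(ps)
  likely <- matrix(FALSE, nrow(ps$mask), ncol(ps$mask))
  likely[ranked[seq_len(n_likely), , drop = FALSE]] <- TRUE
  structure(list(fish_id = ps$fish_id, likely = likely, q = q,
                 mask = ps$mask, lat = ps$lat, lon = ps$lon,
                 isoscape = ps$isoscape),
            class = "binary_surface")
}

#' Per-year-class summary (nursery heat) map
#'
#' Mean of the individual binary indicator surfaces: each cell holds the
#' fraction of fish whose likely set contains it, in [0, 1].
#'
#' @param binaries Non-empty list of `binary_surface`s on one grid.
#' @param year_class,contingent Labels carried to the output.
#' @return A `summary_map` with `values` matrix and `n_fish`.
#' @export
summarize_surfaces <- function(binaries, year_class = NA_integer_,
                               contingent = NA_character_) {
  if (!length(binaries)) stop("empty list of binary surfaces", call. = FALSE)
  ref <- binaries[[1]]
  acc <- matrix(0, nrow(ref$likely), ncol(ref$likely))
  for (b in binaries) {
    if (!same_grid(ref, b) || !identical(dim(b$likely), dim(acc)))
      stop_grid_mismatch("binary surfaces")
    acc <- acc + b$likely
  }
  vals <- acc / length(binaries)
  vals[!ref$mask] <- NA_real_
  structure(list(year_class = year_class, contingent = contingent,
                 values = vals, n_fish = length(binaries),
                 mask = ref$mask, lat = ref$lat, lon = ref$lon),
            class = "summary_map")
}

#' Validate assignment accuracy with known-origin fish
#'
#' Each fish's observed otolith oxygen value is assigned on the isoscape
#' of its year, binarized at `q`; the fish is correct when its likely
#' set intersects the mask of the subregion it was collected in.
#' Accuracy is the proportion of correct fish.
#'
#' @param fish Data frame with columns `fish_id`, `d18o`, `year`
#'   (isoscape year), `subregion`.
#' @param isoscapes Named list of `isoscape`s, names = years.
#' @param vm A [variance_model()].
#' @param subregion_masks Named list of [region_mask()]s keyed by
#'   subregion code.
#' @param q Binarization quantile (default 0.75).
#' @return List with `accuracy`, per-fish logical `correct`, `n`.
#' @export
validate_assignments <- function(fish, isoscapes, vm = variance_model(),
                                 subregion_masks, q = 0.75) {
  stopifnot(nrow(fish) >= 1)
  for (code in unique(fish$subregion)) {
    if (is.null(subregion_masks[[code]]))
      stop(sprintf("no mask supplied for subregion '%s'", code),
           call. = FALSE)
  }
  correct <- vapply(seq_len(nrow(fish)), function(i) {
    iso <- isoscapes[[as.character(fish$year[i])]]
    if (is.null(iso))
      stop(sprintf("no isoscape for year %s", fish$year[i]), call. = FALSE)
    sub <- subregion_masks[[fish$subregion[i]]]
    if (!same_grid(iso, sub)) stop_grid_mismatch("isoscape and subregion mask")
    if (!any(sub$mask & iso$mask))
      stop(sprintf("subregion '%s' is disjoint from the isoscape domain",
                   fish$subregion[i]), call. = FALSE)
    ps <- posterior_surface(fish$d18o[i], iso, vm,
                            fish_id = as.character(fish$fish_id[i]))
    bs <- binarize(ps, q)
    any(bs$likely & sub$mask)
  }, logical(1))
  list(accuracy = mean(correct), correct = correct, n = nrow(fish))
}

#' Accuracy-precision threshold sweep
#'
#' Recomputes validation accuracy over a grid of binarization quantiles
#' (default 0.05-0.95). The chosen threshold is the largest quantile
#' (most precise) whose accuracy still meets `accuracy_floor`; if none
#' does, `chosen` is `NA` with a warning.
#'
#' @inheritParams validate_assignments
#' @param q_grid Strictly increasing quantiles in (0, 1).
#' @param accuracy_floor Minimum acceptable accuracy (default 0.7).
#' @return A `validation_curve`: data frame `curve` (q, accuracy) plus
#'   `chosen`.
#' @export
threshold_sweep <- function(fish, isoscapes, vm = variance_model(),
                            subregion_masks,
                            q_grid = seq(0.05, 0.95, by = 0.05),
                            accuracy_floor = 0.7) {
  if (length(q_grid) < 2 || any(diff(q_grid) <= 0))
    stop("q_grid must contain >= 2 strictly increasing thresholds",
         call. = FALSE)
  acc <- vapply(q_grid, function(q) {
    validate_assignments(fish, isoscapes, vm, subregion_masks, q)$accuracy
  }, numeric(1))
  ok <- which(acc >= accuracy_floor)
  chosen <- if (length(ok)) max(q_grid[ok]) else {
    warning("no threshold meets the accuracy floor; chosen threshold is NA",
            call. = FALSE)
    NA_real_
  }
  structure(list(curve = data.frame(q = q_grid, accuracy = acc),
                 chosen = chosen, accuracy_floor = accuracy_floor),
            class = "validation_curve")
}

#' @export
print.validation_curve <- function(x, ...) {
  cat(sprintf("<validation_curve> %d thresholds, chosen q = %s (floor %.2f)\n",
              nrow(x$curve),
              if (is.na(x$chosen)) "none" else sprintf("%.2f", x$chosen),
              x$accuracy_floor))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Geographic assignment of classified adults
#'
#' Runs the continuous assignment stage for every adult with a definite
#' contingent decision: posterior surface on the isoscape of its own
#' year-class and contingent, binarization, and per-year-class summary
#' maps. Unassigned fish are skipped.
#'
#' @param assignments Output of [classify_adults()] (columns `fish_id`,
#'   `year_class`, `decision`) joined with a `d18o` column.
#' @param isoscapes Nested named list:
#'   `isoscapes[[contingent]][[as.character(year)]]`.
#' @param vm A [variance_model()].
#' @param q Binarization quantile.
#' @return List with `surfaces` (per fish), `binaries`, and
#'   `summaries` (one `summary_map` per year-class x contingent).
#' @export
assign_geographic <- function(assignments, isoscapes, vm = variance_model(),
                              q = 0.75) {
  stopifnot(all(c("fish_id", "year_class", "decision", "d18o") %in%
                  names(assignments)))
  keep <- assignments$decision %in% c("northern", "southern")
  adults <- assignments[keep, , drop = FALSE]
  surfaces <- list(); binaries <- list()
  for (i in seq_len(nrow(adults))) {
    ct <- adults$decision[i]
    yr <- as.character(adults$year_class[i])
    iso <- isoscapes[[ct]][[yr]]
    if (is.null(iso))
      stop(sprintf("no %s isoscape for year-class %s", ct, yr),
           call. = FALSE)
    ps <- posterior_surface(adults$d18o[i], iso, vm,
                            fish_id = as.character(adults$fish_id[i]))
    surfaces[[i]] <- ps
    binaries[[i]] <- binarize(ps, q)
  }
  groups <- split(seq_len(nrow(adults)),
                  interaction(adults$decision, adults$year_class,
                              drop = TRUE))
  summaries <- lapply(groups, function(ix) {
    summarize_surfaces(binaries[ix],
                       year_class = adults$year_class[ix[1]],
                       contingent = adults$decision[ix[1]])
  })
  list(surfaces = surfaces, binaries = binaries, summaries = summaries,
       skipped = assignments$fish_id[!keep])
}
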