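two_cell_isoscape <- function(mu1, mu2) {
  lat <- 40:41; lon <- c(-70, -69)
  vals <- matrix(c(mu1, mu2, NA, NA), 2, 2)
  structure(list(year = 2000L, contingent = "southern", months = 5:7,
                 values = vals, mask = !is.na(vals), lat = lat, lon = lon),
            class = "isoscape")
}

test_that("the combined SD is the root-sum-of-squares of the components", {
  vm <- variance_model(0.1, 0.29)
  expect_equal(combined_sigma(vm), sqrt(0.1^2 + 0.29^2))
  expect_lt(abs(combined_sigma(vm) - 0.3068), 1e-4)
  expect_equal(combined_sigma(variance_model(0.4, 0)), 0.4)
  expect_equal(combined_sigma(variance_model(0, 0)), 0)
  expect_error(variance_model(-0.1, 0.2), ">= 0")
  # a degenerate zero-SD model is rejected by the likelihood
  w <- tiny_world()
  expect_error(posterior_surface(0, w$iso, variance_model(0, 0)), "> 0")
})

test_that("two-cell posteriors match the normal-density ratio", {
  vm <- variance_model(0.1, 0.29)
  sigma <- combined_sigma(vm)
  y <- -1
  delta <- 0.5
  iso <- two_cell_isoscape(y, y + delta)
  ps <- posterior_surface(y, iso, vm)
  p <- ps$posterior[iso$mask]
  expect_equal(p[1] / p[2], exp(delta^2 / (2 * sigma^2)))
  # brute-force density check
  dens <- stats::dnorm(y, mean = c(y, y + delta), sd = sigma)
  expect_equal(p, dens / sum(dens))
})

test_that("posteriors normalize to one, max-scale to one, and stay uniform under equal means", {
  w <- tiny_world()
  vm <- variance_model()
  for (y in c(-2.5, -1, 0, 1)) {
    ps <- posterior_surface(y, w$iso, vm)
    expect_lt(abs(sum(ps$posterior[ps$mask]) - 1), 1e-10)
    expect_identical(max(ps$scaled[ps$mask]), 1)
    # scaled copy is a positive multiple of the posterior
    ratio <- ps$scaled[ps$mask] / ps$posterior[ps$mask]
    expect_lt(diff(range(ratio)), 1e-6 * mean(ratio))
  }
  flat <- two_cell_isoscape(0.3, 0.3)
  ps <- posterior_surface(1, flat, vm)
  expect_equal(unname(ps$posterior[flat$mask]), c(0.5, 0.5))
})

test_that("posterior evaluation matches brute-force densities and survives far-field underflow", {
  w <- tiny_world()
  vm <- variance_model()
  sigma <- combined_sigma(vm)
  mu <- w$iso$values[w$iso$mask]
  for (y in c(-1.2, 0.4)) {
    ps <- posterior_surface(y, w$iso, vm)
    brute <- stats::dnorm(y, mu, sigma)
    brute <- brute / sum(brute)
    expect_lt(max(abs(ps$posterior[w$iso$mask] - brute) / brute), 1e-10)
  }
  # a fish 40 permil outside the isoscape range would underflow dnorm,
  # but the log-space path still returns a proper posterior
  far <- posterior_surface(40, w$iso, vm)
  expect_lt(abs(sum(far$posterior[w$iso$mask]) - 1), 1e-10)
  expect_true(all(is.finite(far$posterior[w$iso$mask])))
})

test_that("a prior reweights and can exclude cells but never goes negative", {
  iso <- two_cell_isoscape(0, 0)
  prior <- matrix(c(3, 1, 0, 0), 2, 2)
  ps <- posterior_surface(0, iso, variance_model(), prior = prior)
  expect_equal(unname(ps$posterior[iso$mask]), c(0.75, 0.25))
  prior0 <- matrix(0, 2, 2)
  expect_error(posterior_surface(0, iso, variance_model(), prior = prior0),
               "excludes")
  priorneg <- matrix(c(-1, 1, 1, 1), 2, 2)
  expect_error(posterior_surface(0, iso, variance_model(),
                                 prior = priorneg), "non-negative")
})

test_that("binarization marks exactly the upper quantile with deterministic ties", {
  vals <- matrix(c(8:1, rep(NA, 1)), 3, 3)  # 8 distinct defined cells
  ps <- surface_from_values(vals)
  bs <- binarize(ps, q = 0.75)
  expect_equal(sum(bs$likely), 2)           # ceil(0.25 * 8)
  expect_true(all(ps$posterior[bs$likely] >=
                    max(ps$posterior[!bs$likely & ps$mask])))
  bs5 <- binarize(surface_from_values(matrix(1:10, 2, 5)), q = 0.5)
  expect_equal(sum(bs5$likely), 5)          # ceil(0.5 * 10)
  # all-tied surface: the count is still exact, chosen by (lat, lon) order
  tied <- surface_from_values(matrix(1, 3, 3))
  bst <- binarize(tied, q = 0.75)
  expect_equal(sum(bst$likely), ceiling(0.25 * 9))
  idx <- which(bst$likely, arr.ind = TRUE)
  expect_equal(idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ],
               c(row = 1, col = 1))
  expect_error(binarize(ps, q = 1.2), "q must be")
  few <- surface_from_values(matrix(c(1, 2, NA, NA), 2, 2))
  expect_error(binarize(few, q = 0.75), ">= 4")
})

test_that("likely sets are nested as the threshold tightens", {
  w <- tiny_world()
  set.seed(31)
  for (rep in 1:5) {
    y <- stats::runif(1, -3, 1)
    ps <- posterior_surface(y, w$iso, variance_model())
    qs <- seq(0.1, 0.9, by = 0.1)
    prev <- NULL
    for (q in qs) {
      cur <- binarize(ps, q)$likely
      if (!is.null(prev)) expect_true(all(prev[cur]))  # cur subset of prev
      prev <- cur
    }
  }
})

test_that("summary maps average binary indicators", {
  vals <- matrix(1:9, 3, 3)
  b1 <- binarize(surface_from_values(vals), 0.75)
  expect_equal(summarize_surfaces(list(b1, b1, b1))$values[b1$mask],
               as.numeric(b1$likely[b1$mask]))
  # two disjoint likely sets average to one half on each
  vals2 <- matrix(9:1, 3, 3)
  b2 <- binarize(surface_from_values(vals2), 0.75)
  expect_true(!any(b1$likely & b2$likely))
  sm <- summarize_surfaces(list(b1, b2))
  expect_equal(sort(unique(sm$values[sm$mask])), c(0, 0.5))
  # 3 of 4 fish marking a cell gives 0.75
  sm4 <- summarize_surfaces(list(b1, b1, b1, b2))
  top <- which(b1$likely, arr.ind = TRUE)[1, , drop = FALSE]
  expect_equal(sm4$values[top], 0.75)
  expect_error(summarize_surfaces(list()), "empty")
})

test_that("validation scores a fish by likely-set overlap with its subregion", {
  w <- tiny_world()
  iso <- w$iso
  isos <- stats::setNames(list(iso), "2016")
  whole <- region_mask(iso$lat, iso$lon, iso$mask, name = "ALL")
  fish <- data.frame(fish_id = "f1", d18o = -1, year = 2016,
                     subregion = "ALL")
  v <- validate_assignments(fish, isos, variance_model(),
                            list(ALL = whole), q = 0.75)
  expect_equal(v$accuracy, 1)  # a subregion covering the domain always hits
  expect_error(validate_assignments(fish, isos, variance_model(),
                                    list(OTHER = whole)), "no mask")
  empty <- region_mask(iso$lat, iso$lon,
                       matrix(FALSE, length(iso$lat), length(iso$lon)))
  expect_error(validate_assignments(fish, isos, variance_model(),
                                    list(ALL = empty)), "disjoint")
})

test_that("the accuracy-precision sweep is monotone and honors the floor", {
  w <- tiny_world()
  isos <- stats::setNames(list(w$iso), "2016")
  fish <- gen_known_origin_fish(w$cfg, w$iso, 40, w$masks$subregions)
  curve <- threshold_sweep(fish, isos, variance_model(),
                           w$masks$subregions,
                           q_grid = seq(0.05, 0.95, by = 0.10),
                           accuracy_floor = 0)
  expect_true(all(diff(curve$curve$accuracy) <= 1e-12))
  expect_equal(curve$chosen, 0.95)  # vacuous floor picks the max threshold
  expect_warning(
    none <- threshold_sweep(fish, isos, variance_model(),
                            w$masks$subregions,
                            q_grid = c(0.5, 0.75), accuracy_floor = 1.01),
    "floor")
  expect_true(is.na(none$chosen))
  expect_error(threshold_sweep(fish, isos, variance_model(),
                               w$masks$subregions, q_grid = 0.5),
               "increasing")
})

test_that("geographic assignment routes each adult to its own cohort and contingent isoscape", {
  w <- tiny_world()
  cfg <- w$cfg
  frac <- fractionation_model()
  isos <- list(southern = list(), northern = list())
  for (yr in cfg$year_classes) {
    oc <- gen_ocean(cfg, yr)
    for (ct in c("southern", "northern")) {
      isos[[ct]][[as.character(yr)]] <-
        build_isoscape(oc$temperature, oc$salinity, yr, ct,
                       lines = w$masks$mixing_lines,
                       domain_mask = w$masks[[ct]],
                       shelf_mask = w$masks$shelf)
    }
  }
  asn <- data.frame(fish_id = c("a", "b", "c"),
                    year_class = c(2014, 2016, 2015),
                    decision = c("northern", "southern", "unassigned"),
                    d18o = c(-0.5, -1.5, 0))
  res <- assign_geographic(asn, isos, variance_model(), q = 0.75)
  expect_length(res$surfaces, 2)  # the unassigned fish is skipped
  expect_equal(res$skipped, "c")
  expect_equal(res$surfaces[[1]]$isoscape$contingent, "northern")
  expect_equal(res$surfaces[[1]]$isoscape$year, 2014)
  expect_length(res$summaries, 2)
  for (s in res$summaries) {
    expect_true(all(s$values[s$mask] >= 0 & s$values[s$mask] <= 1))
  }
})
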