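fake_report <- function(name, acc, auc = 0.5, ll = 0.6, failed = FALSE) {
  structure(list(classifier = name, mean_accuracy = acc, mean_auc = auc,
                 mean_logloss = ll, failed = failed),
            class = "cv_report")
}

test_that("accuracy-proportional weights normalize exactly", {
  w <- compute_weights(list(fake_report("A", 0.8), fake_report("B", 0.8)))
  expect_equal(unname(w), c(0.5, 0.5))
  w <- compute_weights(list(fake_report("A", 0.9), fake_report("B", 0.6)))
  expect_equal(unname(w), c(0.6, 0.4))
  expect_equal(unname(compute_weights(list(fake_report("A", 0.77)))), 1)
  # exact unit sum even for awkward accuracies
  w <- compute_weights(list(fake_report("A", 1 / 3), fake_report("B", 1 / 7),
                            fake_report("C", 1 / 11)))
  expect_identical(sum(w), 1)
  expect_true(all(w >= 0))
  expect_error(compute_weights(list()), "empty")
  expect_error(compute_weights(list(fake_report("A", 0))), "> 0")
})

test_that("member selection respects the strict cutoff, top-k, and exclusions", {
  reps <- list(fake_report("A", 0.5), fake_report("B", 0.77),
               fake_report("C", 0.9), fake_report("NULL", 0.99),
               fake_report("D", 0.95, failed = TRUE))
  sel <- select_members(reps, list(accuracy_cutoff = 0.76))
  expect_setequal(sel, c("B", "C"))
  # 0.76 itself does not pass (strict inequality)
  expect_setequal(select_members(list(fake_report("A", 0.76),
                                      fake_report("B", 0.761)),
                                 list(accuracy_cutoff = 0.76)), "B")
  expect_equal(select_members(reps, list(top_k = 1)), "C")
  expect_error(select_members(list(fake_report("A", 0.5)),
                              list(accuracy_cutoff = 0.76)), "top_k")
  # ties break by AUC, then log-loss, then name
  tied <- list(fake_report("B", 0.8, auc = 0.9), fake_report("A", 0.8, auc = 0.8))
  expect_equal(select_members(tied, list(top_k = 1)), "B")
  tied2 <- list(fake_report("B", 0.8, auc = 0.9, ll = 0.5),
                fake_report("A", 0.8, auc = 0.9, ll = 0.4))
  expect_equal(select_members(tied2, list(top_k = 1)), "A")
})

test_that("the averaged prediction is the weighted mean and stays convex", {
  model <- tiny_ensemble()
  rec <- tiny_baseline_ds()$records[1:20, ]
  member_p <- vapply(model$members,
                     function(m) predict_classifier(m, rec), numeric(20))
  expect_equal(bma_predict(model, rec),
               as.numeric(member_p %*% model$weights))
  expect_true(all(bma_predict(model, rec) >=
                    apply(member_p, 1, min) - 1e-12))
  expect_true(all(bma_predict(model, rec) <=
                    apply(member_p, 1, max) + 1e-12))
  # fitted weights are a proper simplex point
  expect_lt(abs(sum(model$weights) - 1), 1e-12)
  expect_true(all(model$weights >= 0))
})

test_that("contingent assignment uses strict inequalities at the threshold", {
  expect_equal(assign_contingent(0.71, 0.7), "northern")
  expect_equal(assign_contingent(0.70, 0.7), "unassigned")
  expect_equal(assign_contingent(0.29, 0.7), "southern")
  expect_equal(assign_contingent(0.30, 0.7), "unassigned")
  expect_equal(assign_contingent(0.5, 0.51), "unassigned")
  expect_error(assign_contingent(0.5, 0.5))
})

test_that("raising the threshold never decreases the abstention count", {
  p <- withr::with_seed(1, stats::runif(300))
  taus <- seq(0.55, 0.95, by = 0.05)
  unassigned <- vapply(taus, function(t) sum(assign_contingent(p, t) ==
                                               "unassigned"), numeric(1))
  expect_true(all(diff(unassigned) >= 0))
})

test_that("composition report counts assigned and unassigned fish correctly", {
  asn <- data.frame(year_class = rep(2000, 10),
                    decision = c(rep("northern", 8), rep("southern", 2)))
  rep1 <- composition_report(asn)
  expect_equal(rep1$pct_northern, 80)
  expect_equal(rep1$pct_unassigned, 0)
  asn2 <- data.frame(year_class = 2001, decision = rep("unassigned", 4))
  rep2 <- composition_report(asn2)
  expect_true(is.na(rep2$pct_northern))
  expect_equal(rep2$pct_unassigned, 100)
  both <- composition_report(rbind(asn, asn2))
  expect_equal(nrow(both), 2)
  expect_error(composition_report(asn[0, ]), "no assignments")
})

test_that("cross-validation metrics are correct for the chance-level NULL model", {
  ds <- tiny_baseline_ds()
  rep_null <- cross_validate(ds, classifier_spec("NULL"), folds = 10,
                             seed = 3)
  # balanced baseline: p = 0.5 always, so accuracy 0.5, AUC 0.5, log-loss ln 2
  expect_lt(abs(rep_null$mean_accuracy - 0.5), 0.1)
  expect_equal(rep_null$mean_auc, 0.5)
  expect_lt(abs(rep_null$mean_logloss - log(2)), 0.01)
  expect_true(all(abs(rep_null$oof_prob - 0.5) < 0.06))
})

test_that("linear discriminant analysis is near-perfect on well-separated contingents", {
  # 6 SD mean separation: Gaussian Bayes error ~ Phi(-3) ~ 0.001
  cfg <- synthetic_config(seed = 99, year_classes = 2015:2016,
                          n_southern = 25, n_northern = 25,
                          mean_southern = c(d18o = 2.1, d13c = -9.0),
                          mean_northern = c(d18o = 0.0, d13c = -6.0),
                          sd_d18o = 0.35, sd_d13c = 0.5,
                          separation = 1, year_class_jitter_sd = 0)
  ds <- standardize_baseline(oversample_balance(gen_baseline(cfg), seed = 1))
  rep_lda <- cross_validate(ds, classifier_spec("LDA"), folds = 10, seed = 2)
  expect_gte(rep_lda$mean_accuracy, 0.97)
})

test_that("all registry members satisfy the probability contract", {
  ds <- tiny_baseline_ds()
  frame <- natalscape:::model_frame(ds$records)
  newrec <- ds$records[seq(1, nrow(ds$records), by = 9), ]
  for (nm in classifier_names()) {
    spec <- classifier_spec(nm)
    params <- natalscape:::param_grid_rows(spec$grid)[[1]]
    fitted <- withr::with_seed(5, natalscape:::fit_classifier(spec, frame,
                                                              params))
    p <- natalscape:::predict_classifier(fitted, newrec)
    expect_length(p, nrow(newrec))
    expect_true(all(p >= 0 & p <= 1), info = nm)
  }
})

test_that("the NULL member ignores predictors entirely", {
  ds <- tiny_baseline_ds()
  frame <- natalscape:::model_frame(ds$records)
  spec <- natalscape:::fit_classifier(classifier_spec("NULL"), frame, list())
  a <- ds$records[1:3, ]
  b <- a
  b$z_d18o <- b$z_d18o + 100
  expect_equal(natalscape:::predict_classifier(spec, a),
               natalscape:::predict_classifier(spec, b))
})

test_that("ensemble persistence round-trips predictions", {
  model <- tiny_ensemble()
  dir <- withr::local_tempdir()
  save_ensemble(model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  back <- load_ensemble(dir)
  rec <- tiny_baseline_ds()$records[1:5, ]
  expect_equal(bma_predict(back, rec), bma_predict(model, rec))
})

test_that("year-class-agnostic fallback classifies unmatched cohorts", {
  model <- tiny_ensemble()
  ds <- tiny_baseline_ds()
  adults <- make_records(2, "unknown", year_class = NA_integer_, age = 2)
  adults$collection_year <- c(2018, 2010)  # cohorts 2016 (known), 2008 (not)
  adults$year_class <- NULL
  prepped <- suppressWarnings(prepare_adults(ds, adults, strict = FALSE))
  out <- classify_adults(model, prepped)
  expect_equal(nrow(out), 2)
  expect_true(all(out$p_northern >= 0 & out$p_northern <= 1))
})
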