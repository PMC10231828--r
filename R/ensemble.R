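#' Stratified cross-validation folds
#'
#' Folds are stratified by contingent x year-class where every cell has
#' at least `folds` members, otherwise by contingent alone, so each fold
#' contains both classes. Folds are drawn at the level of original fish:
#' oversampled duplicates always share the fold of their source record,
#' so balancing cannot leak a fish across the train/test split. One
#' shared fold assignment is used for every ensemble member so the
#' averaged classifier can itself be cross-validated on out-of-fold
#' predictions.
#'
#' @param ds A standardized `baseline_dataset`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @return Integer vector of fold ids, one per record.
#' @export
make_cv_folds <- function(ds, folds = 10, seed = 1) {
  stopifnot(inherits(ds, "baseline_dataset"), folds >= 2)
  rec <- ds$records
  source_row <- if (!is.null(rec$.source_row)) rec$.source_row else
    seq_len(nrow(rec))
  firsts <- !duplicated(source_row)
  cell_all <- interaction(rec$contingent, rec$year_class, drop = TRUE)
  cell <- cell_all
  if (min(table(cell_all[firsts])) < folds)
    cell <- factor(rec$contingent)
  source_fold <- integer(max(source_row))
  withr::with_seed(as.integer(seed), {
    for (lv in levels(cell)) {
      src <- unique(source_row[cell == lv])
      source_fold[src] <- sample(rep_len(seq_len(folds), length(src)))
    }
  })
  fold <- source_fold[source_row]
  # guard: every fold must see both contingents
  bad <- vapply(seq_len(folds), function(f) {
    length(unique(rec$contingent[fold == f])) < 2
  }, logical(1))
  if (any(bad)) {
    warning("fold(s) with a single contingent; refolding by contingent only",
            call. = FALSE)
    source_fold <- integer(max(source_row))
    withr::with_seed(as.integer(seed) + 1L, {
      for (ct in unique(rec$contingent)) {
        src <- unique(source_row[rec$contingent == ct])
        source_fold[src] <- sample(rep_len(seq_len(folds), length(src)))
      }
    })
    fold <- source_fold[source_row]
  }
  fold
}

binary_metrics <- function(truth, prob) {
  y <- as.integer(truth == "northern")
  acc <- mean((prob > 0.5) == (y == 1))
  auc <- if (length(unique(y)) < 2) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = prob, levels = c(0, 1),
      direction = "<", quiet = TRUE)))
  }
  p <- pmin(pmax(prob, 1e-15), 1 - 1e-15)
  ll <- -mean(y * log(p) + (1 - y) * log(1 - p))
  c(accuracy = acc, auc = auc, logloss = ll)
}

#' Cross-validate one classifier with grid-search tuning
#'
#' Every hyperparameter combination in the spec's grid is evaluated by
#' k-fold cross-validation on the shared folds; the combination with the
#' best mean accuracy (ties: lower log-loss) is retained and its
#' per-fold metrics reported. Log-loss probabilities are clipped to
#' `[1e-15, 1 - 1e-15]`. A member whose fit fails is returned with
#' `failed = TRUE` and is never selected into the ensemble.
#'
#' @param ds Standardized, balanced `baseline_dataset`.
#' @param spec A [classifier_spec()].
#' @param folds Fold count, or an integer fold-id vector from
#'   [make_cv_folds()].
#' @param seed Seed used when `folds` is a count (and for ANN weight
#'   initialization).
#' @return A `cv_report`: per-fold and mean accuracy/AUC/log-loss,
#'   tuned parameters, out-of-fold probabilities, fold ids.
#' @export
cross_validate <- function(ds, spec, folds = 10, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  fold_id <- if (length(folds) == 1) make_cv_folds(ds, folds, seed) else folds
  nf <- max(fold_id)
  frame <- model_frame(ds$records)
  combos <- param_grid_rows(spec$grid)

  run_combo <- function(params) {
    oof <- rep(NA_real_, nrow(frame))
    for (f in seq_len(nf)) {
      train <- frame[fold_id != f, , drop = FALSE]
      test <- frame[fold_id == f, , drop = FALSE]
      state <- withr::with_seed(as.integer(seed) + 1000L * f,
                                spec$fit(train, params))
      p <- as.numeric(spec$predict_prob(state, test))
      if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("probabilities outside [0,1]")
      oof[fold_id == f] <- p
    }
    oof
  }

  result <- tryCatch({
    best <- NULL
    for (params in combos) {
      oof <- run_combo(params)
      m <- binary_metrics(frame$contingent, oof)
      if (is.null(best) || m["accuracy"] > best$acc + 1e-12 ||
          (abs(m["accuracy"] - best$acc) <= 1e-12 &&
           m["logloss"] < best$ll)) {
        best <- list(params = params, oof = oof,
                     acc = unname(m["accuracy"]), ll = unname(m["logloss"]))
      }
    }
    per_fold <- t(vapply(seq_len(nf), function(f) {
      sel <- fold_id == f
      binary_metrics(frame$contingent[sel], best$oof[sel])
    }, c(accuracy = 0, auc = 0, logloss = 0)))
    list(params = best$params, oof = best$oof,
         per_fold = as.data.frame(cbind(fold = seq_len(nf), per_fold)),
         failed = FALSE, message = NULL)
  }, error = function(e) {
    list(params = list(), oof = NULL, per_fold = NULL,
         failed = TRUE, message = conditionMessage(e))
  })

  structure(list(
    classifier = spec$name,
    folds = nf,
    fold_seed = as.integer(seed),
    tuned_params = result$params,
    per_fold = result$per_fold,
    mean_accuracy = if (result$failed) NA_real_ else mean(result$per_fold$accuracy),
    mean_auc = if (result$failed) NA_real_ else mean(result$per_fold$auc, na.rm = TRUE),
    mean_logloss = if (result$failed) NA_real_ else mean(result$per_fold$logloss),
    oof_prob = result$oof,
    fold_id = fold_id,
    failed = result$failed,
    message = result$message
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<cv_report> %s: FAILED (%s)\n", x$classifier, x$message))
  } else {
    cat(sprintf("<cv_report> %s: accuracy %.3f, AUC %.3f, log-loss %.3f (%d folds)\n",
                x$classifier, x$mean_accuracy, x$mean_auc, x$mean_logloss,
                x$folds))
  }
  invisible(x)
}

#' Select ensemble members from cross-validation reports
#'
#' Either all members with mean accuracy strictly above a cutoff
#' (default 0.76), or the `top_k` best by mean accuracy. The NULL
#' benchmark and failed members are never selected. Ties break by higher
#' AUC, then lower log-loss, then name order.
#'
#' @param reports List of `cv_report`s.
#' @param rule `list(accuracy_cutoff = x)` or `list(top_k = k)`.
#' @return Character vector of selected classifier names.
#' @export
select_members <- function(reports, rule = list(accuracy_cutoff = 0.76)) {
  if (!length(reports)) stop("no reports supplied", call. = FALSE)
  ok <- Filter(function(r) !r$failed && r$classifier != "NULL", reports)
  if (!length(ok)) stop("no eligible (non-failed, non-NULL) members", call. = FALSE)
  acc <- vapply(ok, `[[`, 0, "mean_accuracy")
  auc <- vapply(ok, `[[`, 0, "mean_auc")
  ll <- vapply(ok, `[[`, 0, "mean_logloss")
  nm <- vapply(ok, `[[`, "", "classifier")
  ord <- order(-acc, -auc, ll, nm)
  if (!is.null(rule$accuracy_cutoff)) {
    sel <- nm[ord][acc[ord] > rule$accuracy_cutoff]
    if (!length(sel))
      stop(sprintf("no member exceeds accuracy cutoff %.3f; consider rule = list(top_k = k)",
                   rule$accuracy_cutoff), call. = FALSE)
  } else if (!is.null(rule$top_k)) {
    k <- min(rule$top_k, length(nm))
    sel <- nm[ord][seq_len(k)]
  } else {
    stop("rule must contain accuracy_cutoff or top_k", call. = FALSE)
  }
  sel
}

#' Accuracy-proportional model-averaging weights
#'
#' Weights are proportional to cross-validated accuracy and normalized
#' to sum to 1; the final weight is computed as one minus the sum of the
#' others so the total is exact.
#'
#' @param reports List of `cv_report`s for the selected members.
#' @return Named numeric weights summing to exactly 1.
#' @export
compute_weights <- function(reports) {
  if (!length(reports)) stop("empty member selection", call. = FALSE)
  acc <- vapply(reports, `[[`, 0, "mean_accuracy")
  if (any(!is.finite(acc)) || any(acc <= 0))
    stop("all selected accuracies must be > 0", call. = FALSE)
  w <- acc / sum(acc)
  if (length(w) > 1) w[length(w)] <- 1 - sum(w[-length(w)])
  names(w) <- vapply(reports, `[[`, "", "classifier")
  w
}

#' Fit the model-averaged ensemble classifier
#'
#' Cross-validates the whole registry on one shared fold assignment,
#' selects the top performers, weights them by cross-validated accuracy,
#' refits the selected members on the full baseline, and cross-validates
#' the averaged classifier itself from the members' out-of-fold
#' probabilities.
#'
#' @param ds Standardized, balanced `baseline_dataset`.
#' @param registry List of [classifier_spec()]s
#'   (default: the full registry).
#' @param folds Fold count (default 10).
#' @param seed Fold/initialization seed.
#' @param rule Member-selection rule for [select_members()].
#' @param tau Assignment probability threshold (strict, default 0.7).
#' @return An `ensemble_model`.
#' @export
fit_ensemble <- function(ds, registry = classifier_registry(), folds = 10,
                         seed = 1, rule = list(accuracy_cutoff = 0.76),
                         tau = 0.7) {
  stopifnot(inherits(ds, "baseline_dataset"))
  if (is.null(ds$standardization))
    stop("baseline dataset must be standardized first", call. = FALSE)
  if (tau <= 0.5 || tau > 1) stop("tau must be in (0.5, 1]", call. = FALSE)
  fold_id <- make_cv_folds(ds, folds, seed)
  reports <- lapply(registry, function(spec)
    cross_validate(ds, spec, folds = fold_id, seed = seed))
  names(reports) <- vapply(reports, `[[`, "", "classifier")
  for (r in reports) {
    if (r$failed)
      warning(sprintf("classifier %s failed during cross-validation: %s",
                      r$classifier, r$message), call. = FALSE)
  }
  selected <- select_members(reports, rule)
  weights <- compute_weights(reports[selected])

  frame <- model_frame(ds$records)
  members <- lapply(selected, function(nm) {
    spec <- registry[[nm]]
    spec <- withr::with_seed(as.integer(seed) + 7L,
                             fit_classifier(spec, frame,
                                            reports[[nm]]$tuned_params))
    spec
  })
  names(members) <- selected

  # cross-validated performance of the averaged classifier itself
  oof <- vapply(selected, function(nm) reports[[nm]]$oof_prob,
                numeric(nrow(frame)))
  bma_oof <- as.numeric(oof %*% weights)
  per_fold <- t(vapply(seq_len(max(fold_id)), function(f) {
    sel <- fold_id == f
    binary_metrics(frame$contingent[sel], bma_oof[sel])
  }, c(accuracy = 0, auc = 0, logloss = 0)))

  structure(list(
    members = members,
    weights = weights,
    rule = rule,
    tau = tau,
    reports = reports,
    fold_id = fold_id,
    seed = as.integer(seed),
    standardization = ds$standardization,
    yc_levels = levels(frame$yc),
    bma_cv = list(
      per_fold = as.data.frame(cbind(fold = seq_len(nrow(per_fold)), per_fold)),
      mean_accuracy = mean(per_fold[, "accuracy"]),
      mean_auc = mean(per_fold[, "auc"], na.rm = TRUE),
      mean_logloss = mean(per_fold[, "logloss"]),
      oof_prob = bma_oof
    )
  ), class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members, tau = %.2f\n",
              length(x$members), x$tau))
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  cat(sprintf("  cross-validated: accuracy %.3f, AUC %.3f, log-loss %.3f\n",
              x$bma_cv$mean_accuracy, x$bma_cv$mean_auc,
              x$bma_cv$mean_logloss))
  invisible(x)
}

#' Model-averaged probability of northern membership
#'
#' The convex combination of member probabilities with the
#' accuracy-proportional weights; always bounded by the member minimum
#' and maximum.
#'
#' @param model An `ensemble_model`.
#' @param records Standardized otolith records (see [prepare_adults()]).
#' @return Numeric vector of P(northern) per record.
#' @export
bma_predict <- function(model, records) {
  stopifnot(inherits(model, "ensemble_model"))
  probs <- vapply(model$members, function(m) predict_classifier(m, records),
                  numeric(nrow(records)))
  if (nrow(records) == 1) probs <- matrix(probs, nrow = 1)
  as.numeric(probs %*% model$weights)
}

#' Threshold a membership probability into a contingent decision
#'
#' Assigns northern when `p > tau`, southern when `1 - p > tau`,
#' otherwise `unassigned` (the inequalities are strict; abstentions are
#' excluded from geographic assignment downstream).
#'
#' @param p Probability (vector) of northern membership.
#' @param tau Threshold in (0.5, 1], default 0.7.
#' @return Character vector in
#'   `{"northern", "southern", "unassigned"}`.
#' @export
assign_contingent <- function(p, tau = 0.7) {
  stopifnot(all(p >= 0 & p <= 1), tau > 0.5, tau <= 1)
  ifelse(p > tau, "northern", ifelse(1 - p > tau, "southern", "unassigned"))
}

#' Year-class-agnostic ensemble probability
#'
#' Marginalizes the ensemble prediction uniformly over every baseline
#' year-class: used as the opt-in fallback for adults whose cohort has
#' no baseline coverage.
#'
#' @inheritParams bma_predict
#' @return Numeric vector of P(northern) per record.
#' @export
bma_predict_marginal <- function(model, records) {
  per_yc <- vapply(model$yc_levels, function(yc) {
    r <- records
    r$year_class <- as.integer(yc)
    bma_predict(model, r)
  }, numeric(nrow(records)))
  if (nrow(records) == 1) per_yc <- matrix(per_yc, nrow = 1)
  rowMeans(per_yc)
}

#' Classify unknown adults with the ensemble
#'
#' Adults flagged by [prepare_adults()] (`strict = FALSE`) as lacking
#' baseline year-class coverage are classified with the
#' year-class-agnostic marginal prediction.
#'
#' @param model An `ensemble_model`.
#' @param adults Standardized adult records from [prepare_adults()].
#' @return Data frame with `fish_id`, `year_class`, `p_northern`,
#'   `decision`.
#' @export
classify_adults <- function(model, adults) {
  fallback <- if (is.null(adults$.year_class_fallback)) {
    rep(FALSE, nrow(adults))
  } else adults$.year_class_fallback
  p <- numeric(nrow(adults))
  if (any(!fallback))
    p[!fallback] <- bma_predict(model, adults[!fallback, , drop = FALSE])
  if (any(fallback))
    p[fallback] <- bma_predict_marginal(model,
                                        adults[fallback, , drop = FALSE])
  data.frame(fish_id = adults$fish_id,
             year_class = adults$year_class,
             p_northern = p,
             decision = assign_contingent(p, model$tau),
             stringsAsFactors = FALSE)
}

#' Per-year-class contingent composition
#'
#' Percentage northern is computed among assigned fish only; percentage
#' unassigned among all fish of the year-class. Year-classes with no
#' fish are omitted; a year-class with no assigned fish reports
#' `pct_northern = NA`.
#'
#' @param assignments Data frame with `year_class` and `decision`
#'   columns (as returned by [classify_adults()]).
#' @return Data frame with counts and percentages per year-class.
#' @export
composition_report <- function(assignments) {
  if (!nrow(assignments)) stop("no assignments supplied", call. = FALSE)
  ycs <- sort(unique(assignments$year_class))
  rows <- lapply(ycs, function(yc) {
    d <- assignments$decision[assignments$year_class == yc]
    n <- length(d)
    n_n <- sum(d == "northern"); n_s <- sum(d == "southern")
    n_u <- sum(d == "unassigned")
    assigned <- n_n + n_s
    data.frame(year_class = yc, n = n,
               n_northern = n_n, n_southern = n_s, n_unassigned = n_u,
               pct_northern = if (assigned > 0) 100 * n_n / assigned else NA_real_,
               pct_unassigned = 100 * n_u / n)
  })
  do.call(rbind, rows)
}

#' Persist an ensemble model to a directory
#'
#' Weights, selection rule, tuned parameters, and cross-validation
#' reports are written as JSON for inspection; fitted member states are
#' serialized alongside so the model can be reloaded for prediction.
#'
#' @param model An `ensemble_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    members = names(model$members),
    weights = as.list(model$weights),
    rule = model$rule,
    tau = model$tau,
    seed = model$seed,
    standardization = model$standardization,
    cv = lapply(model$reports, function(r) list(
      classifier = r$classifier, failed = r$failed,
      mean_accuracy = r$mean_accuracy, mean_auc = r$mean_auc,
      mean_logloss = r$mean_logloss, tuned_params = r$tuned_params)),
    bma_cv = model$bma_cv[c("mean_accuracy", "mean_auc", "mean_logloss")]
  )
  jsonlite::write_json(summ, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a persisted ensemble model
#' @param dir Directory written by [save_ensemble()].
#' @return An `ensemble_model`.
#' @export
load_ensemble <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
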