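# Classifier registry for contingent classification.
#
# Every member exposes the same contract: fit(train, params) -> state,
# predict_prob(state, newdata) -> P(northern) in [0,1]. Predictors are
# the standardized isotopes z_d18o, z_d13c plus year-class as a
# categorical variable (one-hot where the backend needs a numeric
# matrix). The mixed-effect logistic regression instead gives both
# isotope slopes a per-year-class random effect. The intercept-only NULL
# model ignores all predictors and benchmarks chance performance.

CONTINGENT_LEVELS <- c("southern", "northern")

model_frame <- function(records, yc_levels = NULL) {
  if (is.null(yc_levels)) yc_levels <- sort(unique(records$year_class))
  df <- data.frame(
    z_d18o = records$z_d18o,
    z_d13c = records$z_d13c,
    yc = factor(records$year_class, levels = yc_levels)
  )
  if ("contingent" %in% names(records) &&
      all(records$contingent %in% CONTINGENT_LEVELS)) {
    df$contingent <- factor(records$contingent, levels = CONTINGENT_LEVELS)
  }
  df
}

onehot_matrix <- function(df) {
  x <- cbind(z_d18o = df$z_d18o, z_d13c = df$z_d13c)
  if (nlevels(df$yc) > 1) {
    mm <- stats::model.matrix(~ yc - 1, data = df)
    x <- cbind(x, mm)
  }
  x
}

clip_prob <- function(p) pmin(pmax(p, 0), 1)

#' Available classifier names
#' @return Character vector of registry names.
#' @export
classifier_names <- function() {
  c("LR", "MELR", "LDA", "QDA", "ANN", "DT", "kNN", "NB", "RF", "SVM", "NULL")
}

#' Default hyperparameter grids
#'
#' Small, user-overridable grid-search spaces per classifier; parameter-
#' free members have an empty grid. Grids are crossed and searched by
#' cross-validated accuracy in [cross_validate()].
#'
#' @param name A classifier name from [classifier_names()].
#' @return Named list of parameter-value vectors.
#' @export
default_grid <- function(name) {
  switch(name,
         ANN = list(size = c(2L, 5L), decay = c(0.01, 0.1)),
         DT  = list(cp = c(0.01, 0.001)),
         kNN = list(k = c(5L, 11L, 21L)),
         RF  = list(mtry = c(1L, 2L)),
         SVM = list(cost = c(0.5, 2)),
         list())
}

#' Construct a classifier specification
#'
#' @param name Registry name (see [classifier_names()]).
#' @param grid Hyperparameter grid; defaults to [default_grid()].
#' @return A `classifier_spec` with `fit`/`predict_prob` closures.
#' @export
classifier_spec <- function(name, grid = NULL) {
  name <- match.arg(name, classifier_names())
  if (is.null(grid)) grid <- default_grid(name)
  backend <- classifier_backend(name)
  structure(list(name = name, grid = grid,
                 fit = backend$fit, predict_prob = backend$predict_prob,
                 tuned_params = NULL, fitted = NULL),
            class = "classifier_spec")
}

#' Full classifier registry
#' @param names Subset of [classifier_names()] to include.
#' @return Named list of [classifier_spec()] objects.
#' @export
classifier_registry <- function(names = classifier_names()) {
  specs <- lapply(names, classifier_spec)
  names(specs) <- names
  specs
}

classifier_backend <- function(name) {
  switch(
    name,
    LR = list(
      fit = function(train, params) {
        stats::glm(contingent ~ z_d18o + z_d13c + yc, data = train,
                   family = stats::binomial())
      },
      predict_prob = function(state, newdata) {
        clip_prob(stats::predict(state, newdata, type = "response"))
      }
    ),
    MELR = list(
      fit = function(train, params) {
        fit <- tryCatch({
          m <- suppressWarnings(lme4::glmer(
            contingent ~ z_d18o + z_d13c +
              (0 + z_d18o + z_d13c | yc),
            data = train, family = stats::binomial(),
            control = lme4::glmerControl(calc.derivs = FALSE)))
          conv <- m@optinfo$conv$opt
          if (!is.null(conv) && conv != 0) stop("optimizer did not converge")
          m
        }, error = function(e) NULL)
        if (is.null(fit)) {
          warning("MELR: mixed fit did not converge; falling back to fixed year-class x isotope interactions",
                  call. = FALSE)
          fit <- stats::glm(contingent ~ yc * (z_d18o + z_d13c),
                            data = train, family = stats::binomial())
        }
        fit
      },
      predict_prob = function(state, newdata) {
        if (inherits(state, "merMod")) {
          clip_prob(stats::predict(state, newdata, type = "response",
                                   allow.new.levels = TRUE))
        } else {
          clip_prob(stats::predict(state, newdata, type = "response"))
        }
      }
    ),
    LDA = list(
      fit = function(train, params) {
        MASS::lda(contingent ~ z_d18o + z_d13c + yc, data = train)
      },
      predict_prob = function(state, newdata) {
        clip_prob(stats::predict(state, newdata)$posterior[, "northern"])
      }
    ),
    QDA = list(
      fit = function(train, params) {
        MASS::qda(contingent ~ z_d18o + z_d13c + yc, data = train)
      },
      predict_prob = function(state, newdata) {
        clip_prob(stats::predict(state, newdata)$posterior[, "northern"])
      }
    ),
    ANN = list(
      fit = function(train, params) {
        nnet::nnet(contingent ~ z_d18o + z_d13c + yc, data = train,
                   size = params$size, decay = params$decay,
                   maxit = 300, trace = FALSE)
      },
      predict_prob = function(state, newdata) {
        # single output unit models P(second factor level) = northern
        clip_prob(as.numeric(stats::predict(state, newdata, type = "raw")))
      }
    ),
    DT = list(
      fit = function(train, params) {
        rpart::rpart(contingent ~ z_d18o + z_d13c + yc, data = train,
                     method = "class",
                     control = rpart::rpart.control(cp = params$cp))
      },
      predict_prob = function(state, newdata) {
        clip_prob(stats::predict(state, newdata, type = "prob")[, "northern"])
      }
    ),
    kNN = list(
      fit = function(train, params) {
        list(x = onehot_matrix(train), y = train$contingent,
             k = params$k, yc_levels = levels(train$yc))
      },
      predict_prob = function(state, newdata) {
        newdata$yc <- factor(newdata$yc, levels = state$yc_levels)
        pred <- class::knn(state$x, onehot_matrix(newdata), state$y,
                           k = state$k, prob = TRUE)
        win <- attr(pred, "prob")
        clip_prob(ifelse(pred == "northern", win, 1 - win))
      }
    ),
    NB = list(
      fit = function(train, params) {
        e1071::naiveBayes(contingent ~ z_d18o + z_d13c + yc, data = train)
      },
      predict_prob = function(state, newdata) {
        clip_prob(stats::predict(state, newdata, type = "raw")[, "northern"])
      }
    ),
    RF = list(
      fit = function(train, params) {
        randomForest::randomForest(contingent ~ z_d18o + z_d13c + yc,
                                   data = train, ntree = 300,
                                   mtry = params$mtry)
      },
      predict_prob = function(state, newdata) {
        clip_prob(stats::predict(state, newdata, type = "prob")[, "northern"])
      }
    ),
    SVM = list(
      fit = function(train, params) {
        e1071::svm(contingent ~ z_d18o + z_d13c + yc, data = train,
                   kernel = "radial", cost = params$cost,
                   probability = TRUE)
      },
      predict_prob = function(state, newdata) {
        pr <- attr(stats::predict(state, newdata, probability = TRUE),
                   "probabilities")
        clip_prob(pr[, "northern"])
      }
    ),
    "NULL" = list(
      fit = function(train, params) {
        list(p = mean(train$contingent == "northern"))
      },
      predict_prob = function(state, newdata) {
        rep(state$p, nrow(newdata))
      }
    ),
    stop("unknown classifier: ", name, call. = FALSE)
  )
}

fit_classifier <- function(spec, train, params = list()) {
  spec$fitted <- spec$fit(train, params)
  spec$tuned_params <- params
  spec$yc_levels <- levels(train$yc)
  spec
}

predict_classifier <- function(spec, records) {
  if (is.null(spec$fitted)) stop("classifier not fitted", call. = FALSE)
  nd <- model_frame(records, yc_levels = spec$yc_levels)
  p <- as.numeric(spec$predict_prob(spec$fitted, nd))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop(sprintf("classifier %s returned probabilities outside [0,1]",
                 spec$name), call. = FALSE)
  p
}

param_grid_rows <- function(grid) {
  if (!length(grid)) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}
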