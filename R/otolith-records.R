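#' Read otolith records from CSV
#'
#' One row per fish. Required columns: `fish_id`, `d18o`, `d13c`
#' (per-mil VPDB), `year_class`, `age`, `contingent`
#' (`northern`/`southern`/`unknown`). Optional: `subregion`,
#' `collection_year`. Missing values in required columns are rejected.
#'
#' @param path CSV file path.
#' @return A validated data frame of otolith records.
#' @export
read_otolith_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_otolith_records(df)
}

#' Write otolith records to CSV
#' @param records Otolith record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otolith_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Validate otolith records
#'
#' Checks column presence and types, finite isotope values, non-negative
#' ages, contingent levels, and (where both are present) the identity
#' `year_class = collection_year - age`.
#'
#' @param records Data frame of otolith records.
#' @return The records, with `contingent` normalized to lower case.
#' @export
validate_otolith_records <- function(records) {
  required <- c("fish_id", "d18o", "d13c", "year_class", "age", "contingent")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in required) {
    if (anyNA(records[[col]]))
      stop(sprintf("missing values in required column '%s'", col),
           call. = FALSE)
  }
  if (!all(is.finite(records$d18o)) || !all(is.finite(records$d13c)))
    stop("d18o and d13c must be finite", call. = FALSE)
  if (any(records$age < 0)) stop("age must be >= 0", call. = FALSE)
  records$contingent <- tolower(as.character(records$contingent))
  bad <- setdiff(unique(records$contingent),
                 c("northern", "southern", "unknown"))
  if (length(bad))
    stop("contingent must be northern/southern/unknown; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if ("collection_year" %in% names(records)) {
    both <- !is.na(records$collection_year)
    off <- both & (records$year_class !=
                     records$collection_year - records$age)
    if (any(off))
      stop("year_class must equal collection_year - age; violated for fish: ",
           paste(utils::head(records$fish_id[off], 5), collapse = ", "),
           call. = FALSE)
  }
  records
}

#' Filter records into a classification baseline
#'
#' Keeps known-contingent records up to a per-contingent maximum age.
#' Young-of-year baselines are typically age 1; the northern baseline may
#' be augmented with age-2 fish where age-1 coverage is thin, since
#' immigration of southern fish into the northern nursery region before
#' age 2 is rare.
#'
#' @param records Otolith records.
#' @param max_age Named list/vector of maximum baseline age per
#'   contingent. Default `c(northern = 2, southern = 1)`.
#' @return Baseline-eligible records.
#' @export
baseline_filter <- function(records, max_age = c(northern = 2, southern = 1)) {
  records <- validate_otolith_records(records)
  keep <- records$contingent %in% c("northern", "southern") &
    records$age <= unname(max_age[records$contingent])
  records[keep, , drop = FALSE]
}

#' Balance contingent sample sizes by random oversampling
#'
#' Within each year-class, the minority contingent is resampled with
#' replacement (seeded) until both contingents have equal counts. All
#' original records are retained; duplicates only ever copy existing
#' rows, so no isotope value is invented.
#'
#' @param records Baseline records (contingent northern/southern only).
#' @param seed Integer seed controlling the resampling.
#' @param equalize_year_classes If `TRUE`, additionally oversample both
#'   contingents so that every year-class reaches the per-contingent
#'   count of the largest year-class.
#' @return A `baseline_dataset`: list with `records` (balanced data
#'   frame, extra column `.oversampled`), `seed`, and a `NULL`
#'   `standardization` slot until [standardize_baseline()] is applied.
#' @export
oversample_balance <- function(records, seed,
                               equalize_year_classes = FALSE) {
  records <- validate_otolith_records(records)
  if (any(records$contingent == "unknown"))
    stop("baseline records must have known contingent", call. = FALSE)
  ycs <- sort(unique(records$year_class))
  for (yc in ycs) {
    present <- unique(records$contingent[records$year_class == yc])
    if (length(present) < 2)
      stop(sprintf("year-class %s has only one contingent (%s); cannot balance",
                   yc, present), call. = FALSE)
  }
  records$.oversampled <- FALSE
  records$.source_row <- seq_len(nrow(records))
  out <- withr::with_seed(as.integer(seed), {
    pieces <- list(records)
    target_n <- if (equalize_year_classes) {
      max(table(records$year_class, records$contingent))
    } else NA_integer_
    for (yc in ycs) {
      in_yc <- records$year_class == yc
      for (ct in c("northern", "southern")) {
        idx <- which(in_yc & records$contingent == ct)
        other <- which(in_yc & records$contingent != ct)
        tgt <- if (equalize_year_classes) target_n else length(other)
        deficit <- tgt - length(idx)
        if (deficit > 0) {
          dup <- records[sample(idx, deficit, replace = TRUE), , drop = FALSE]
          dup$.oversampled <- TRUE
          pieces[[length(pieces) + 1L]] <- dup
        }
      }
    }
    do.call(rbind, pieces)
  })
  rownames(out) <- NULL
  structure(list(records = out, standardization = NULL,
                 seed = as.integer(seed)),
            class = "baseline_dataset")
}

#' @export
print.baseline_dataset <- function(x, ...) {
  tab <- table(x$records$year_class, x$records$contingent)
  cat(sprintf("<baseline_dataset> %d records, %d year-classes%s\n",
              nrow(x$records), nrow(tab),
              if (is.null(x$standardization)) "" else ", standardized"))
  print(tab)
  invisible(x)
}

#' Standardize baseline isotope predictors to z-scores
#'
#' Computes per-predictor mean and SD on the balanced baseline and stores
#' them so the identical transform can later be applied to unknown adults
#' (the transform is never refit on unknowns). Adds columns `z_d18o`,
#' `z_d13c`.
#'
#' @param ds A `baseline_dataset` from [oversample_balance()].
#' @return The dataset with a populated `standardization` slot.
#' @export
standardize_baseline <- function(ds) {
  stopifnot(inherits(ds, "baseline_dataset"))
  std <- lapply(c(d18o = "d18o", d13c = "d13c"), function(col) {
    x <- ds$records[[col]]
    if (length(unique(x)) < 2)
      stop(sprintf("predictor '%s' has zero variance; cannot standardize", col),
           call. = FALSE)
    list(mean = mean(x), sd = stats::sd(x))
  })
  ds$standardization <- std
  ds$records$z_d18o <- (ds$records$d18o - std$d18o$mean) / std$d18o$sd
  ds$records$z_d13c <- (ds$records$d13c - std$d13c$mean) / std$d13c$sd
  ds
}

#' Apply a stored baseline standardization to new records
#'
#' @param ds A standardized `baseline_dataset`.
#' @param records Otolith records (e.g. unknown adults).
#' @return `records` with `z_d18o`, `z_d13c` columns.
#' @export
apply_standardization <- function(ds, records) {
  if (is.null(ds$standardization))
    stop("baseline dataset is not standardized", call. = FALSE)
  std <- ds$standardization
  records$z_d18o <- (records$d18o - std$d18o$mean) / std$d18o$sd
  records$z_d13c <- (records$d13c - std$d13c$mean) / std$d13c$sd
  records
}

#' Prepare unknown adults for classification
#'
#' Maps adults to year-class via `collection_year - age` where
#' `year_class` is absent, applies the baseline standardization, and
#' (strict mode) drops adults whose year-class has no baseline coverage,
#' flagging them in the `dropped` attribute.
#'
#' @param ds A standardized `baseline_dataset`.
#' @param adults Otolith records of unknown-origin adults.
#' @param strict Drop adults whose year-class is absent from the baseline
#'   (default `TRUE`). With `strict = FALSE` such adults are retained and
#'   classified by a year-class-agnostic fallback.
#' @return Standardized adult records; attribute `dropped` lists excluded
#'   fish ids.
#' @export
prepare_adults <- function(ds, adults, strict = TRUE) {
  if (!"year_class" %in% names(adults) || anyNA(adults$year_class)) {
    if (!all(c("collection_year", "age") %in% names(adults)))
      stop("adults need year_class or collection_year + age", call. = FALSE)
    adults$year_class <- adults$collection_year - adults$age
  }
  adults <- validate_otolith_records(adults)
  adults <- apply_standardization(ds, adults)
  known_yc <- unique(ds$records$year_class)
  unmatched <- !(adults$year_class %in% known_yc)
  dropped <- character(0)
  if (any(unmatched)) {
    if (strict) {
      dropped <- as.character(adults$fish_id[unmatched])
      warning(sprintf("%d adult(s) with year-classes absent from the baseline excluded (strict mode)",
                      sum(unmatched)), call. = FALSE)
      adults <- adults[!unmatched, , drop = FALSE]
    } else {
      adults$.year_class_fallback <- unmatched
    }
  }
  attr(adults, "dropped") <- dropped
  adults
}
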