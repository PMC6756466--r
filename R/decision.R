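#' Inclusion filter for decision modelling
#'
#' The clinical decision model is trained only on patients for whom a
#' treatment decision was genuinely on the table: a completed NIHSS severity
#' score, a known onset time, and a scan completed with at least 30 min left
#' to give thrombolysis within the age-dependent window, i.e.
#' `onset_to_arrival + arrival_to_scan <= treatment_window_min(age) - 30`.
#'
#' @param records cohort data frame (see [synthesize_cohort()]).
#' @return logical vector, TRUE for rows meeting the inclusion criteria.
#' @export
#' @examples
#' co <- synthesize_cohort(make_hospital_profile(), years = 0.1, seed = 1)
#' sum(include_for_decision_modelling(co))
include_for_decision_modelling <- function(records) {
  nihss_cols <- paste0("nihss_", names(nihss_item_max))
  sev_complete <- stats::complete.cases(records[, nihss_cols, drop = FALSE])
  onset_to_scan <- records$onset_to_arrival_min + records$arrival_to_scan_min
  in_time <- !is.na(onset_to_scan) &
    onset_to_scan <= treatment_window_min(records$age) - 30
  sev_complete & records$onset_known & in_time
}

#' Default decision-model feature schema
#'
#' Declares the feature columns and their handling for [build_dataset()]:
#' numeric clinical features (age, NIHSS total and the 15 itemised
#' components, pre-stroke mRS), binary features (sex, comorbidity,
#' medication and stroke-type flags) and one-hot encoding of the hospital
#' attended.
#'
#' @param hospital_onehot encode the attended hospital as one-hot columns.
#' @return a `feature_schema` list with elements `numeric`, `binary`,
#'   `hospital_onehot`.
#' @export
default_feature_schema <- function(hospital_onehot = TRUE) {
  structure(list(
    numeric = c("age", "nihss_total", paste0("nihss_", names(nihss_item_max)),
                "prestroke_mrs"),
    binary = c("sex_male", "ischaemic_stroke", "atrial_fibrillation",
               "hypertension", "diabetes", "prior_stroke", "heart_failure",
               "smoker", "on_anticoagulant", "on_antiplatelet"),
    hospital_onehot = isTRUE(hospital_onehot)
  ), class = "feature_schema")
}

#' Build a decision-modelling dataset
#'
#' Applies the inclusion filter, assembles the feature table in the
#' deterministic column order declared by the schema (hospital one-hot
#' columns last, in sorted hospital order), and extracts the treatment
#' labels. Haemorrhagic strokes meeting the time/severity inclusion remain in
#' the dataset (encoded through the `ischaemic_stroke` flag) so the model can
#' learn the contraindication; set `ischaemic_only = TRUE` to restrict.
#'
#' @param records cohort data frame; ages are assumed pre-censored.
#' @param schema a [default_feature_schema()] object.
#' @param ischaemic_only drop haemorrhagic strokes.
#' @return a `decision_dataset`: list with `features` (data frame), `labels`
#'   (0/1 integer), `hospital_ids` (character), `hospitals` (sorted unique).
#' @export
build_dataset <- function(records, schema = default_feature_schema(),
                          ischaemic_only = FALSE) {
  stopifnot(inherits(schema, "feature_schema"))
  keep <- include_for_decision_modelling(records)
  if (ischaemic_only) keep <- keep & records$stroke_type == "ischaemic"
  rec <- records[keep, , drop = FALSE]
  rec$ischaemic_stroke <- as.integer(rec$stroke_type == "ischaemic")
  cols <- c(schema$numeric, schema$binary)
  missing_cols <- setdiff(cols, names(rec))
  if (length(missing_cols))
    stop("records lack schema feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  feats <- rec[, cols, drop = FALSE]
  hospitals <- sort(unique(as.character(records$hospital_id)))
  if (schema$hospital_onehot) {
    for (h in hospitals)
      feats[[paste0("hosp_", h)]] <- as.integer(rec$hospital_id == h)
  }
  rownames(feats) <- NULL
  structure(list(features = feats,
                 labels = as.integer(rec$thrombolysis_given),
                 hospital_ids = as.character(rec$hospital_id),
                 hospitals = hospitals,
                 schema = schema),
            class = "decision_dataset")
}

#' @export
print.decision_dataset <- function(x, ...) {
  cat(sprintf("Decision-modelling dataset: %d patients, %d features, %d hospitals\n",
              length(x$labels), ncol(x$features), length(x$hospitals)))
  cat(sprintf("  treated: %d (%.1f%%)\n", sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

#' Random-forest classifier specification
#'
#' The pluggable classifier behind the decision model. The default is a
#' random forest (ranger engine) with 500 fully grown trees (minimum node
#' size 1, the classification default): a hospital's model then reproduces
#' its own observed treatment rate when applied to its own patients, while
#' cross-hospital predictions remain genuinely out-of-sample. Any classifier
#' can be substituted by supplying `fit`/`predict` functions with the same
#' signatures.
#'
#' @param num.trees,min.node.size forest hyperparameters.
#' @return a `classifier_spec`: list with `fit(features, labels, seed)`
#'   returning a fitted model and `predict(model, features)` returning 0/1
#'   predictions.
#' @export
rf_classifier <- function(num.trees = 500, min.node.size = 1) {
  structure(list(
    fit = function(features, labels, seed) {
      df <- cbind(features, .y = factor(labels, levels = c(0, 1)))
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = num.trees, min.node.size = min.node.size,
                     seed = seed, num.threads = 1)
    },
    predict = function(model, features) {
      # fixed seed: ranger breaks 250/250 voting ties randomly otherwise
      as.integer(as.character(stats::predict(model, data = features,
                                             num.threads = 1,
                                             seed = 1L)$predictions))
    }
  ), class = "classifier_spec")
}

# Stratified k-fold assignment: per class, shuffle then deal round-robin,
# filling the currently smallest folds first so total fold sizes differ by
# at most one and per-fold class counts differ from proportionality by at
# most one patient.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    sizes <- integer(k)
    for (cls in sort(unique(labels), decreasing = TRUE)) {
      idx <- sample(which(labels == cls))
      for (j in seq_along(idx)) {
        target <- order(sizes, seq_len(k))[1L]  # smallest fold, ties by index
        fold[idx[j]] <- target
        sizes[target] <- sizes[target] + 1L
      }
    }
  })
  fold
}

#' Cross-validated prediction accuracy
#'
#' Stratified k-fold validation of the decision classifier: the data are
#' split into k subsets with near-equal size and class balance, the model is
#' run k times each holding one subset back for testing, and every patient
#' is tested exactly once. Returns the pooled accuracy.
#'
#' @param dataset a [build_dataset()] object.
#' @param k number of folds (default 10).
#' @param classifier a [rf_classifier()] spec.
#' @param seed integer seed (fold assignment and model fits).
#' @return accuracy fraction in [0, 1]; the fold assignment is attached as
#'   attribute `"folds"`.
#' @export
crossvalidated_accuracy <- function(dataset, k = 10L, classifier = rf_classifier(),
                                    seed = 1L) {
  stopifnot(inherits(dataset, "decision_dataset"))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  y <- dataset$labels
  if (length(unique(y)) < 2)
    stop("cross-validation requires both classes present", call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  pred <- integer(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    model <- classifier$fit(dataset$features[!test, , drop = FALSE],
                            y[!test], seed = seed + f)
    pred[test] <- classifier$predict(model,
                                     dataset$features[test, , drop = FALSE])
  }
  acc <- mean(pred == y)
  attr(acc, "folds") <- fold
  acc
}

#' Train a decision model on one hospital's decisions
#'
#' Fits the classifier to the included patients of a single hospital. The
#' returned decision function neutralises hospital-identity features when
#' predicting: the one-hot hospital columns of any cohort it is applied to
#' are set to the training hospital's identity, so predictions reflect that
#' hospital's decision culture applied to the supplied case mix.
#'
#' @param dataset a [build_dataset()] object.
#' @param hospital_id hospital to train on; a vector pools several hospitals
#'   (hospital columns are then zeroed at prediction time).
#' @param classifier a [rf_classifier()] spec.
#' @param seed integer seed.
#' @param min_patients minimum included patients required (default 50).
#' @return a `hospital_decision_model` with a [predict][predict.hospital_decision_model]
#'   method.
#' @export
train_on_hospital <- function(dataset, hospital_id, classifier = rf_classifier(),
                              seed = 1L, min_patients = 50L) {
  stopifnot(inherits(dataset, "decision_dataset"))
  rows <- dataset$hospital_ids %in% hospital_id
  if (sum(rows) < min_patients)
    stop(sprintf("hospital '%s' has %d included patients; %d required",
                 paste(hospital_id, collapse = "+"), sum(rows), min_patients),
         call. = FALSE)
  y <- dataset$labels[rows]
  if (length(unique(y)) < 2)
    stop("training hospital has a single decision class; cannot fit", call. = FALSE)
  model <- classifier$fit(dataset$features[rows, , drop = FALSE], y, seed = seed)
  structure(list(model = model, classifier = classifier,
                 hospital_id = hospital_id,
                 hospital_cols = grep("^hosp_", names(dataset$features),
                                      value = TRUE),
                 n_train = sum(rows),
                 observed_rate = 100 * mean(y)),
            class = "hospital_decision_model")
}

#' Predict treatment decisions with a hospital-trained model
#'
#' @param object a [train_on_hospital()] model.
#' @param newdata feature data frame (as `dataset$features`).
#' @param ... unused.
#' @return 0/1 vector of predicted treat decisions.
#' @export
predict.hospital_decision_model <- function(object, newdata, ...) {
  feats <- newdata
  if (length(object$hospital_cols)) {
    for (col in object$hospital_cols) feats[[col]] <- 0L
    if (length(object$hospital_id) == 1L) {
      own <- paste0("hosp_", object$hospital_id)
      if (own %in% names(feats)) feats[[own]] <- 1L
    }
  }
  object$classifier$predict(object$model, feats)
}

#' @export
print.hospital_decision_model <- function(x, ...) {
  cat(sprintf("Decision model trained on hospital %s (%d patients, observed rate %.0f%%)\n",
              paste(x$hospital_id, collapse = "+"), x$n_train, x$observed_rate))
  invisible(x)
}

#' Decision-transplant matrix
#'
#' Quantifies cross-hospital differences in decision making: entry (i, j) is
#' the percentage of hospital j's included patients that the model trained on
#' hospital i's decisions predicts would be treated. Rows therefore express
#' decision culture (transplanting one hospital's decision making to every
#' cohort) and columns express case mix (one cohort as judged by every
#' hospital).
#'
#' @inheritParams train_on_hospital
#' @return a `decision_matrix`: list with `matrix` (train x cohort, in
#'   percent), `actual_rates` (observed percentages per hospital), and
#'   `hospitals`.
#' @export
decision_transplant_matrix <- function(dataset, classifier = rf_classifier(),
                                       seed = 1L, min_patients = 50L) {
  stopifnot(inherits(dataset, "decision_dataset"))
  hosp <- dataset$hospitals
  models <- lapply(seq_along(hosp), function(i)
    train_on_hospital(dataset, hosp[i], classifier = classifier,
                      seed = seed + i, min_patients = min_patients))
  mat <- matrix(NA_real_, length(hosp), length(hosp),
                dimnames = list(train = hosp, cohort = hosp))
  for (i in seq_along(hosp)) {
    for (j in seq_along(hosp)) {
      rows <- dataset$hospital_ids == hosp[j]
      pred <- predict(models[[i]], dataset$features[rows, , drop = FALSE])
      mat[i, j] <- 100 * mean(pred)
    }
  }
  actual <- vapply(hosp, function(h)
    100 * mean(dataset$labels[dataset$hospital_ids == h]), numeric(1))
  structure(list(matrix = mat, actual_rates = actual, hospitals = hosp),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, digits = 0, ...) {
  cat("Actual thrombolysis use by hospital (%):\n")
  print(round(x$actual_rates, digits))
  cat("\nPredicted use: rows = hospital used to train the decision model,\n")
  cat("columns = hospital whose patients are judged (%):\n")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Benchmark eligibility rate for a hospital
#'
#' Trains the classifier on a reference ("benchmark") set of hospitals and
#' returns the fraction of the target hospital's included patients the
#' benchmark model predicts to treat. This probability feeds the pathway
#' simulator's eligibility gate under the benchmark ("alternative")
#' scenario.
#'
#' @inheritParams train_on_hospital
#' @param benchmark_hospitals hospitals whose pooled decisions define the
#'   benchmark.
#' @param target_hospital hospital whose patients are judged.
#' @return fraction in [0, 1].
#' @export
benchmark_eligibility <- function(dataset, benchmark_hospitals, target_hospital,
                                  classifier = rf_classifier(), seed = 1L,
                                  min_patients = 50L) {
  model <- train_on_hospital(dataset, benchmark_hospitals,
                             classifier = classifier, seed = seed,
                             min_patients = min_patients)
  rows <- dataset$hospital_ids == target_hospital
  if (!any(rows)) stop("no included patients for target hospital", call. = FALSE)
  mean(predict(model, dataset$features[rows, , drop = FALSE]))
}

#' Select the benchmark hospital from a transplant matrix
#'
#' Picks the training hospital with the maximum mean predicted thrombolysis
#' use across cohorts, i.e. the most treatment-predisposed decision culture.
#'
#' @param dm a [decision_transplant_matrix()] result.
#' @return hospital id.
#' @export
select_benchmark_hospital <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  dm$hospitals[which.max(rowMeans(dm$matrix))]
}
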