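#' Construct a subject-grouped dataset
#'
#' The unit of cross-validation is the subject: all scans sharing a
#' subject id leave the training set together, which prevents
#' "twinning" bias (within-subject scan similarity leaking into the
#' test set).
#'
#' @param X Scans x features numeric matrix.
#' @param subject Subject id per scan (length `nrow(X)`).
#' @param label Optional class label per scan; must be constant within
#'   subject.
#' @param age Optional numeric target per scan; constant within subject.
#' @return Object of class `grouped_dataset`.
#' @export
grouped_dataset <- function(X, subject, label = NULL, age = NULL) {
  assert_that(is.matrix(X) && all(is.finite(X)), "X must be a finite matrix")
  subject <- as.character(subject)
  assert_that(length(subject) == nrow(X), "one subject id per scan required")
  counts <- table(subject)
  assert_that(length(unique(counts)) == 1,
              "every subject must contribute the same number of scans")
  check_const <- function(v, what) {
    if (is.null(v)) return(NULL)
    assert_that(length(v) == nrow(X), "one ", what, " per scan required")
    per <- tapply(as.vector(v), subject, function(x) length(unique(x)))
    assert_that(all(per == 1), what, " must be constant within subject")
    v
  }
  structure(list(X = X, subject = subject,
                 label = check_const(label, "label"),
                 age = check_const(if (!is.null(age)) as.numeric(age), "age"),
                 subjects = sort(unique(subject)),
                 scans_per_subject = as.integer(counts[1])),
            class = "grouped_dataset")
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat("<grouped_dataset> ", length(x$subjects), " subjects x ",
      x$scans_per_subject, " scans, ", ncol(x$X), " features\n", sep = "")
  invisible(x)
}

#' Convert a synthetic cohort into a grouped dataset
#'
#' @param cohort A [generate_cohort()] result.
#' @param target `"group"` (class labels), `"sex"`, or `"age"`.
#' @return A [grouped_dataset()].
#' @export
as_grouped_dataset <- function(cohort, target = c("group", "sex", "age")) {
  target <- match.arg(target)
  assert_that(inherits(cohort, "synthetic_cohort"),
              "`cohort` must be a synthetic_cohort")
  ix <- match(cohort$scans$subject_id, cohort$subjects$id)
  if (target == "age") {
    grouped_dataset(cohort$Z, cohort$scans$subject_id,
                    age = cohort$subjects$age[ix])
  } else {
    grouped_dataset(cohort$Z, cohort$scans$subject_id,
                    label = cohort$subjects[[target]][ix])
  }
}

# Training/test row split for one LOOCV fold.  Structural twinning
# guard: no training row may share the held-out subject.
fold_rows <- function(data, held_out) {
  test <- which(data$subject == held_out)
  train <- which(data$subject != held_out)
  assert_that(!any(data$subject[train] == held_out),
              "twinning guard violated for subject ", held_out)
  list(train = train, test = test)
}

subject_label <- function(data) {
  vapply(data$subjects,
         function(s) as.character(data$label[data$subject == s][1]), "")
}

#' Exact binomial upper-tail probability
#'
#' `Pr(X >= n_correct)` for `X ~ Binomial(n_trials, p_chance)`, the
#' significance of an observed correct-classification count when each
#' cross-validation fold is treated as a Bernoulli trial.  Computed by
#' exact summation of the tail, never a normal approximation.
#'
#' @param n_correct Observed number of successes (0..n_trials).
#' @param n_trials Number of trials.
#' @param p_chance Chance success probability in (0, 1).
#' @return Exact tail probability in (0, 1].
#' @export
binomial_tail <- function(n_correct, n_trials, p_chance = 0.5) {
  assert_that(is_count(n_trials), "`n_trials` must be a positive integer")
  assert_that(is.numeric(n_correct) && length(n_correct) == 1 &&
                n_correct == floor(n_correct) &&
                n_correct >= 0 && n_correct <= n_trials,
              "`n_correct` must be an integer in 0..n_trials")
  assert_that(is_number(p_chance) && p_chance > 0 && p_chance < 1,
              "`p_chance` must lie strictly between 0 and 1")
  if (n_correct == 0) return(1)
  pbinom(n_correct - 1, n_trials, p_chance, lower.tail = FALSE)
}

#' Least-squares line through (true, predicted) pairs
#'
#' Ordinary least squares of predicted on true values.  A perfect
#' predictor gives slope 1, intercept 0, R-squared 1; R-squared is the
#' squared Pearson correlation between predicted and true values.
#'
#' @param predicted Predicted ages (or any numeric predictions).
#' @param true True ages; must not be constant.
#' @return List with `slope`, `intercept`, `r_squared`, `residuals`.
#' @export
regression_line <- function(predicted, true) {
  assert_that(is.numeric(predicted) && is.numeric(true) &&
                length(predicted) == length(true) && length(true) >= 3,
              "need >= 3 (predicted, true) pairs")
  assert_that(var(true) > 0, "true values are constant; line undefined")
  fit <- lm(predicted ~ true)
  r <- suppressWarnings(cor(predicted, true))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (is.finite(r)) r^2 else 0,
       residuals = unname(stats::residuals(fit)))
}

new_cv_report <- function(task, folds, subject_table, extra = list()) {
  structure(c(list(task = task, folds = folds, subjects = subject_table),
              extra),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> task = ", x$task, ", ", nrow(x$subjects), " subjects\n",
      sep = "")
  if (!is.null(x$accuracy)) {
    cat("  accuracy ", format(x$accuracy, digits = 4), " (",
        x$n_correct, "/", nrow(x$subjects), "), exact binomial p = ",
        format(x$p_value, digits = 3), "\n", sep = "")
  }
  if (!is.null(x$regression)) {
    cat("  predicted-vs-true line: slope ",
        format(x$regression$slope, digits = 3), ", intercept ",
        format(x$regression$intercept, digits = 3), ", R^2 ",
        format(x$regression$r_squared, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Subject-grouped leave-one-out cross-validation: binary classification
#'
#' For each fold, one subject's scans are held out; a Welch-t filter
#' ranks features on the training scans only, a binary SVM is trained
#' on the top `k`, and the held-out scans are classified.  The subject
#' prediction is the majority vote over its scans (ties broken by the
#' sign of the summed decision values).  Accuracy is counted over
#' subjects and tested against chance 1/2 with the exact binomial tail.
#'
#' @param data A [grouped_dataset()] with a binary `label`.
#' @param k Number of features retained per fold.
#' @param C SVM penalty.
#' @param kernel A [kernel_spec()].
#' @return A `cv_report` with per-fold selections/weights, per-scan and
#'   per-subject predictions, `accuracy` and exact binomial `p_value`.
#' @export
loocv_classify <- function(data, k = 100, C = 0.1,
                           kernel = kernel_spec("linear")) {
  assert_that(inherits(data, "grouped_dataset"), "`data` must be grouped")
  assert_that(!is.null(data$label), "classification needs labels")
  lev <- sort(unique(as.character(data$label)))
  assert_that(length(lev) == 2, "binary classification needs 2 classes")
  subj_lab <- subject_label(data)
  assert_that(all(table(subj_lab) >= 2), "need >= 2 subjects per class")
  y_num <- ifelse(as.character(data$label) == lev[2], 1, -1)

  folds <- lapply(data$subjects, function(s) {
    rows <- fold_rows(data, s)
    assert_that(length(unique(y_num[rows$train])) == 2,
                "a class is absent from the training fold for subject ", s)
    sel <- select_top_t(data$X[rows$train, , drop = FALSE],
                        y_num[rows$train], k)
    model <- train_binary_svm(data$X[rows$train, sel$selected, drop = FALSE],
                              y_num[rows$train], C = C, kernel = kernel)
    scores <- decision_function(model, data$X[rows$test, sel$selected,
                                              drop = FALSE])
    scan_pred <- ifelse(scores >= 0, 1, -1)
    vote <- sum(scan_pred)
    subj_pred <- if (vote != 0) sign(vote) else if (sum(scores) >= 0) 1 else -1
    list(held_out_subject = s, selection = sel,
         weights = if (kernel$kind == "linear") model$w else NULL,
         b = model$b, scan_scores = scores, scan_pred = scan_pred,
         subject_prediction = lev[(subj_pred + 3) / 2],
         correct = lev[(subj_pred + 3) / 2] == subj_lab[s])
  })
  names(folds) <- data$subjects

  subject_table <- data.frame(
    subject = data$subjects,
    true = unname(subj_lab),
    predicted = vapply(folds, function(f) f$subject_prediction, ""),
    correct = vapply(folds, function(f) f$correct, TRUE),
    row.names = NULL)
  n_correct <- sum(subject_table$correct)
  new_cv_report("binary_classification", folds, subject_table,
                list(levels = lev, k = k, C = C, kernel = kernel,
                     n_correct = n_correct,
                     accuracy = n_correct / nrow(subject_table),
                     p_value = binomial_tail(n_correct, nrow(subject_table), 0.5)))
}

#' Subject-grouped LOOCV: Weston-Watkins multiclass classification
#'
#' As [loocv_classify()] but with the all-at-once multiclass SVM.  The
#' per-fold filter ranks features by the largest absolute Welch t over
#' all class pairs; subject prediction is the majority vote over scans
#' with ties broken by summed class scores; chance level in the
#' binomial test is `1/K`.
#'
#' @param data A [grouped_dataset()] with a `label` of K >= 2 classes.
#' @param k Features retained per fold.
#' @param C Penalty.
#' @return A `cv_report`.
#' @export
loocv_multiclass <- function(data, k = 28, C = 0.1) {
  assert_that(inherits(data, "grouped_dataset"), "`data` must be grouped")
  assert_that(!is.null(data$label), "classification needs labels")
  lev <- sort(unique(as.character(data$label)))
  K <- length(lev)
  assert_that(K >= 2, "need at least 2 classes")
  subj_lab <- subject_label(data)
  lab <- as.character(data$label)

  pairs <- utils::combn(lev, 2, simplify = FALSE)
  folds <- lapply(data$subjects, function(s) {
    rows <- fold_rows(data, s)
    lab_tr <- lab[rows$train]
    assert_that(all(lev %in% lab_tr),
                "a class is absent from the training fold for subject ", s)
    # pairwise Welch t over all class pairs; rank by the max |t|
    score <- rep(0, ncol(data$X))
    for (pr in pairs) {
      t_pr <- welch_t_cols(data$X[rows$train, , drop = FALSE][lab_tr %in% pr, ,
                                                              drop = FALSE],
                           lab_tr[lab_tr %in% pr] == pr[1])
      score <- pmax(score, abs(t_pr))
    }
    sel <- top_k_by_abs(score, k, "t")
    model <- train_multiclass_svm(data$X[rows$train, sel$selected,
                                         drop = FALSE], lab_tr, C = C)
    sc <- multiclass_scores(model, data$X[rows$test, sel$selected,
                                          drop = FALSE])
    scan_pred <- model$levels[apply(sc, 1, which.max)]
    tab <- table(factor(scan_pred, levels = model$levels))
    top <- which(tab == max(tab))
    subj_pred <- if (length(top) == 1) model$levels[top] else
      model$levels[top][which.max(colSums(sc[, top, drop = FALSE]))]
    list(held_out_subject = s, selection = sel, scan_scores = sc,
         scan_pred = scan_pred, subject_prediction = subj_pred,
         correct = subj_pred == subj_lab[s])
  })
  names(folds) <- data$subjects

  subject_table <- data.frame(
    subject = data$subjects, true = unname(subj_lab),
    predicted = vapply(folds, function(f) f$subject_prediction, ""),
    correct = vapply(folds, function(f) f$correct, TRUE), row.names = NULL)
  n_correct <- sum(subject_table$correct)
  new_cv_report("multiclass_classification", folds, subject_table,
                list(levels = lev, k = k, C = C, n_correct = n_correct,
                     accuracy = n_correct / nrow(subject_table),
                     p_value = binomial_tail(n_correct, nrow(subject_table),
                                             1 / K)))
}

#' Subject-grouped LOOCV: continuous age prediction with SVR
#'
#' Per fold, features are ranked by absolute correlation with age on
#' the training scans, an epsilon-insensitive SVR is trained on the top
#' `k`, and the held-out subject's predicted age is the mean over its
#' scans.  Performance is the least-squares line of predicted on true
#' subject ages ([regression_line()]).
#'
#' @param data A [grouped_dataset()] with `age`.
#' @param k Features retained per fold.
#' @param C Penalty.
#' @param epsilon Tube half-width.
#' @param kernel A [kernel_spec()].
#' @return A `cv_report` with `regression` (slope, intercept,
#'   r_squared, residuals) over subjects.
#' @export
loocv_svr <- function(data, k = 298, C = 1, epsilon = 0.1,
                      kernel = kernel_spec("linear")) {
  assert_that(inherits(data, "grouped_dataset"), "`data` must be grouped")
  assert_that(!is.null(data$age), "regression needs ages")
  assert_that(length(data$subjects) >= 3, "need >= 3 subjects")

  subj_age <- vapply(data$subjects,
                     function(s) data$age[data$subject == s][1], 0)
  folds <- lapply(data$subjects, function(s) {
    rows <- fold_rows(data, s)
    assert_that(var(data$age[rows$train]) > 0,
                "training ages constant in fold for subject ", s)
    sel <- select_top_corr(data$X[rows$train, , drop = FALSE],
                           data$age[rows$train], k)
    model <- train_svr(data$X[rows$train, sel$selected, drop = FALSE],
                       data$age[rows$train], C = C, epsilon = epsilon,
                       kernel = kernel)
    preds <- predict_svr(model, data$X[rows$test, sel$selected, drop = FALSE])
    list(held_out_subject = s, selection = sel,
         weights = if (kernel$kind == "linear") model$w else NULL,
         b = model$b, scan_pred = preds, subject_prediction = mean(preds))
  })
  names(folds) <- data$subjects

  predicted <- vapply(folds, function(f) f$subject_prediction, 0)
  subject_table <- data.frame(subject = data$subjects,
                              true_age = unname(subj_age),
                              predicted_age = unname(predicted),
                              row.names = NULL)
  reg <- regression_line(predicted, subj_age)
  new_cv_report("svr_regression", folds, subject_table,
                list(k = k, C = C, epsilon = epsilon, kernel = kernel,
                     regression = reg))
}

#' Serialize a cross-validation report
#'
#' Writes `report.json` (summary plus per-fold selections) and
#' `subjects.csv` (per-subject predictions) under `dir`.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  assert_that(inherits(report, "cv_report"), "`report` must be a cv_report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  summary <- list(task = report$task,
                  accuracy = report$accuracy, n_correct = report$n_correct,
                  p_value = report$p_value,
                  regression = report$regression[c("slope", "intercept",
                                                   "r_squared")],
                  folds = lapply(report$folds, function(f) {
                    list(held_out_subject = f$held_out_subject,
                         selected = f$selection$selected,
                         subject_prediction = f$subject_prediction)
                  }))
  jsonlite::write_json(summary[!vapply(summary, is.null, TRUE)],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
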