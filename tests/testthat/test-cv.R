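test_that("binomial_tail matches exact summation and its identities", {
  expect_equal(binomial_tail(0, 10, 0.5), 1)
  expect_equal(binomial_tail(1, 1, 0.5), 0.5)
  # exact summation oracle for 44 of 52 at chance 1/2
  oracle <- sum(choose(52, 44:52)) / 2^52
  expect_equal(binomial_tail(44, 52, 0.5), oracle, tolerance = 1e-12)
  # symmetry: upper tail from 44 equals lower tail to 8
  expect_equal(oracle, sum(choose(52, 0:8)) / 2^52, tolerance = 1e-15)
  # tail(k) + lower-tail(k-1) = 1, and monotone decreasing in k
  for (k in c(0, 1, 7, 13)) {
    expect_equal(binomial_tail(k, 13, 0.3) +
                   pbinom(k - 1, 13, 0.3), 1, tolerance = 1e-12)
  }
  tails <- vapply(0:13, binomial_tail, 0, n_trials = 13, p_chance = 1 / 3)
  expect_true(all(diff(tails) < 0))
  expect_error(binomial_tail(14, 13, 0.5), "0..n_trials")
  expect_error(binomial_tail(3, 13, 1), "between 0 and 1")
})

test_that("regression_line matches the closed-form least squares", {
  true <- c(20, 35, 50, 65, 80)
  expect_equal(regression_line(true, true)[c("slope", "intercept", "r_squared")],
               list(slope = 1, intercept = 0, r_squared = 1))
  shifted <- 0.5 * true + 23
  reg <- regression_line(shifted, true)
  expect_equal(reg$slope, 0.5, tolerance = 1e-12)
  expect_equal(reg$intercept, 23, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  set.seed(6)
  pred <- rnorm(20); tr <- rnorm(20)
  reg2 <- regression_line(pred, tr)
  # normal-equations oracle
  slope_o <- cov(pred, tr) / var(tr)
  expect_equal(reg2$slope, slope_o, tolerance = 1e-12)
  expect_equal(reg2$intercept, mean(pred) - slope_o * mean(tr),
               tolerance = 1e-12)
  expect_equal(reg2$r_squared, cor(pred, tr)^2, tolerance = 1e-12)
  expect_error(regression_line(pred, rep(1, 20)), "constant")
})

test_that("grouped datasets enforce subject structure", {
  X <- matrix(rnorm(12 * 4), 12)
  subj <- rep(c("a", "b", "c", "d"), each = 3)
  d <- grouped_dataset(X, subj, label = rep(c("y", "y", "o", "o"), each = 3))
  expect_equal(d$scans_per_subject, 3L)
  expect_error(grouped_dataset(X[1:11, ], subj[1:11]),
               "same number of scans")
  bad_label <- rep(c("y", "o"), 6)
  expect_error(grouped_dataset(X, subj, label = bad_label),
               "constant within subject")
})

test_that("a noiseless separable cohort is classified perfectly", {
  data <- as_grouped_dataset(noiseless_binary_cohort(), "group")
  rep <- loocv_classify(data, k = 6, C = 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$n_correct, 10L)
  expect_equal(rep$p_value, 0.5^10, tolerance = 1e-12)
})

test_that("reported accuracy equals recomputed per-fold subject correctness", {
  data <- as_grouped_dataset(generate_cohort(two_group_spec(n_per_group = 6,
                                                            seed = 19)),
                             "group")
  rep <- loocv_classify(data, k = 20, C = 0.1)
  truth <- vapply(data$subjects,
                  function(s) data$label[data$subject == s][1], "")
  correct <- vapply(rep$folds,
                    function(f) f$subject_prediction ==
                      truth[f$held_out_subject], TRUE)
  expect_equal(rep$accuracy, mean(correct))
  expect_equal(rep$p_value,
               binomial_tail(sum(correct), length(correct), 0.5))
})

test_that("held-out scans never influence the trained fold (twinning guard)", {
  spec <- two_group_spec(n_per_group = 4, n_rois = 10, seed = 23)
  cohort <- generate_cohort(spec)
  data <- as_grouped_dataset(cohort, "group")
  rep1 <- loocv_classify(data, k = 10, C = 0.1)
  target <- data$subjects[3]
  X_mut <- data$X
  X_mut[data$subject == target, ] <- X_mut[data$subject == target, ] + 50
  data_mut <- grouped_dataset(X_mut, data$subject, label = data$label)
  rep2 <- loocv_classify(data_mut, k = 10, C = 0.1)
  f1 <- rep1$folds[[target]]; f2 <- rep2$folds[[target]]
  expect_identical(f1$selection$selected, f2$selection$selected)
  expect_equal(f1$weights, f2$weights)
  expect_equal(f1$b, f2$b)
})

test_that("permuted labels drive accuracy to chance", {
  spec <- two_group_spec(n_per_group = 10, n_rois = 16,
                         n_informative_edges = 8, seed = 29)
  cohort <- generate_cohort(spec)
  data <- as_grouped_dataset(cohort, "group")
  subj_lab <- vapply(data$subjects,
                     function(s) data$label[data$subject == s][1], "")
  true_rep <- loocv_classify(data, k = 16, C = 0.1)
  perm_reps <- lapply(1:3, function(p) {
    set.seed(1000 + p)
    shuffled <- sample(unname(subj_lab))
    names(shuffled) <- data$subjects
    lab_perm <- shuffled[data$subject]
    loocv_classify(grouped_dataset(data$X, data$subject,
                                   label = unname(lab_perm)),
                   k = 16, C = 0.1)
  })
  # genuine signal is highly significant; permuted labels never are
  # (subject-grouped LOOCV is conservative under the null: its
  # anti-learning bias pushes null accuracy at or below chance)
  expect_lt(true_rep$p_value, 1e-4)
  for (r in perm_reps) {
    expect_gt(r$p_value, 0.01)
    expect_lt(r$accuracy, true_rep$accuracy)
  }
})

test_that("multiclass LOOCV separates clean groups and reduces to binary at K = 2", {
  # wide age gaps between groups so zero-noise classes are separable
  spec3 <- cohort_spec(list(group_spec(4, 19, 30, "young"),
                            group_spec(4, 45, 55, "middle"),
                            group_spec(4, 70, 85, "old")),
                       n_rois = 10, n_informative_edges = 8,
                       edge_effect = 0.6, subject_sd = 0, scan_sd = 0,
                       seed = 31)
  data3 <- as_grouped_dataset(generate_cohort(spec3), "group")
  rep3 <- loocv_multiclass(data3, k = 12, C = 1)
  expect_equal(rep3$accuracy, 1)
  expect_equal(rep3$p_value, (1 / 3)^12, tolerance = 1e-12)

  data2 <- as_grouped_dataset(noiseless_binary_cohort(seed = 11), "group")
  rep_bin <- loocv_classify(data2, k = 6, C = 1)
  rep_mc <- loocv_multiclass(data2, k = 6, C = 1)
  expect_equal(rep_mc$subjects$predicted, rep_bin$subjects$predicted)
})

test_that("SVR LOOCV recovers a noiseless linear age signal and fails on permuted ages", {
  spec <- linear_age_spec(n_subjects = c(8, 6, 6), n_rois = 12,
                          n_informative_edges = 8, edge_effect = 0.3,
                          subject_sd = 0, scan_sd = 0, seed = 37)
  data <- as_grouped_dataset(generate_cohort(spec), "age")
  rep <- loocv_svr(data, k = 8, C = 10, epsilon = 0.1)
  expect_gt(rep$regression$r_squared, 0.99)

  set.seed(38)
  subj_age <- vapply(data$subjects,
                     function(s) data$age[data$subject == s][1], 0)
  perm_age <- sample(unname(subj_age))
  names(perm_age) <- data$subjects
  data_perm <- grouped_dataset(data$X, data$subject,
                               age = unname(perm_age[data$subject]))
  rep_perm <- loocv_svr(data_perm, k = 8, C = 10, epsilon = 0.1)
  expect_lt(rep_perm$regression$r_squared, 0.3)
})

test_that("cross-validation reports serialize deterministically", {
  data <- as_grouped_dataset(noiseless_binary_cohort(seed = 3), "group")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cv_report(loocv_classify(data, k = 5, C = 0.5), d1)
  write_cv_report(loocv_classify(data, k = 5, C = 0.5), d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "subjects.csv")),
                   readLines(file.path(d2, "subjects.csv")))
})
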