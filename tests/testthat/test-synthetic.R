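test_that("cohort structure matches its specification", {
  spec <- cohort_spec(list(group_spec(26, 19, 35, "young"),
                           group_spec(26, 55, 85, "old")),
                      n_rois = 10, n_informative_edges = 5,
                      edge_effect = 0.1, seed = 3)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort$subjects), 52L)
  expect_equal(nrow(cohort$scans), 156L)  # 3 scans per subject
  expect_equal(ncol(cohort$Z), n_features(10))
  expect_true(all(table(cohort$scans$subject_id) == 3))
  young <- cohort$subjects[cohort$subjects$group == "young", ]
  old <- cohort$subjects[cohort$subjects$group == "old", ]
  expect_true(all(young$age >= 19 & young$age <= 35))
  expect_true(all(old$age >= 55 & old$age <= 85))
  # near-balanced sexes within each group
  expect_lte(abs(diff(table(young$sex))), 1)
  expect_equal(nrow(cohort$truth), 5L)
  expect_true(all(cohort$truth$feature %in% seq_len(n_features(10))))
})

test_that("zero noise and no informative edges give a constant cohort", {
  spec <- cohort_spec(list(group_spec(3, 20, 40, "a")),
                      n_rois = 6, subject_sd = 0, scan_sd = 0,
                      baseline_z = 0.3, seed = 8)
  cohort <- generate_cohort(spec)
  expect_true(all(cohort$Z == 0.3))
})

test_that("cohorts are bit-identical under the same seed and differ across seeds", {
  spec <- two_group_spec(seed = 77)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$Z, c2$Z)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$truth, c2$truth)
  spec2 <- two_group_spec(seed = 78)
  expect_gt(max(abs(generate_cohort(spec2)$Z - c1$Z)), 0)
})

test_that("per-subject sub-streams keep existing subjects stable under extension", {
  base <- cohort_spec(list(group_spec(4, 20, 30, "young"),
                           group_spec(4, 60, 70, "old")),
                      n_rois = 8, n_informative_edges = 3,
                      edge_effect = 0.1, seed = 55)
  bigger <- base
  bigger$groups[[2]] <- group_spec(6, 60, 70, "old")
  small <- generate_cohort(base)
  big <- generate_cohort(bigger)
  # appending subjects to the last group leaves all earlier subjects,
  # their ages, the planted edges and their connectomes untouched
  expect_identical(small$truth, big$truth)
  expect_equal(small$subjects, big$subjects[seq_len(8), ])
  expect_equal(small$Z, big$Z[seq_len(24), ])
})

test_that("empirical group difference on a planted edge matches the generative model", {
  # slope 2 z/decade between fixed ages 20 and 80 -> 12 z-units difference
  spec <- cohort_spec(list(group_spec(170, 20, 20, "young"),
                           group_spec(170, 80, 80, "old")),
                      n_rois = 5, n_informative_edges = 2,
                      edge_effect = 2, subject_sd = 0.1, scan_sd = 0.1,
                      seed = 91)
  cohort <- generate_cohort(spec)
  ix <- match(cohort$scans$subject_id, cohort$subjects$id)
  grp <- cohort$subjects$group[ix]
  for (row in seq_len(nrow(cohort$truth))) {
    e <- cohort$truth$feature[row]
    beta <- cohort$truth$beta[row]
    diff_obs <- mean(cohort$Z[grp == "old", e]) -
      mean(cohort$Z[grp == "young", e])
    # closed form: beta * (80 - 20)/10; MC error ~ sqrt(2*0.02/510) z
    expect_equal(diff_obs, beta * 6, tolerance = 0.05)
  }
})

test_that("rendered time series recover the planted z within Fisher sampling error", {
  spec <- cohort_spec(list(group_spec(2, 25, 35, "young")),
                      n_rois = 8, n_volumes = 2000, scans_per_subject = 1,
                      n_informative_edges = 4, edge_effect = 0.1,
                      subject_sd = 0.1, scan_sd = 0.1, seed = 13)
  cohort <- render_timeseries(generate_cohort(spec))
  se <- 3 / sqrt(2000 - 3)
  hit <- 0; total <- 0
  for (si in seq_len(nrow(cohort$scans))) {
    z_obs <- as.numeric(vectorize_connectome(
      correlation_matrix(cohort$timeseries[[si]])))
    # compare against the projected target (nearest correlation matrix),
    # which is what the sampler realizes
    r_target <- tanh(devectorize_connectome(cohort$Z[si, ], 8))
    diag(r_target) <- 1
    r_proj <- as.matrix(Matrix::nearPD(r_target, corr = TRUE)$mat)
    z_target <- as.numeric(vectorize_connectome(r_proj))
    hit <- hit + sum(abs(z_obs - z_target) <= se)
    total <- total + length(z_obs)
  }
  expect_gte(hit / total, 0.97)
})

test_that("single-ROI rendering degenerates to a unit correlation matrix", {
  spec <- cohort_spec(list(group_spec(1, 25, 25, "a")), n_rois = 2,
                      n_volumes = 50, scans_per_subject = 1,
                      subject_sd = 0, scan_sd = 0, baseline_z = 0,
                      seed = 2)
  cohort <- render_timeseries(generate_cohort(spec))
  r <- correlation_matrix(cohort$timeseries[[1]])
  expect_equal(diag(r), c(1, 1))
})

test_that("invalid cohort specifications fail with the offending field named", {
  g <- group_spec(4, 20, 30, "a")
  expect_error(group_spec(0, 20, 30, "a"), "n_subjects")
  expect_error(group_spec(3, 40, 30, "a"), "age_low")
  expect_error(cohort_spec(list(g), n_rois = 5,
                           n_informative_edges = 100),
               "n_informative_edges")
  expect_error(cohort_spec(list(g), tr = 0), "tr")
  expect_error(cohort_spec(list(g), subject_sd = -1), "subject_sd")
})

test_that("cohort tables are written as plain CSV", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(two_group_spec(n_per_group = 2, n_rois = 6,
                                           seed = 5))
  write_cohort(cohort, dir)
  subjects <- read.csv(file.path(dir, "subjects.csv"))
  expect_equal(nrow(subjects), 4L)
  expect_equal(sort(list.files(dir, pattern = "^connectome_")),
               sort(sprintf("connectome_%s_%d.csv",
                            rep(cohort$subjects$id, each = 3), 1:3)))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$feature_number, cohort$truth$feature)
})
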