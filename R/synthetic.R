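#' Define one age group of a synthetic cohort
#'
#' @param n_subjects Number of subjects in the group.
#' @param age_low,age_high Age range in years (inclusive); ages are drawn
#'   uniformly within it.
#' @param label Class label for the group.
#' @return Object of class `group_spec`.
#' @export
#' @examples
#' group_spec(26, 19, 35, "young")
group_spec <- function(n_subjects, age_low, age_high, label) {
  assert_that(is_count(n_subjects), "`n_subjects` must be a positive integer")
  assert_that(is_number(age_low) && is_number(age_high) && age_low <= age_high,
              "need age_low <= age_high")
  assert_that(is.character(label) && length(label) == 1L && nzchar(label),
              "`label` must be a non-empty string")
  structure(list(n_subjects = as.integer(n_subjects),
                 age_low = age_low, age_high = age_high, label = label),
            class = "group_spec")
}

#' Specify a synthetic resting-state cohort
#'
#' Describes a cohort with the statistical structure the downstream
#' analysis assumes: subjects in age groups, a fixed number of scans per
#' subject, and per-scan Fisher-z connectomes in which a planted subset
#' of ROI-pair edges drifts linearly with age.  The generative model for
#' an informative edge `e` of a scan of a subject with age `a` is
#'
#'   `z = baseline_z + beta_e * (a - 50) / 10 + u_subject + noise_scan`
#'
#' with `u_subject ~ N(0, subject_sd)` shared across that subject's
#' scans (this is what makes subject-grouped cross-validation
#' necessary) and `noise_scan ~ N(0, scan_sd)` independent per scan.
#' Non-informative edges omit the age term.  Planted slopes alternate
#' sign, `+edge_effect, -edge_effect, ...`, reflecting that connectivity
#' both strengthens and weakens with age.
#'
#' @param groups List of [group_spec()] objects.
#' @param n_rois Number of ROIs (default 100).
#' @param n_volumes Volumes per scan when time series are rendered
#'   (default 128).
#' @param tr Repetition time in seconds (default 2).
#' @param scans_per_subject Scans per subject (default 3).
#' @param n_informative_edges Number of edges with a planted age effect.
#' @param edge_effect Planted slope magnitude, z-units per decade of age.
#' @param baseline_z Mean connectivity in z units (default 0.3).
#' @param subject_sd,scan_sd Noise standard deviations in z units
#'   (default 0.1 each).
#' @param seed Integer master seed; all randomness flows from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, n_rois = 100, n_volumes = 128, tr = 2.0,
                        scans_per_subject = 3, n_informative_edges = 0,
                        edge_effect = 0, baseline_z = 0.3,
                        subject_sd = 0.1, scan_sd = 0.1, seed = 1L) {
  assert_that(is.list(groups) && length(groups) >= 1 &&
                all(vapply(groups, inherits, TRUE, "group_spec")),
              "`groups` must be a non-empty list of group_spec objects")
  assert_that(is_count(n_rois) && n_rois >= 2, "`n_rois` must be an integer >= 2")
  assert_that(is_count(n_volumes), "`n_volumes` must be a positive integer")
  assert_that(is_number(tr) && tr > 0, "`tr` must be > 0")
  assert_that(is_count(scans_per_subject),
              "`scans_per_subject` must be a positive integer")
  p <- n_features(n_rois)
  assert_that(is.numeric(n_informative_edges) && length(n_informative_edges) == 1 &&
                n_informative_edges >= 0 && n_informative_edges <= p &&
                n_informative_edges == floor(n_informative_edges),
              "`n_informative_edges` must be an integer in 0..", p)
  assert_that(is_number(edge_effect), "`edge_effect` must be a number")
  assert_that(is_number(baseline_z), "`baseline_z` must be a number")
  assert_that(is_number(subject_sd) && subject_sd >= 0, "`subject_sd` must be >= 0")
  assert_that(is_number(scan_sd) && scan_sd >= 0, "`scan_sd` must be >= 0")
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be an integer")
  structure(list(groups = groups, n_rois = as.integer(n_rois),
                 n_volumes = as.integer(n_volumes), tr = tr,
                 scans_per_subject = as.integer(scans_per_subject),
                 n_informative_edges = as.integer(n_informative_edges),
                 edge_effect = edge_effect, baseline_z = baseline_z,
                 subject_sd = subject_sd, scan_sd = scan_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The slope magnitude giving a target scan-level effect size
#'
#' For a two-group design, returns the `edge_effect` (z-units/decade)
#' for which the between-group mean difference on an informative edge
#' equals `d` scan-level noise standard deviations
#' (`sqrt(subject_sd^2 + scan_sd^2)`), i.e. a scan-level Cohen's d of
#' about `d` (age spread within groups adds a little extra variance).
#'
#' @param d Target standardized effect size.
#' @param spec A [cohort_spec()] with exactly two groups.
#' @return Slope magnitude in z-units per decade.
#' @export
edge_effect_for_d <- function(d, spec) {
  assert_that(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  assert_that(length(spec$groups) == 2, "effect-size calibration needs 2 groups")
  mid <- vapply(spec$groups, function(g) (g$age_low + g$age_high) / 2, 0)
  delta_decades <- abs(mid[2] - mid[1]) / 10
  noise_sd <- sqrt(spec$subject_sd^2 + spec$scan_sd^2)
  d * noise_sd / delta_decades
}

#' Generate a synthetic cohort
#'
#' Deterministic given `spec$seed`: cohort-level draws (ages, sexes,
#' informative-edge positions) come from the master seed, and each
#' subject's connectivity noise comes from a per-subject sub-stream, so
#' adding subjects does not reshuffle existing ones.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: a list with
#'   `subjects` (id, age, sex, group), `scans` (subject_id, scan_index),
#'   `Z` (scans x features matrix of Fisher-z connectomes),
#'   `truth` (feature, beta for each planted edge) and the `spec`.
#' @export
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  p <- n_features(spec$n_rois)

  # group-level and edge-level draws come from their own sub-streams, so
  # enlarging one group leaves the others (and the planted edges) intact
  subjects <- do.call(rbind, lapply(seq_along(spec$groups), function(gi) {
    g <- spec$groups[[gi]]
    with_seed(derive_seed(spec$seed, 500000 + gi), {
      data.frame(age = runif(g$n_subjects, g$age_low, g$age_high),
                 sex = rep_len(c("M", "F"), g$n_subjects),
                 group = g$label, stringsAsFactors = FALSE)
    })
  }))
  edges <- if (spec$n_informative_edges > 0) {
    with_seed(derive_seed(spec$seed, 900001),
              sort(sample.int(p, spec$n_informative_edges)))
  } else integer(0)
  n_subj <- nrow(subjects)
  subjects <- data.frame(id = sprintf("S%03d", seq_len(n_subj)), subjects,
                         stringsAsFactors = FALSE)
  betas <- if (length(edges)) spec$edge_effect * rep_len(c(1, -1), length(edges)) else numeric(0)

  nsps <- spec$scans_per_subject
  scans <- data.frame(subject_id = rep(subjects$id, each = nsps),
                      scan_index = rep(seq_len(nsps), n_subj),
                      stringsAsFactors = FALSE)
  Z <- matrix(spec$baseline_z, nrow(scans), p)
  if (length(edges)) {
    age_term <- outer((subjects$age - 50) / 10, betas)  # subjects x edges
    Z[, edges] <- Z[, edges] + age_term[rep(seq_len(n_subj), each = nsps), , drop = FALSE]
  }
  for (s in seq_len(n_subj)) {
    noise <- with_seed(derive_seed(spec$seed, s), {
      u <- rnorm(p, 0, spec$subject_sd)
      e <- matrix(rnorm(nsps * p, 0, spec$scan_sd), nsps, p)
      sweep(e, 2, u, "+")
    })
    rows <- (s - 1) * nsps + seq_len(nsps)
    Z[rows, ] <- Z[rows, ] + noise
  }
  colnames(Z) <- NULL

  out <- list(subjects = subjects, scans = scans, Z = Z,
              truth = data.frame(feature = edges, beta = betas),
              spec = spec)
  class(out) <- "synthetic_cohort"
  validate_cohort(out)
  out
}

validate_cohort <- function(cohort) {
  spec <- cohort$spec
  counts <- table(cohort$scans$subject_id)
  assert_that(all(counts == spec$scans_per_subject),
              "every subject must have exactly ", spec$scans_per_subject, " scans")
  expected <- sum(vapply(spec$groups, function(g) g$n_subjects, 0L))
  assert_that(nrow(cohort$subjects) == expected, "subject count mismatch")
  for (g in spec$groups) {
    a <- cohort$subjects$age[cohort$subjects$group == g$label]
    assert_that(length(a) == g$n_subjects &&
                  all(a >= g$age_low & a <= g$age_high),
                "ages outside declared range for group ", g$label)
  }
  p <- n_features(spec$n_rois)
  assert_that(all(cohort$truth$feature >= 1 & cohort$truth$feature <= p),
              "truth features out of range")
  invisible(cohort)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$scans), " scans, ", ncol(x$Z), " features, ",
      nrow(x$truth), " informative edges\n", sep = "")
  invisible(x)
}

#' Render per-scan ROI time series realizing each scan's connectome
#'
#' For each scan, converts the target z-vector to a correlation matrix
#' (`tanh`), projects it to the nearest valid correlation matrix
#' (Higham's algorithm via `Matrix::nearPD`), factorizes, and draws
#' `n_volumes` Gaussian samples so that the sample Pearson correlation
#' matrix converges to the target as `n_volumes` grows.
#'
#' @param cohort A [generate_cohort()] result.
#' @param n_volumes Number of volumes; defaults to the spec value.
#' @return The cohort with a `timeseries` element: a list of
#'   [scan_timeseries()], one per scan row.
#' @export
render_timeseries <- function(cohort, n_volumes = cohort$spec$n_volumes) {
  assert_that(inherits(cohort, "synthetic_cohort"),
              "`cohort` must be a synthetic_cohort")
  spec <- cohort$spec
  n <- spec$n_rois
  cohort$timeseries <- lapply(seq_len(nrow(cohort$scans)), function(si) {
    r <- tanh(devectorize_connectome(cohort$Z[si, ], n_rois = n))
    diag(r) <- 1
    if (n > 1) {
      pd <- Matrix::nearPD(r, corr = TRUE, maxit = 200)
      r <- as.matrix(pd$mat)
    }
    ch <- tryCatch(chol(r + diag(1e-10, n)), error = function(e) NULL)
    if (is.null(ch)) {
      abort("scan ", si, " (", cohort$scans$subject_id[si], " scan ",
            cohort$scans$scan_index[si],
            "): target matrix not positive definite after projection")
    }
    vals <- with_seed(derive_seed(spec$seed, 100000 + si), {
      t(matrix(rnorm(n_volumes * n), n_volumes, n) %*% ch)
    })
    scan_timeseries(vals, tr = spec$tr)
  })
  cohort
}

#' Render synthetic 4-D volumes from rendered time series
#'
#' Paints each ROI's time series into all voxels whose centre lies
#' inside its sphere, optionally adds voxel-level white noise, and
#' attaches an affine mapping voxel indices to MNI mm.  Background
#' voxels carry pure noise.
#'
#' @param cohort A cohort that has been through [render_timeseries()].
#' @param atlas An [roi_atlas()]; every sphere must fit inside the grid.
#' @param grid_shape Integer 3-vector of voxel counts.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param voxel_noise_sd Standard deviation of additive voxel noise
#'   (default 0).
#' @return List of [image4d()] objects, one per scan row.
#' @export
render_volumes <- function(cohort, atlas, grid_shape = c(16, 16, 16),
                           voxel_size_mm = 4, voxel_noise_sd = 0) {
  assert_that(inherits(cohort, "synthetic_cohort"),
              "`cohort` must be a synthetic_cohort")
  assert_that(!is.null(cohort$timeseries),
              "run render_timeseries() before render_volumes()")
  assert_that(inherits(atlas, "roi_atlas"), "`atlas` must be an roi_atlas")
  assert_that(nrow(atlas) == cohort$spec$n_rois,
              "atlas size must match the cohort's n_rois")
  grid_shape <- as.integer(grid_shape)
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 1),
              "`grid_shape` must be 3 positive integers")

  # affine: world = voxel * size + offset, grid centred on the origin
  offset <- -(grid_shape - 1) / 2 * voxel_size_mm
  affine <- rbind(cbind(diag(voxel_size_mm, 3), offset), c(0, 0, 0, 1))

  lo <- offset
  hi <- offset + (grid_shape - 1) * voxel_size_mm
  for (r in seq_len(nrow(atlas))) {
    c3 <- c(atlas$x[r], atlas$y[r], atlas$z[r])
    if (any(c3 - atlas$radius[r] < lo) || any(c3 + atlas$radius[r] > hi)) {
      abort("ROI ", atlas$index[r], " (", atlas$name[r],
            "): sphere extends outside the voxel grid")
    }
  }

  idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]) - 1,
                               j = seq_len(grid_shape[2]) - 1,
                               k = seq_len(grid_shape[3]) - 1))
  world <- cbind(idx, 1) %*% t(affine)
  membership <- lapply(seq_len(nrow(atlas)), function(r) {
    which((world[, 1] - atlas$x[r])^2 + (world[, 2] - atlas$y[r])^2 +
            (world[, 3] - atlas$z[r])^2 <= atlas$radius[r]^2)
  })

  lapply(seq_along(cohort$timeseries), function(si) {
    ts <- cohort$timeseries[[si]]$values
    nv <- ncol(ts)
    flat <- with_seed(derive_seed(cohort$spec$seed, 200000 + si), {
      m <- if (voxel_noise_sd > 0)
        matrix(rnorm(nrow(world) * nv, 0, voxel_noise_sd), nrow(world), nv)
      else matrix(0, nrow(world), nv)
      for (r in seq_along(membership)) {
        m[membership[[r]], ] <- m[membership[[r]], , drop = FALSE] +
          matrix(ts[r, ], length(membership[[r]]), nv, byrow = TRUE)
      }
      m
    })
    image4d(array(flat, c(grid_shape, nv)), affine, tr = cohort$spec$tr)
  })
}

#' Write a cohort's tables to a directory
#'
#' Emits `subjects.csv` (id, age, sex, group), `truth.csv`
#' (feature_number, beta) and one `connectome_<subject>_<scan>.csv` per
#' scan in [write_connectome()] format.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(data.frame(feature_number = cohort$truth$feature,
                       beta = cohort$truth$beta),
            file.path(dir, "truth.csv"), row.names = FALSE)
  for (si in seq_len(nrow(cohort$scans))) {
    f <- sprintf("connectome_%s_%d.csv", cohort$scans$subject_id[si],
                 cohort$scans$scan_index[si])
    write_connectome(connectome(cohort$Z[si, ], cohort$spec$n_rois),
                     file.path(dir, f))
  }
  invisible(dir)
}
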