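# Sphere extraction on synthetic volumes, including NIfTI round trips.

test_that("sphere voxel membership matches brute-force enumeration", {
  atlas <- roi_atlas(1, "center", 0, 0, 0, radius = 5)
  dims <- c(9, 9, 9); vs <- 3
  offset <- -(dims - 1) / 2 * vs
  affine <- rbind(cbind(diag(vs, 3), offset), c(0, 0, 0, 1))
  img <- image4d(array(rnorm(prod(dims) * 2), c(dims, 2)), affine, tr = 2)

  # brute force: count voxel centers within 5 mm of the origin
  centers <- expand.grid(x = offset[1] + (0:8) * vs,
                         y = offset[2] + (0:8) * vs,
                         z = offset[3] + (0:8) * vs)
  inside <- centers$x^2 + centers$y^2 + centers$z^2 <= 25
  expect_equal(sum(inside), 19L)  # 1 + 6 + 12 centers on a 3 mm grid

  arr <- as.array(img)
  flat <- matrix(arr, prod(dims), 2)
  # expand.grid in extraction enumerates i fastest, as does centers here
  expected <- colMeans(flat[inside, ])
  ts <- extract_roi_timeseries(img, atlas)
  expect_equal(as.numeric(ts$values), expected, tolerance = 1e-12)
})

test_that("constant images extract to constant series", {
  atlas <- synthetic_atlas(2, spacing_mm = 18, radius = 5)
  dims <- c(12, 12, 12)
  offset <- -(dims - 1) / 2 * 4
  affine <- rbind(cbind(diag(4, 3), offset), c(0, 0, 0, 1))
  img <- image4d(array(7.5, c(dims, 5)), affine)
  ts <- extract_roi_timeseries(img, atlas)
  expect_equal(ts$values, matrix(7.5, 2, 5))
})

test_that("rendered volumes round-trip exactly at zero voxel noise", {
  spec <- cohort_spec(list(group_spec(2, 20, 30, "young")),
                      n_rois = 4, n_volumes = 20, scans_per_subject = 1,
                      subject_sd = 0.05, scan_sd = 0.05, seed = 33)
  cohort <- render_timeseries(generate_cohort(spec))
  atlas <- synthetic_atlas(4, spacing_mm = 16, radius = 5)
  vols <- render_volumes(cohort, atlas, grid_shape = c(14, 14, 14),
                         voxel_size_mm = 4, voxel_noise_sd = 0)
  for (si in seq_along(vols)) {
    ts <- extract_roi_timeseries(vols[[si]], atlas)
    expect_equal(ts$values, cohort$timeseries[[si]]$values, tolerance = 1e-10)
  }
})

test_that("voxel averaging inside a sphere suppresses voxel noise", {
  spec <- cohort_spec(list(group_spec(1, 25, 25, "young")),
                      n_rois = 2, n_volumes = 150, scans_per_subject = 1,
                      subject_sd = 0.05, scan_sd = 0.05, seed = 44)
  cohort <- render_timeseries(generate_cohort(spec))
  atlas <- synthetic_atlas(2, spacing_mm = 20, radius = 5)
  # 3 mm grid: 19 voxels per 5 mm sphere; noise shrinks ~ 1/sqrt(19)
  vols <- render_volumes(cohort, atlas, grid_shape = c(20, 20, 20),
                         voxel_size_mm = 3, voxel_noise_sd = 1)
  ts <- extract_roi_timeseries(vols[[1]], atlas)
  for (r in 1:2) {
    expect_gt(cor(ts$values[r, ], cohort$timeseries[[1]]$values[r, ]), 0.95)
  }
})

test_that("spheres outside the grid and empty spheres fail by name", {
  spec <- cohort_spec(list(group_spec(1, 25, 25, "y")), n_rois = 2,
                      n_volumes = 8, scans_per_subject = 1, seed = 5)
  cohort <- render_timeseries(generate_cohort(spec))
  far <- roi_atlas(1:2, c("ok", "outside"), c(0, 500), c(0, 0), c(0, 0))
  expect_error(render_volumes(cohort, far, grid_shape = c(10, 10, 10),
                              voxel_size_mm = 4),
               "outside.*grid|ROI 2")

  atlas <- roi_atlas(1, "tiny", 0, 0, 0, radius = 0.5)
  # grid centers sit at ..., -1.5, 1.5, ...: none within 0.5 mm of origin
  offset <- -(c(8, 8, 8) - 1) / 2 * 3
  affine <- rbind(cbind(diag(3, 3), offset), c(0, 0, 0, 1))
  img <- image4d(array(0, c(8, 8, 8, 3)), affine)
  expect_error(extract_roi_timeseries(img, atlas), "no voxel centre")
})

test_that("NIfTI write/read preserves data, affine, and extraction", {
  spec <- cohort_spec(list(group_spec(1, 30, 30, "y")), n_rois = 3,
                      n_volumes = 12, scans_per_subject = 1,
                      subject_sd = 0.05, scan_sd = 0.05, seed = 21)
  cohort <- render_timeseries(generate_cohort(spec))
  atlas <- synthetic_atlas(3, spacing_mm = 16, radius = 5)
  vols <- render_volumes(cohort, atlas, grid_shape = c(14, 14, 14),
                         voxel_size_mm = 4)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_image_nifti(vols[[1]], path)
  ts_mem <- extract_roi_timeseries(vols[[1]], atlas)
  ts_file <- extract_roi_timeseries(path, atlas)
  expect_equal(ts_file$values, ts_mem$values, tolerance = 1e-5)
  expect_equal(ts_file$tr, 2)
})
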