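#' Extract mean ROI time series from a 4-D image
#'
#' For each atlas ROI, averages the time series of all voxels whose
#' centre lies within `radius` mm (Euclidean distance in world/MNI
#' space) of the sphere centre.
#'
#' @param image A 4-D array with an `affine` attribute, an
#'   `RNifti::niftiImage`, or a path to a NIfTI file.  The affine maps
#'   0-based voxel indices to world mm.
#' @param atlas An [roi_atlas()].
#' @param tr Repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header (`pixdim[4]`) when available.
#' @return A [scan_timeseries()] with one row per ROI, atlas order.
#' @export
extract_roi_timeseries <- function(image, atlas, tr = NULL) {
  assert_that(inherits(atlas, "roi_atlas"), "`atlas` must be an roi_atlas")
  if (is.character(image)) image <- RNifti::readNifti(image)
  affine <- image_affine(image)
  arr <- as.array(image)
  assert_that(length(dim(arr)) == 4, "image must be 4-D (x, y, z, time)")
  if (is.null(tr)) tr <- image_tr(image)
  dims <- dim(arr)[1:3]
  nv <- dim(arr)[4]

  # world coordinates of every voxel centre (0-based voxel convention)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                               j = seq_len(dims[2]) - 1,
                               k = seq_len(dims[3]) - 1))
  world <- cbind(idx, 1) %*% t(affine)

  flat <- matrix(arr, prod(dims), nv)
  out <- matrix(NA_real_, nrow(atlas), nv)
  for (r in seq_len(nrow(atlas))) {
    d2 <- (world[, 1] - atlas$x[r])^2 + (world[, 2] - atlas$y[r])^2 +
      (world[, 3] - atlas$z[r])^2
    inside <- d2 <= atlas$radius[r]^2
    if (!any(inside)) {
      abort("ROI ", atlas$index[r], " (", atlas$name[r],
            "): sphere contains no voxel centre")
    }
    out[r, ] <- colMeans(flat[inside, , drop = FALSE])
  }
  scan_timeseries(out, tr = tr)
}

image_affine <- function(image) {
  if (inherits(image, "niftiImage")) return(unclass(RNifti::xform(image)))
  aff <- attr(image, "affine")
  assert_that(!is.null(aff) && is.matrix(aff) && all(dim(aff) == c(4, 4)),
              "image carries no 4x4 voxel-to-mm affine")
  aff
}

image_tr <- function(image) {
  if (inherits(image, "niftiImage")) {
    pd <- RNifti::pixdim(image)
    if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) return(pd[4])
  }
  tr <- attr(image, "tr")
  if (!is.null(tr) && is.finite(tr) && tr > 0) return(tr)
  2.0
}

#' Construct an in-memory 4-D image
#'
#' Lightweight container used by the synthetic volume renderer: a 4-D
#' array carrying a voxel-to-mm `affine` (0-based voxel convention) and
#' the `tr`.
#'
#' @param data 4-D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param tr Repetition time in seconds.
#' @return The array with attributes set, class `conn_image4d`.
#' @export
image4d <- function(data, affine, tr = 2.0) {
  assert_that(length(dim(data)) == 4, "`data` must be 4-D")
  assert_that(is.matrix(affine) && all(dim(affine) == c(4, 4)),
              "`affine` must be 4x4")
  structure(data, affine = affine, tr = tr, class = "conn_image4d")
}

#' @export
as.array.conn_image4d <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Write an image to NIfTI
#'
#' @param image A `conn_image4d` or plain array with an `affine` attribute.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(image, path) {
  aff <- image_affine(image)
  tr <- image_tr(image)
  arr <- as.array(image)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 4L))
  pd <- RNifti::pixdim(img)
  if (length(pd) >= 4) {
    pd[4] <- tr
    img <- RNifti::`pixdim<-`(img, pd)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
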