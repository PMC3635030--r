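#' Number of ROI-pair features for an atlas of `n_rois` regions
#'
#' The connectome feature space is the strict lower triangle of the
#' `n_rois` x `n_rois` correlation matrix: `n_rois * (n_rois - 1) / 2`
#' values (4950 for the standard 100-ROI atlas).
#'
#' @param n_rois Number of regions of interest.
#' @return Integer feature count.
#' @export
#' @examples
#' n_features(100)  # 4950
n_features <- function(n_rois) {
  assert_that(is_count(n_rois) && n_rois >= 2, "`n_rois` must be an integer >= 2")
  as.integer(n_rois * (n_rois - 1) / 2)
}

#' Map an ROI pair to its linear feature number
#'
#' Features enumerate the strict lower triangle of the ROI-by-ROI
#' correlation matrix column-major with 1-based indices: feature
#' `k(i, j) = (j - 1) * n - j * (j - 1) / 2 + (i - j)` for row ROI
#' `i` > column ROI `j`.  This is the convention used by the published
#' consensus-feature tables (e.g. pair (60, 7) -> 632 among 100 ROIs)
#' and is identical to R's `lower.tri()` ordering.
#'
#' @param i Row ROI index (larger of the pair), vectorised.
#' @param j Column ROI index (smaller of the pair), vectorised.
#' @param n_rois Number of ROIs in the atlas.
#' @return Integer feature number(s) in `1:n_features(n_rois)`.
#' @seealso [feature_to_pair()] for the exact inverse.
#' @export
#' @examples
#' pair_to_feature(60, 7, 100)   # 632
#' pair_to_feature(2, 1, 100)    # 1
#' pair_to_feature(100, 99, 100) # 4950
pair_to_feature <- function(i, j, n_rois = 100) {
  assert_that(is_count(n_rois) && n_rois >= 2, "`n_rois` must be an integer >= 2")
  ok <- is.numeric(i) && is.numeric(j) && length(i) == length(j) &&
    all(is.finite(i)) && all(is.finite(j)) &&
    all(i == floor(i)) && all(j == floor(j))
  assert_that(ok, "`i` and `j` must be integer vectors of equal length")
  assert_that(all(j >= 1) && all(i <= n_rois),
              "ROI indices must lie in 1..n_rois")
  assert_that(all(i > j),
              "row ROI `i` must exceed column ROI `j` (strict lower triangle)")
  as.integer((j - 1) * n_rois - j * (j - 1) / 2 + (i - j))
}

#' Map a linear feature number back to its ROI pair
#'
#' Exact inverse of [pair_to_feature()].
#'
#' @param k Feature number(s) in `1:n_features(n_rois)`.
#' @param n_rois Number of ROIs in the atlas.
#' @return Data frame with columns `feature`, `i` (row ROI), `j` (column ROI).
#' @export
#' @examples
#' feature_to_pair(632, 100)  # i = 60, j = 7
feature_to_pair <- function(k, n_rois = 100) {
  assert_that(is_count(n_rois) && n_rois >= 2, "`n_rois` must be an integer >= 2")
  p <- n_features(n_rois)
  ok <- is.numeric(k) && all(is.finite(k)) && all(k == floor(k)) &&
    all(k >= 1) && all(k <= p)
  assert_that(ok, "feature numbers must be integers in 1..", p)
  k <- as.integer(k)
  # Column j is the largest j with offset(j) = (j-1)*n - j*(j-1)/2 < k.
  # Invert the quadratic offset; correct any rounding at block boundaries.
  n <- n_rois
  jj <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2) + 1
  off <- (jj - 1) * n - jj * (jj - 1) / 2
  too_big <- off >= k
  while (any(too_big)) {
    jj[too_big] <- jj[too_big] - 1L
    off <- (jj - 1) * n - jj * (jj - 1) / 2
    too_big <- off >= k
  }
  ii <- k - off + jj
  data.frame(feature = k, i = as.integer(ii), j = as.integer(jj))
}

#' Fisher z-transformation of correlation coefficients
#'
#' `z = atanh(r)`, with `|r|` clipped to `1 - 1e-7` so that degenerate
#' correlations of exactly +/-1 (which arise for noiseless synthetic
#' data) stay finite.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @export
#' @examples
#' fisher_z(0.5)  # 0.5493
fisher_z <- function(r) {
  assert_that(is.numeric(r) && all(is.finite(r)), "`r` must be finite numeric")
  assert_that(all(abs(r) <= 1), "correlations must satisfy |r| <= 1")
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

#' Vectorize a correlation matrix into a connectome feature vector
#'
#' Retains the strict lower triangle column-major (the canonical feature
#' ordering, see [pair_to_feature()]) and applies the Fisher
#' z-transformation unless the matrix already holds z values.
#'
#' @param m Square symmetric matrix of pairwise correlations (or z values).
#' @param fisher Apply [fisher_z()] to the retained entries (default TRUE).
#' @param tol Symmetry tolerance.
#' @return Object of class `connectome`: the feature vector with
#'   attributes `n_rois` and `convention`.
#' @export
vectorize_connectome <- function(m, fisher = TRUE, tol = 1e-8) {
  assert_that(is.matrix(m) && nrow(m) == ncol(m) && nrow(m) >= 2,
              "`m` must be a square matrix with >= 2 rows")
  assert_that(all(is.finite(m)), "`m` must be finite")
  assert_that(max(abs(m - t(m))) <= tol,
              "`m` is not symmetric within tolerance ", tol)
  z <- m[lower.tri(m)]
  if (fisher) z <- fisher_z(z)
  connectome(z, n_rois = nrow(m))
}

#' Construct a connectome object from a feature vector
#'
#' @param z Numeric vector of Fisher-z connectivity values, length
#'   `n_features(n_rois)`, in the canonical lower-triangular column-major
#'   ordering.
#' @param n_rois Number of ROIs.
#' @return Object of class `connectome`.
#' @export
connectome <- function(z, n_rois) {
  assert_that(is.numeric(z) && all(is.finite(z)), "`z` must be finite numeric")
  assert_that(length(z) == n_features(n_rois),
              "`z` must have length n_rois*(n_rois-1)/2 = ", n_features(n_rois))
  structure(as.numeric(z), n_rois = as.integer(n_rois),
            convention = "lower-triangular, column-major, 1-based",
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", length(x), " Fisher-z features over ",
      attr(x, "n_rois"), " ROIs\n", sep = "")
  invisible(x)
}

#' Rebuild the square z matrix from a connectome vector
#'
#' Inverse of [vectorize_connectome()] up to the (discarded) diagonal,
#' which is set to `diag_value`.
#'
#' @param x A `connectome` or plain numeric vector.
#' @param n_rois Number of ROIs (taken from the object if absent).
#' @param diag_value Value placed on the diagonal (default 0).
#' @return Symmetric `n_rois` x `n_rois` matrix.
#' @export
devectorize_connectome <- function(x, n_rois = attr(x, "n_rois"),
                                   diag_value = 0) {
  assert_that(!is.null(n_rois), "`n_rois` is required for plain vectors")
  assert_that(length(x) == n_features(n_rois),
              "vector length does not match n_rois")
  m <- matrix(diag_value, n_rois, n_rois)
  m[lower.tri(m)] <- as.numeric(x)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Write a connectome to a plain-text table
#'
#' One row per ROI pair: `feature_number, roi_i, roi_j, roi_i_name,
#' roi_j_name, r, z` where `r = tanh(z)`.
#'
#' @param x A `connectome`.
#' @param path Output CSV path.
#' @param atlas Optional [roi_atlas()] supplying ROI names.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path, atlas = NULL) {
  n_rois <- attr(x, "n_rois")
  pairs <- feature_to_pair(seq_along(x), n_rois)
  nm <- function(idx) {
    if (is.null(atlas)) rep(NA_character_, length(idx))
    else atlas$name[idx]
  }
  df <- data.frame(feature_number = pairs$feature,
                   roi_i = pairs$i, roi_j = pairs$j,
                   roi_i_name = nm(pairs$i), roi_j_name = nm(pairs$j),
                   r = tanh(as.numeric(x)), z = as.numeric(x))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a connectome written by [write_connectome()]
#'
#' @param path CSV path.
#' @return A `connectome`.
#' @export
read_connectome <- function(path) {
  df <- read.csv(path)
  assert_that(all(c("feature_number", "z") %in% names(df)),
              "connectome table needs feature_number and z columns")
  df <- df[order(df$feature_number), ]
  p <- nrow(df)
  n_rois <- (1 + sqrt(1 + 8 * p)) / 2
  assert_that(n_rois == floor(n_rois),
              "row count is not a triangular number")
  assert_that(all(df$feature_number == seq_len(p)), "feature numbers must be 1..p")
  connectome(df$z, n_rois = as.integer(n_rois))
}
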