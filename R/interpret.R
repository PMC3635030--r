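#' Consensus features across cross-validation folds
#'
#' The intersection of the selected feature sets over all folds:
#' features the filter retained in *every* fold, which is the standard
#' way to report a stable connectivity signature from per-fold
#' selection.
#'
#' @param selections List of `feature_selection` objects (or plain
#'   integer vectors), one per fold.
#' @return Sorted integer vector of consensus feature numbers.
#' @export
consensus_features <- function(selections) {
  assert_that(is.list(selections) && length(selections) >= 1,
              "need at least one fold")
  sets <- lapply(selections, function(s) {
    v <- if (inherits(s, "feature_selection")) s$selected else as.integer(s)
    assert_that(length(v) >= 1, "a fold has an empty selection")
    v
  })
  sort(Reduce(intersect, sets))
}

#' Aggregate linear model weights over folds for the consensus features
#'
#' For each consensus feature, the signed weight is the mean over folds
#' of the linear model's coefficient for that feature; the reported
#' magnitude is its absolute value.  ROI endpoints come from the
#' canonical feature-index mapping ([feature_to_pair()]).
#'
#' @param folds List of fold results from [loocv_classify()] or
#'   [loocv_svr()] (each carrying `selection` and `weights`); RBF folds
#'   have no interpretable weights and are rejected.
#' @param consensus Integer vector of consensus feature numbers.
#' @param n_rois Number of ROIs in the feature space.
#' @param atlas Optional [roi_atlas()] supplying ROI names.
#' @return Data frame of class `feature_report`: `feature_number`,
#'   `roi_i`, `roi_j` (+ names if atlas given), `weight` (signed mean),
#'   `magnitude`; sorted by feature number.
#' @export
aggregate_feature_weights <- function(folds, consensus, n_rois,
                                      atlas = NULL) {
  assert_that(is.list(folds) && length(folds) >= 1, "need >= 1 fold")
  assert_that(length(consensus) >= 1, "consensus set is empty")
  per_fold <- vapply(folds, function(f) {
    assert_that(!is.null(f$weights),
                "fold has no linear weights (RBF models are not ",
                "interpretable feature-wise)")
    pos <- match(consensus, f$selection$selected)
    assert_that(!anyNA(pos),
                "a consensus feature is missing from a fold's selection")
    f$weights[pos]
  }, numeric(length(consensus)))
  if (is.null(dim(per_fold))) per_fold <- matrix(per_fold, nrow = 1)
  signed <- rowMeans(per_fold)

  pairs <- feature_to_pair(consensus, n_rois)
  out <- data.frame(feature_number = consensus,
                    roi_i = pairs$i, roi_j = pairs$j,
                    weight = signed, magnitude = abs(signed))
  if (!is.null(atlas)) {
    out$roi_i_name <- atlas$name[out$roi_i]
    out$roi_j_name <- atlas$name[out$roi_j]
  }
  out <- out[order(out$feature_number), ]
  rownames(out) <- NULL
  class(out) <- c("feature_report", "data.frame")
  out
}

#' Per-ROI node weights from a feature report
#'
#' A node's (ROI's) importance is proportional to the sum of the
#' weights of the connections incident to it: each feature contributes
#' its signed weight to both of its endpoint ROIs, and the node weight
#' is `|sum of incident signed weights| / 2`.  The one-half constant
#' makes a single printed feature-magnitude table reproduce the
#' corresponding printed node-weight table exactly.  ROIs with no
#' incident feature are omitted.
#'
#' @param report A `feature_report` (or data frame with
#'   `feature_number` and `weight`).
#' @param n_rois Number of ROIs.
#' @param atlas Optional [roi_atlas()] for names.
#' @return Data frame of class `node_weight_table`: `roi_index`
#'   (+ `roi_name` if atlas given), `weight` (>= 0), sorted by ROI.
#' @export
node_weights <- function(report, n_rois, atlas = NULL) {
  assert_that(is.data.frame(report) && nrow(report) >= 1,
              "`report` must be a nonempty data frame")
  assert_that(all(c("feature_number", "weight") %in% names(report)),
              "`report` needs feature_number and weight columns")
  pairs <- feature_to_pair(report$feature_number, n_rois)
  incident <- c(tapply(report$weight, pairs$i, sum),
                tapply(report$weight, pairs$j, sum))
  sums <- tapply(incident, names(incident), sum)
  out <- data.frame(roi_index = as.integer(names(sums)),
                    weight = abs(as.numeric(sums)) / 2)
  out <- out[order(out$roi_index), ]
  if (!is.null(atlas)) out$roi_name <- atlas$name[out$roi_index]
  out <- out[, c("roi_index", intersect("roi_name", names(out)), "weight")]
  rownames(out) <- NULL
  class(out) <- c("node_weight_table", "data.frame")
  out
}

#' Export BrainNet Viewer .node and .edge files
#'
#' The `.node` file has one whitespace-delimited line per atlas ROI:
#' `x y z color size label`, with size equal to the node weight (0 for
#' ROIs absent from the table) and color 1.  The `.edge` file is the
#' full `n_rois` x `n_rois` symmetric matrix of feature weight
#' magnitudes (zero diagonal, zeros for non-report pairs),
#' tab-delimited.
#'
#' @param nodes A [node_weights()] table.
#' @param report A `feature_report`.
#' @param atlas An [roi_atlas()] covering every ROI referenced.
#' @param node_path,edge_path Output file paths.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_brainnet <- function(nodes, report, atlas, node_path, edge_path) {
  assert_that(inherits(atlas, "roi_atlas"), "`atlas` must be an roi_atlas")
  n_rois <- nrow(atlas)
  assert_that(all(nodes$roi_index %in% atlas$index),
              "node table references ROIs missing from the atlas")
  pairs <- feature_to_pair(report$feature_number, n_rois)

  size <- numeric(n_rois)
  size[nodes$roi_index] <- nodes$weight
  node_lines <- sprintf("%g\t%g\t%g\t%d\t%g\t%s",
                        atlas$x, atlas$y, atlas$z, rep(1L, n_rois),
                        size, atlas$name)
  writeLines(node_lines, node_path)

  edge <- matrix(0, n_rois, n_rois)
  mag <- if ("magnitude" %in% names(report)) report$magnitude
         else abs(report$weight)
  edge[cbind(pairs$i, pairs$j)] <- mag
  edge[cbind(pairs$j, pairs$i)] <- mag
  utils::write.table(edge, edge_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}
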