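test_that("consensus is the exact intersection across folds", {
  s1 <- list(1:10, 1:10, 1:10)
  expect_equal(consensus_features(s1), 1:10)
  expect_equal(consensus_features(list(1:5, 6:10)), integer(0))
  set.seed(61)
  sets <- lapply(1:52, function(i) sample.int(4950, 100))
  got <- consensus_features(sets)
  # counting oracle: a feature is consensus iff it appears in all folds
  counts <- table(unlist(lapply(sets, unique)))
  oracle <- sort(as.integer(names(counts)[counts == 52]))
  expect_equal(got, oracle)
  expect_error(consensus_features(list(integer(0))), "empty")
})

test_that("feature weights aggregate as the fold mean", {
  fold <- function(sel, w) list(selection = list(selected = sel),
                                weights = w)
  one <- list(fold(c(2L, 5L, 9L), c(0.5, -0.2, 0.1)))
  rep1 <- aggregate_feature_weights(one, c(2L, 5L, 9L), n_rois = 6)
  expect_equal(rep1$weight, c(0.5, -0.2, 0.1))
  expect_equal(rep1$magnitude, c(0.5, 0.2, 0.1))

  two <- list(fold(c(2L, 5L), c(0.4, -0.3)), fold(c(2L, 5L), c(-0.4, 0.3)))
  rep2 <- aggregate_feature_weights(two, c(2L, 5L), n_rois = 6)
  expect_equal(rep2$weight, c(0, 0))  # cancellation is visible, not hidden

  set.seed(67)
  sel <- sort(sample.int(45, 8))
  folds <- lapply(1:5, function(i) fold(sel, rnorm(8)))
  rep3 <- aggregate_feature_weights(folds, sel, n_rois = 10)
  manual <- rowMeans(vapply(folds, `[[`, numeric(8), "weights"))
  expect_equal(rep3$weight, manual)

  rbf_fold <- list(list(selection = list(selected = 1:3), weights = NULL))
  expect_error(aggregate_feature_weights(rbf_fold, 1:3, 6),
               "not interpretable")
})

test_that("node weights are half the summed incident feature weights", {
  svm_feat <- read.csv(extdata("svm_consensus_features.csv"))
  svm_node <- read.csv(extdata("svm_node_weights.csv"))
  nodes <- node_weights(svm_feat, n_rois = 100)
  # ROIs whose printed incident weights all share one sign reproduce the
  # printed node weight exactly (printed values are 4-digit magnitudes)
  for (roi in c(7, 12, 15, 60)) {
    expect_equal(nodes$weight[nodes$roi_index == roi],
                 svm_node$weight[svm_node$roi_index == roi],
                 tolerance = 5e-4)
  }
  svr_feat <- read.csv(extdata("svr_consensus_features.csv"))
  svr_node <- read.csv(extdata("svr_node_weights.csv"))
  nodes_svr <- node_weights(svr_feat, n_rois = 100)
  expect_equal(nodes_svr$weight[nodes_svr$roi_index == 12],
               svr_node$weight[svr_node$roi_index == 12],
               tolerance = 5e-4)
  # every ROI in the node tables is incident to a reported feature
  expect_true(all(svm_node$roi_index %in% nodes$roi_index))
})

test_that("ROIs with no incident features are omitted", {
  report <- data.frame(feature_number = pair_to_feature(2, 1, 6),
                       weight = 0.8)
  nodes <- node_weights(report, n_rois = 6)
  expect_equal(nodes$roi_index, c(1L, 2L))
  expect_equal(nodes$weight, c(0.4, 0.4))
})

test_that("signed incident sums double-count each feature exactly twice", {
  set.seed(71)
  feats <- sort(sample.int(n_features(10), 12))
  report <- data.frame(feature_number = feats, weight = rnorm(12))
  pairs <- feature_to_pair(report$feature_number, 10)
  incident_sum <- sum(tapply(report$weight, pairs$i, sum)) +
    sum(tapply(report$weight, pairs$j, sum))
  expect_equal(incident_sum, 2 * sum(report$weight), tolerance = 1e-12)
})

test_that("BrainNet files round-trip and the edge matrix is symmetric", {
  atlas <- synthetic_atlas(8)
  report <- data.frame(feature_number = c(pair_to_feature(3, 1, 8),
                                          pair_to_feature(7, 4, 8)),
                       weight = c(0.6, -0.25),
                       magnitude = c(0.6, 0.25))
  nodes <- node_weights(report, n_rois = 8, atlas = atlas)
  node_path <- withr::local_tempfile(fileext = ".node")
  edge_path <- withr::local_tempfile(fileext = ".edge")
  export_brainnet(nodes, report, atlas, node_path, edge_path)

  nl <- read.table(node_path, sep = "\t")
  expect_equal(nrow(nl), 8L)
  expect_equal(nl$V1, atlas$x)
  expect_equal(nl$V5[3], nodes$weight[nodes$roi_index == 3])
  expect_equal(nl$V5[2], 0)  # uninvolved ROI has zero size

  edge <- as.matrix(read.table(edge_path))
  dimnames(edge) <- NULL
  expect_equal(dim(edge), c(8L, 8L))
  expect_equal(edge, t(edge))
  expect_equal(diag(edge), rep(0, 8))
  expect_equal(edge[3, 1], 0.6)
  expect_equal(edge[4, 7], 0.25)
  expect_equal(sum(edge != 0), 4L)

  empty <- data.frame(feature_number = integer(0), weight = numeric(0))
  expect_error(node_weights(empty, 8), "nonempty")
})
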