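#' Welch two-sample t-statistic
#'
#' Unequal-variance t: `(mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)`
#' with n-1 variance denominators.  Features with zero variance in both
#' groups and equal means score 0 by convention (degrees of freedom are
#' not computed: the statistic is used only to *rank* features, never
#' for p-values).
#'
#' @param a,b Numeric sample vectors, each of length >= 2.
#' @return The t statistic.
#' @export
welch_t <- function(a, b) {
  assert_that(is.numeric(a) && is.numeric(b) && length(a) >= 2 && length(b) >= 2,
              "each group needs at least 2 values")
  num <- mean(a) - mean(b)
  den <- sqrt(var(a) / length(a) + var(b) / length(b))
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

# Vectorised Welch t over the columns of X (rows split by the logical
# mask `in_a`).  Zero-denominator columns get 0 (equal means) or +/-Inf.
welch_t_cols <- function(X, in_a) {
  Xa <- X[in_a, , drop = FALSE]
  Xb <- X[!in_a, , drop = FALSE]
  na <- nrow(Xa); nb <- nrow(Xb)
  ma <- colMeans(Xa); mb <- colMeans(Xb)
  va <- colSums(sweep(Xa, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(Xb, 2, mb)^2) / (nb - 1)
  num <- ma - mb
  den <- sqrt(va / na + vb / nb)
  t_stat <- num / den
  t_stat[den == 0 & num == 0] <- 0
  t_stat[den == 0 & num != 0] <- sign(num[den == 0 & num != 0]) * Inf
  t_stat
}

new_feature_selection <- function(selected, scores, k, statistic) {
  structure(list(selected = as.integer(selected),
                 scores = as.numeric(scores), k = as.integer(k),
                 statistic = statistic),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> top ", x$k, " by |", x$statistic, "|: ",
      paste(head(x$selected, 8), collapse = ", "),
      if (x$k > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Shared top-k machinery: rank by |score| descending, ties broken by
# smaller feature number so folds are reproducible.
top_k_by_abs <- function(scores, k, statistic) {
  ord <- order(-abs(scores), seq_along(scores))
  sel <- sort(ord[seq_len(k)])
  new_feature_selection(sel, scores[sel], k, statistic)
}

#' Select the top-k features by absolute Welch t-statistic
#'
#' The per-fold classification filter: a Welch t-test contrasts the two
#' classes on every feature of the *training* rows and the `k` features
#' with the largest absolute t are retained.
#'
#' @param X Scans x features numeric matrix (training rows only).
#' @param labels Binary labels, one per row (any two distinct values).
#' @param k Number of features to retain.
#' @return A `feature_selection` with elements `selected` (sorted
#'   feature numbers), `scores` (their t values) and `k`.
#' @export
select_top_t <- function(X, labels, k) {
  assert_that(is.matrix(X) && nrow(X) == length(labels),
              "`labels` must have one entry per row of X")
  assert_that(is_count(k) && k <= ncol(X), "`k` must be in 1..ncol(X)")
  lv <- unique(labels)
  assert_that(length(lv) == 2, "exactly two classes required, got ", length(lv))
  in_a <- labels == lv[1]
  assert_that(sum(in_a) >= 2 && sum(!in_a) >= 2,
              "each class needs at least 2 rows")
  top_k_by_abs(welch_t_cols(X, in_a), k, "t")
}

#' Select the top-k features by absolute correlation with age
#'
#' The per-fold regression filter: Pearson correlation of every feature
#' with the continuous target (age), ranked by absolute value.
#' Zero-variance features score 0.
#'
#' @param X Scans x features numeric matrix (training rows only).
#' @param age Numeric target, one per row; must not be constant.
#' @param k Number of features to retain.
#' @return A `feature_selection` (scores are correlations).
#' @export
select_top_corr <- function(X, age, k) {
  assert_that(is.matrix(X) && nrow(X) == length(age),
              "`age` must have one entry per row of X")
  assert_that(is_count(k) && k <= ncol(X), "`k` must be in 1..ncol(X)")
  assert_that(is.numeric(age) && all(is.finite(age)), "`age` must be finite")
  assert_that(var(age) > 0, "`age` is constant; correlations undefined")
  r <- suppressWarnings(as.numeric(cor(X, age)))
  r[!is.finite(r)] <- 0  # zero-variance features
  top_k_by_abs(r, k, "r")
}
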