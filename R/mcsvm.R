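#' Train a Weston-Watkins multiclass SVM
#'
#' All-at-once multiclass formulation: a single quadratic program over
#' per-class linear discriminants `(w_m, b_m)` and per-example,
#' per-wrong-class slacks,
#'
#'   `min 1/2 sum_m ||w_m||^2 + C sum_i sum_{m != y_i} xi_im`
#'   subject to `(w_{y_i} - w_m) . x_i + b_{y_i} - b_m >= 1 - xi_im`,
#'   `xi_im >= 0`,
#'
#' solved as an explicit QP (a tiny ridge regularizes the bias/slack
#' block, which enters the objective only linearly).  Prediction is
#' `argmax_m (w_m . x + b_m)` with ties broken by the smallest class
#' index.
#'
#' @param X Examples x features numeric matrix.
#' @param y Class labels: integers `1..K`, or a factor/character vector
#'   (levels sorted to define class indices).
#' @param C Penalty (> 0), default 0.1.
#' @return Object of class `multiclass_svm`: `W` (features x K weight
#'   matrix), `b` (length-K biases), `C`, `levels`, `objective`.
#' @export
train_multiclass_svm <- function(X, y, C = 0.1) {
  assert_that(is.matrix(X) && all(is.finite(X)), "X must be a finite matrix")
  assert_that(length(y) == nrow(X), "one label per row required")
  assert_that(is_number(C) && C > 0, "C must be > 0")
  lev <- sort(unique(as.character(y)))
  K <- length(lev)
  assert_that(K >= 2, "at least two classes required")
  yi <- match(as.character(y), lev)
  n <- nrow(X); p <- ncol(X)

  n_slack <- n * (K - 1)
  dim_theta <- K * p + K + n_slack
  w_ix <- function(m) ((m - 1) * p + 1):(m * p)
  b_ix <- function(m) K * p + m

  ridge <- 1e-10
  H <- diag(c(rep(1, K * p), rep(ridge, K + n_slack)))
  d <- c(rep(0, K * p + K), rep(C, n_slack))

  n_con <- 2 * n_slack
  A <- matrix(0, n_con, dim_theta)
  rhs <- numeric(n_con)
  row <- 0L
  slack <- 0L
  for (i in seq_len(n)) {
    for (m in seq_len(K)) {
      if (m == yi[i]) next
      slack <- slack + 1L
      s_ix <- K * p + K + slack
      row <- row + 1L
      A[row, w_ix(yi[i])] <- -X[i, ]
      A[row, w_ix(m)] <- X[i, ]
      A[row, b_ix(yi[i])] <- -1
      A[row, b_ix(m)] <- 1
      A[row, s_ix] <- -1
      rhs[row] <- -1
      row <- row + 1L
      A[row, s_ix] <- -1
      rhs[row] <- 0
    }
  }

  theta <- qp_ineq(H, d, A, rhs)
  assert_that(all(is.finite(theta)), "multiclass QP did not converge")
  W <- matrix(theta[seq_len(K * p)], p, K)
  b <- theta[K * p + seq_len(K)]
  xi <- pmax(theta[(K * p + K + 1):dim_theta], 0)
  obj <- 0.5 * sum(W^2) + C * sum(xi)

  structure(list(W = W, b = b, C = C, levels = lev, objective = obj),
            class = "multiclass_svm")
}

#' @export
print.multiclass_svm <- function(x, ...) {
  cat("<multiclass_svm> ", length(x$levels), " classes (",
      paste(x$levels, collapse = ", "), "), C = ", x$C, "\n", sep = "")
  invisible(x)
}

#' Per-class scores and class predictions for a multiclass SVM
#'
#' @param model A [train_multiclass_svm()] model.
#' @param X New examples x features matrix (or a single vector).
#' @return `multiclass_scores()` returns the examples x classes score
#'   matrix `X W + b`; `classify_multiclass()` returns the argmax class
#'   labels (ties to the smallest class index).
#' @export
multiclass_scores <- function(model, X) {
  assert_that(inherits(model, "multiclass_svm"),
              "`model` must be a multiclass_svm")
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  assert_that(ncol(X) == nrow(model$W), "feature dimension mismatch")
  sweep(X %*% model$W, 2, model$b, "+")
}

#' @rdname multiclass_scores
#' @export
classify_multiclass <- function(model, X) {
  s <- multiclass_scores(model, X)
  model$levels[apply(s, 1, which.max)]
}
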