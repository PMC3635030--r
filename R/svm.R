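#' Train a soft-margin binary SVM (dual form)
#'
#' Solves the dual quadratic program
#' `max_a sum(a) - 1/2 sum_ij y_i y_j a_i a_j k(x_i, x_j)` subject to
#' `sum(y * a) = 0`, `0 <= a <= C`, with an SMO-style maximal-violating-
#' pair coordinate solver (the working pair is solved analytically each
#' iteration).  The bias is the average of `y_i - f0(x_i)` over margin
#' support vectors (`0 < a_i < C`); when none exist it is the midpoint
#' of the KKT-feasible interval.
#'
#' @param X Examples x features numeric matrix.
#' @param y Labels in \{-1, +1\}, one per row.
#' @param C Soft-margin penalty (> 0).
#' @param kernel A [kernel_spec()] (default linear).
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter Iteration cap.
#' @return Object of class `binary_svm`: `alpha`, `b`, `C`, `kernel`,
#'   `support` (indices with alpha > 0), `w` (linear kernel only),
#'   `objective` (final dual objective value) and the training data
#'   needed for kernel prediction.
#' @export
train_binary_svm <- function(X, y, C = 0.1, kernel = kernel_spec("linear"),
                             tol = 1e-8, max_iter = NULL) {
  assert_that(is.matrix(X) && all(is.finite(X)), "X must be a finite matrix")
  assert_that(length(y) == nrow(X), "one label per row required")
  assert_that(all(y %in% c(-1, 1)), "labels must be -1 or +1")
  assert_that(length(unique(y)) == 2, "both classes must be present")
  assert_that(is_number(C) && C > 0, "C must be > 0")
  n <- nrow(X)
  y <- as.numeric(y)
  K <- kernel_matrix(kernel, X)
  if (is.null(max_iter)) max_iter <- max(20000L, 500L * n)

  alpha <- numeric(n)
  grad <- rep(-1, n)  # gradient of 1/2 a'Qa - e'a at a = 0
  eps <- tol * max(1, C)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # -y*grad is the quantity whose spread across the two index sets
    # measures KKT violation (Keerthi's m - M criterion)
    yg <- -y * grad
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    lo <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] < eps || iter > max_iter) break

    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 0) eta <- 1e-12
    t_star <- (yg[i] - yg[j]) / eta
    # box limits for alpha_i + y_i t and alpha_j - y_j t
    t_hi <- min(if (y[i] > 0) C - alpha[i] else alpha[i],
                if (y[j] > 0) alpha[j] else C - alpha[j])
    t_step <- min(t_star, t_hi)
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    grad <- grad + t_step * y * (K[, i] - K[, j])
  }
  alpha <- pmin(pmax(alpha, 0), C)

  yg <- -y * grad
  margin <- alpha > 1e-7 * C & alpha < C * (1 - 1e-7)
  b <- if (any(margin)) mean(yg[margin]) else {
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    (max(yg[up]) + min(yg[lo])) / 2
  }

  model <- structure(list(alpha = alpha, b = b, C = C, kernel = kernel,
                          support = which(alpha > 1e-9 * C),
                          X = X, y = y,
                          objective = sum(alpha) -
                            0.5 * drop(t(alpha * y) %*% K %*% (alpha * y))),
                     class = "binary_svm")
  if (kernel$kind == "linear") model$w <- drop(t(X) %*% (alpha * y))
  check_binary_svm(model)
  model
}

# Post-training constraint checks; never assumed, always verified.
check_binary_svm <- function(model) {
  n <- length(model$alpha)
  assert_that(all(model$alpha >= 0 & model$alpha <= model$C),
              "dual coefficients escaped the box [0, C]")
  assert_that(abs(sum(model$y * model$alpha)) <= 1e-6 * model$C * n,
              "equality constraint sum(y * alpha) = 0 violated")
  invisible(model)
}

#' @export
print.binary_svm <- function(x, ...) {
  cat("<binary_svm> ", x$kernel$kind, " kernel, C = ", x$C, ", ",
      length(x$support), "/", length(x$alpha), " support vectors\n", sep = "")
  invisible(x)
}

#' SVM decision values
#'
#' `f(x) = sum_j y_j a_j k(x_j, x) + b`; the predicted class is
#' `sign(f(x))`.  For linear models this equals `w . x + b`.
#'
#' @param model A [train_binary_svm()] model.
#' @param X New examples x features matrix (or a single vector).
#' @return Numeric decision values.
#' @export
decision_function <- function(model, X) {
  assert_that(inherits(model, "binary_svm"), "`model` must be a binary_svm")
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  assert_that(ncol(X) == ncol(model$X),
              "feature dimension mismatch: model has ", ncol(model$X),
              ", input has ", ncol(X))
  Kx <- kernel_matrix(model$kernel, X, model$X)
  drop(Kx %*% (model$alpha * model$y)) + model$b
}

#' @rdname decision_function
#' @export
classify <- function(model, X) {
  f <- decision_function(model, X)
  ifelse(f >= 0, 1, -1)
}

#' Explicit weight vector of a linear SVM
#'
#' `w = sum_i y_i a_i x_i`.  Only linear-kernel models have an explicit
#' weight vector; RBF weights live in the kernel feature space and are
#' not interpretable as per-feature contributions.
#'
#' @param model A linear-kernel [train_binary_svm()] model.
#' @return Numeric weight vector, one entry per feature.
#' @export
extract_weights <- function(model) {
  assert_that(inherits(model, c("binary_svm", "svr_model")),
              "`model` must be a binary_svm or svr_model")
  if (model$kernel$kind != "linear") {
    abort("RBF-kernel weights are not interpretable as per-feature ",
          "contributions; weight extraction requires a linear kernel")
  }
  model$w
}
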