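#' Kernel specification
#'
#' @param kind `"linear"` or `"rbf"`.  The Gaussian (RBF) kernel is
#'   `k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`.
#' @param sigma RBF bandwidth (default 2, the standard setting for
#'   Fisher-z connectivity features; ignored for the linear kernel).
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), sigma = 2) {
  kind <- match.arg(kind)
  assert_that(is_number(sigma) && sigma > 0, "`sigma` must be > 0")
  structure(list(kind = kind, sigma = sigma), class = "kernel_spec")
}

#' Kernel (Gram) matrix between two sets of examples
#'
#' @param kernel A [kernel_spec()].
#' @param X Examples x features matrix.
#' @param Y Optional second matrix (defaults to `X`).
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(kernel, X, Y = X) {
  assert_that(inherits(kernel, "kernel_spec"), "`kernel` must be a kernel_spec")
  assert_that(is.matrix(X) && is.matrix(Y) && ncol(X) == ncol(Y),
              "X and Y must be matrices with matching feature counts")
  assert_that(all(is.finite(X)) && all(is.finite(Y)),
              "features must be finite")
  if (kernel$kind == "linear") return(X %*% t(Y))
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * kernel$sigma^2))
}
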