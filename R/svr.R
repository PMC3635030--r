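#' Train an epsilon-insensitive support vector regression model
#'
#' Points within a tube of half-width `epsilon` around the regression
#' function carry no loss; `C` trades tube violations against flatness.
#' The dual is solved in the collapsed variables `beta_i = a_i - a*_i`
#' (which automatically satisfy the complementarity `a_i a*_i = 0`):
#'
#'   `min_beta 1/2 beta' K beta - y' beta + epsilon ||beta||_1`
#'   subject to `sum(beta) = 0`, `-C <= beta <= C`,
#'
#' by SMO-style maximal-violating-pair updates with an exact piecewise-
#' quadratic line search (the L1 term adds kinks where a `beta` crosses
#' zero).
#'
#' @param X Examples x features numeric matrix.
#' @param y Numeric targets.
#' @param C Penalty (> 0), default 1.
#' @param epsilon Tube half-width (>= 0), default 0.1.
#' @param kernel A [kernel_spec()].
#' @param tol KKT violation tolerance.
#' @param max_iter Iteration cap.
#' @return Object of class `svr_model`: `beta`, `alpha`, `alpha_star`,
#'   `b`, `C`, `epsilon`, `kernel`, `support`, `w` (linear only),
#'   `objective` (dual objective value) and the training data.
#' @export
train_svr <- function(X, y, C = 1, epsilon = 0.1,
                      kernel = kernel_spec("linear"),
                      tol = 1e-8, max_iter = NULL) {
  assert_that(is.matrix(X) && all(is.finite(X)), "X must be a finite matrix")
  assert_that(is.numeric(y) && length(y) == nrow(X) && all(is.finite(y)),
              "one finite target per row required")
  assert_that(is_number(C) && C > 0, "C must be > 0")
  assert_that(is_number(epsilon) && epsilon >= 0, "epsilon must be >= 0")
  n <- nrow(X)
  K <- kernel_matrix(kernel, X)
  if (is.null(max_iter)) max_iter <- max(40000L, 1000L * n)

  beta <- numeric(n)
  g0 <- -y  # gradient of the smooth part 1/2 b'Kb - y'b
  eps_tol <- tol * max(1, C)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    up <- g0 + epsilon * ifelse(beta >= 0, 1, -1)   # derivative, beta_i up
    dn <- -g0 + epsilon * ifelse(beta <= 0, 1, -1)  # derivative, beta_i down
    btol <- 1e-10 * C  # coefficients this close to a bound are at it
    can_up <- beta < C - btol
    can_dn <- beta > -C + btol
    if (!any(can_up) || !any(can_dn)) break
    # maximal violating pair; when one index minimizes both derivatives,
    # compare the two ways of excluding it and keep the worse violation
    up_m <- ifelse(can_up, up, Inf)
    dn_m <- ifelse(can_dn, dn, Inf)
    i <- which.min(up_m)
    j <- which.min(dn_m)
    if (i == j) {
      up_alt <- up_m; up_alt[i] <- Inf
      dn_alt <- dn_m; dn_alt[j] <- Inf
      i2 <- which.min(up_alt); j2 <- which.min(dn_alt)
      if (!is.finite(up_alt[i2]) && !is.finite(dn_alt[j2])) break
      if (up_alt[i2] + dn_m[j] <= up_m[i] + dn_alt[j2]) i <- i2 else j <- j2
    }
    if (up[i] + dn[j] > -eps_tol || iter > max_iter) break

    # exact minimization along beta + t (e_i - e_j), t in (0, t_max]
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_max <- min(C - beta[i], beta[j] + C)
    brk <- c(if (beta[i] < 0) -beta[i], if (beta[j] > 0) beta[j])
    brk <- sort(unique(brk[brk > 0 & brk < t_max]))
    bounds <- c(0, brk, t_max)
    slope0 <- g0[i] - g0[j]
    best_t <- 0; best_val <- 0
    for (seg in seq_len(length(bounds) - 1)) {
      a0 <- bounds[seg]; a1 <- bounds[seg + 1]
      mid <- (a0 + a1) / 2
      s_i <- if (beta[i] + mid >= 0) 1 else -1
      s_j <- if (beta[j] - mid >= 0) 1 else -1
      lin <- slope0 + epsilon * (s_i - s_j)
      cand <- if (eta > 0) min(max(-lin / eta, a0), a1) else if (lin < 0) a1 else a0
      for (t in unique(c(cand, a1))) {
        val <- 0.5 * eta * t^2 + slope0 * t +
          epsilon * (abs(beta[i] + t) - abs(beta[i]) +
                       abs(beta[j] - t) - abs(beta[j]))
        if (val < best_val - 1e-15) { best_val <- val; best_t <- t }
      }
    }
    if (best_t <= 0) break
    beta[i] <- beta[i] + best_t
    beta[j] <- beta[j] - best_t
    g0 <- g0 + best_t * (K[, i] - K[, j])
  }
  beta <- pmin(pmax(beta, -C), C)
  snap <- 1e-10 * C
  beta[abs(beta - C) < snap] <- C
  beta[abs(beta + C) < snap] <- -C
  beta[abs(beta) < snap] <- 0

  margin_pos <- beta > 1e-7 * C & beta < C * (1 - 1e-7)
  margin_neg <- beta < -1e-7 * C & beta > -C * (1 - 1e-7)
  if (any(margin_pos) || any(margin_neg)) {
    b <- mean(c(-(g0[margin_pos] + epsilon), -(g0[margin_neg] - epsilon)))
  } else {
    up <- g0 + epsilon * ifelse(beta >= 0, 1, -1)
    dn <- -g0 + epsilon * ifelse(beta <= 0, 1, -1)
    lo <- max(-up[beta < C]) ; hi <- min(dn[beta > -C])
    b <- (lo + hi) / 2
  }

  obj <- -(0.5 * drop(t(beta) %*% K %*% beta) - sum(y * beta) +
             epsilon * sum(abs(beta)))
  model <- structure(list(beta = beta, alpha = pmax(beta, 0),
                          alpha_star = pmax(-beta, 0), b = b, C = C,
                          epsilon = epsilon, kernel = kernel,
                          support = which(abs(beta) > 1e-9 * C),
                          X = X, y = y, objective = obj),
                     class = "svr_model")
  if (kernel$kind == "linear") model$w <- drop(t(X) %*% beta)
  check_svr(model)
  model
}

check_svr <- function(model) {
  n <- length(model$beta)
  assert_that(all(model$alpha >= 0 & model$alpha <= model$C) &&
                all(model$alpha_star >= 0 & model$alpha_star <= model$C),
              "dual coefficients escaped [0, C]")
  assert_that(all(model$alpha * model$alpha_star == 0),
              "complementarity alpha * alpha_star = 0 violated")
  assert_that(abs(sum(model$beta)) <= 1e-6 * model$C * n,
              "equality constraint sum(alpha - alpha_star) = 0 violated")
  invisible(model)
}

#' @export
print.svr_model <- function(x, ...) {
  cat("<svr_model> ", x$kernel$kind, " kernel, C = ", x$C,
      ", epsilon = ", x$epsilon, ", ", length(x$support), "/",
      length(x$beta), " support vectors\n", sep = "")
  invisible(x)
}

#' Predict from an SVR model
#'
#' `f(x) = sum_j (a_j - a*_j) k(x_j, x) + b`; for linear kernels this
#' equals `w . x + b` with `w = sum_j (a_j - a*_j) x_j`.
#'
#' @param model A [train_svr()] model.
#' @param X New examples x features matrix (or a single vector).
#' @return Numeric predictions.
#' @export
predict_svr <- function(model, X) {
  assert_that(inherits(model, "svr_model"), "`model` must be an svr_model")
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  assert_that(ncol(X) == ncol(model$X),
              "feature dimension mismatch: model has ", ncol(model$X),
              ", input has ", ncol(X))
  Kx <- kernel_matrix(model$kernel, X, model$X)
  drop(Kx %*% model$beta) + model$b
}
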