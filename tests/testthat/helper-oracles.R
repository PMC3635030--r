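# Independent oracles used across the suite.
#
# qp_oracle() is a textbook primal active-set method for convex QPs,
# warm-started from pracma::quadprog and iterated to ~1e-10: working-set
# KKT solve, blocking-constraint line search, multiplier-sign dropping.
# The SVM/SVR/multiclass oracles below assemble the *dual* programs of
# the models (the package solves the binary/SVR duals by SMO and the
# multiclass primal), so implementation and oracle take different
# routes to the same optimal value.

qp_oracle <- function(H, d, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                      x0 = NULL, max_iter = 500) {
  nv <- length(d)
  if (is.null(A)) { A <- matrix(0, 0, nv); b <- numeric(0) }
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, nv); beq <- numeric(0) }
  if (is.null(x0)) x0 <- rep(0, nv)
  x <- x0
  scale <- max(1, abs(b), abs(beq))
  W <- which(b - drop(A %*% x) < 1e-7 * scale)
  obj <- function(x) 0.5 * drop(t(x) %*% H %*% x) + sum(d * x)
  # keep only working-set rows that are linearly independent given Aeq
  prune <- function(W) {
    cur <- t(Aeq)
    r0 <- if (ncol(cur)) qr(cur)$rank else 0
    keep <- integer(0)
    for (w in W) {
      aug <- cbind(cur, A[w, ])
      if (qr(aug)$rank > r0) { keep <- c(keep, w); cur <- aug; r0 <- r0 + 1 }
    }
    keep
  }
  for (it in seq_len(max_iter)) {
    W <- prune(W)
    Aw <- rbind(Aeq, A[W, , drop = FALSE])
    bw <- c(beq, b[W])
    nc <- nrow(Aw)
    M <- rbind(cbind(H, t(Aw)), cbind(Aw, matrix(0, nc, nc)))
    r <- c(-d, bw)
    kkt <- tryCatch(solve(M, r), error = function(e) NULL)
    if (is.null(kkt)) kkt <- tryCatch(qr.solve(M, r, tol = 1e-13),
                                      error = function(e) NULL)
    if (is.null(kkt) || any(!is.finite(kkt))) break
    x_star <- kkt[seq_len(nv)]
    mu <- kkt[nv + seq_len(nc)]
    mu_ineq <- if (nc > nrow(Aeq)) mu[(nrow(Aeq) + 1):nc] else numeric(0)
    step <- x_star - x
    if (max(abs(step)) < 1e-12 * max(1, max(abs(x)))) {
      if (length(mu_ineq) && min(mu_ineq) < -1e-9) {
        W <- W[-which.min(mu_ineq)]
        next
      }
      break
    }
    notW <- setdiff(seq_len(nrow(A)), W)
    t_max <- 1; blocker <- NA
    if (length(notW)) {
      As <- drop(A[notW, , drop = FALSE] %*% step)
      slack <- b[notW] - drop(A[notW, , drop = FALSE] %*% x)
      pos <- which(As > 1e-13)
      if (length(pos)) {
        tt <- slack[pos] / As[pos]
        jm <- which.min(tt)
        if (tt[jm] < t_max) { t_max <- max(tt[jm], 0); blocker <- notW[pos[jm]] }
      }
    }
    x <- x + t_max * step
    if (!is.na(blocker)) W <- sort(c(W, blocker))
  }
  list(x = x, value = obj(x))
}

# Optimal dual objective of the binary soft-margin SVM.
svm_dual_oracle <- function(X, y, C, kernel = kernel_spec("linear")) {
  n <- nrow(X)
  K <- kernel_matrix(kernel, X)
  Q <- (y %o% y) * K
  ws <- tryCatch(pracma::quadprog(Q + diag(1e-10, n), rep(-1, n),
                                  Aeq = matrix(y, 1), beq = 0,
                                  lb = rep(0, n), ub = rep(C, n)),
                 error = function(e) list(xmin = rep(0, n)))
  o <- qp_oracle(Q + diag(1e-12, n), rep(-1, n),
                 A = rbind(diag(n), -diag(n)), b = c(rep(C, n), rep(0, n)),
                 Aeq = matrix(y, 1), beq = 0, x0 = ws$xmin)
  -o$value
}

# Optimal dual objective of epsilon-insensitive SVR in (alpha, alpha*).
svr_dual_oracle <- function(X, y, C, epsilon, kernel = kernel_spec("linear")) {
  n <- nrow(X)
  K <- kernel_matrix(kernel, X)
  H <- rbind(cbind(K, -K), cbind(-K, K))
  d <- c(epsilon - y, epsilon + y)
  Aeq <- matrix(c(rep(1, n), rep(-1, n)), 1)
  ws <- tryCatch(pracma::quadprog(H + diag(1e-10, 2 * n), d, Aeq = Aeq,
                                  beq = 0, lb = rep(0, 2 * n),
                                  ub = rep(C, 2 * n)),
                 error = function(e) list(xmin = rep(0, 2 * n)))
  o <- qp_oracle(H + diag(1e-12, 2 * n), d,
                 A = rbind(diag(2 * n), -diag(2 * n)),
                 b = c(rep(C, 2 * n), rep(0, 2 * n)),
                 Aeq = Aeq, beq = 0, x0 = ws$xmin)
  -o$value
}

# Optimal dual objective of the Weston-Watkins multiclass SVM (margin 1).
# Variables alpha_im (m != y_i); w_m = sum_i (delta(y_i = m) A_i -
# alpha_im) x_i with A_i the row sum; objective sum(alpha) -
# 1/2 sum_m ||w_m||^2 under per-class equality constraints and the box.
ww_dual_oracle <- function(X, y_int, C) {
  n <- nrow(X)
  Kcl <- max(y_int)
  Kx <- X %*% t(X)
  vars <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, setdiff(seq_len(Kcl), y_int[i]))))
  nv <- nrow(vars)
  B <- matrix(0, n * Kcl, nv)
  for (v in seq_len(nv)) {
    i <- vars[v, 1]; m <- vars[v, 2]
    B[i + (y_int[i] - 1) * n, v] <- 1
    B[i + (m - 1) * n, v] <- -1
  }
  G <- t(B) %*% kronecker(diag(Kcl), Kx) %*% B
  S <- kronecker(diag(Kcl), matrix(1, 1, n))
  Aeq <- (S %*% B)[-Kcl, , drop = FALSE]  # last class row is redundant
  d <- rep(-1, nv)
  ws <- tryCatch(pracma::quadprog(G + diag(1e-10, nv), d, Aeq = Aeq,
                                  beq = rep(0, nrow(Aeq)),
                                  lb = rep(0, nv), ub = rep(C, nv)),
                 error = function(e) list(xmin = rep(0, nv)))
  o <- qp_oracle(G + diag(1e-12, nv), d,
                 A = rbind(diag(nv), -diag(nv)),
                 b = c(rep(C, nv), rep(0, nv)),
                 Aeq = Aeq, beq = rep(0, nrow(Aeq)), x0 = ws$xmin)
  -o$value
}

rel_diff <- function(a, b) abs(a - b) / max(1, abs(b))
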