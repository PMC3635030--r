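# Internal quadratic-programming helper.
#
# pracma::quadprog terminates at roughly 1e-5 relative accuracy, which
# is too loose for a solver whose optima are checked against duality
# identities.  qp_ineq() therefore treats it as a warm start and
# polishes the solution with an active-set refinement: solve the
# equality-constrained KKT system on the current working set, add the
# most violated constraint when infeasible, drop the most negative
# multiplier when suboptimal, until the working set stabilizes.

# min 1/2 x'Hx + d'x  s.t.  A x <= b.  H must be positive definite.
qp_ineq <- function(H, d, A, b, max_polish = 200L) {
  sol <- pracma::quadprog(H, d, A = A, b = b)
  x <- sol$xmin
  scale_b <- max(1, max(abs(b)))
  act <- which(b - drop(A %*% x) < 1e-6 * scale_b)

  obj <- function(x) 0.5 * drop(t(x) %*% H %*% x) + sum(d * x)
  best <- list(x = x, value = obj(x))
  for (iter in seq_len(max_polish)) {
    if (length(act) == 0) {
      x_try <- tryCatch(solve(H, -d), error = function(e) NULL)
      lambda <- numeric(0)
    } else {
      Aa <- A[act, , drop = FALSE]
      M <- rbind(cbind(H, t(Aa)),
                 cbind(Aa, matrix(0, length(act), length(act))))
      r <- c(-d, b[act])
      kkt <- tryCatch(solve(M, r), error = function(e) NULL)
      if (is.null(kkt)) kkt <- tryCatch(qr.solve(M, r, tol = 1e-12),
                                        error = function(e) NULL)
      if (is.null(kkt)) break
      x_try <- kkt[seq_len(ncol(H))]
      lambda <- -kkt[-seq_len(ncol(H))]
    }
    if (is.null(x_try) || any(!is.finite(x_try))) break
    viol <- drop(A %*% x_try) - b
    worst <- which.max(viol)
    if (viol[worst] > 1e-9 * scale_b) {
      if (worst %in% act) break  # numerical degeneracy; stop polishing
      act <- sort(c(act, worst))
      next
    }
    # feasible: accept if it improves, then check multiplier signs
    if (obj(x_try) <= best$value + 1e-12) best <- list(x = x_try,
                                                       value = obj(x_try))
    if (length(lambda) && min(lambda) < -1e-9) {
      act <- act[-which.min(lambda)]
      next
    }
    break
  }
  best$x
}
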