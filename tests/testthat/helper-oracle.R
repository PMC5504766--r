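# Independent optimization oracles used to certify the package's solvers.
# None of these share code paths with the package: the full objective is
# minimized by smoothed BFGS with analytic gradients and eps-continuation
# (the sparse block eliminated in closed form through its Huber-type
# partial minimum), the TV subproblem by its dual box-constrained QP, the
# elementwise prox by 1-D numeric minimization, and the nuclear-norm prox
# by an exact subdifferential certificate.

# min over (L, S) of 1/2||D-L-S||_F^2 + alpha||L||_* + lambda||S||_1
#                    + beta * sum_i TV(row i of L)
# Setting lambda = Inf forces S = 0, i.e. the low-rank subproblem oracle.
oracle_reglrsd_min <- function(D, alpha, lambda, beta,
                               eps_seq = c(1e-2, 1e-4, 1e-6, 1e-8)) {
  p <- nrow(D); n <- ncol(D)
  hub <- function(r) {
    ifelse(abs(r) <= lambda, 0.5 * r^2, lambda * abs(r) - 0.5 * lambda^2)
  }
  hubd <- function(r) ifelse(abs(r) <= lambda, r, lambda * sign(r))
  fn <- function(v, eps) {
    L <- matrix(v, p, n)
    sv <- svd(L, nu = 0, nv = 0)$d
    tv <- if (n >= 2)
      sum(sqrt((L[, -1, drop = FALSE] - L[, -n, drop = FALSE])^2 + eps^2) -
            eps)
    else 0
    sum(hub(D - L)) + alpha * sum(sqrt(sv^2 + eps^2) - eps) + beta * tv
  }
  gr <- function(v, eps) {
    L <- matrix(v, p, n)
    sv <- svd(L)
    gnuc <- sv$u %*% ((sv$d / sqrt(sv$d^2 + eps^2)) * t(sv$v))
    gtv <- matrix(0, p, n)
    if (n >= 2) {
      dif <- L[, -1, drop = FALSE] - L[, -n, drop = FALSE]
      w <- dif / sqrt(dif^2 + eps^2)
      gtv[, -1] <- gtv[, -1, drop = FALSE] + w
      gtv[, -n] <- gtv[, -n, drop = FALSE] - w
    }
    as.vector(-hubd(D - L) + alpha * gnuc + beta * gtv)
  }
  v <- numeric(p * n)
  for (eps in eps_seq)
    v <- optim(v, fn, gr, eps = eps, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))$par
  L <- matrix(v, p, n)
  r <- D - L
  S <- if (is.finite(lambda)) sign(r) * pmax(abs(r) - lambda, 0)
       else matrix(0, p, n)
  # exact (unsmoothed) objective, term by term
  obj <- 0.5 * sum((D - L - S)^2) + alpha * sum(svd(L, nu = 0, nv = 0)$d) +
    (if (is.finite(lambda)) lambda * sum(abs(S)) else 0) +
    beta * (if (n >= 2) sum(abs(L[, -1, drop = FALSE] -
                                  L[, -n, drop = FALSE])) else 0)
  list(L = L, S = S, objective = obj)
}

# min over L of 1/2||R - L||_F^2 + alpha||L||_* + beta * sum_i TV(row i)
oracle_low_rank_min <- function(R, alpha, beta) {
  oracle_reglrsd_min(R, alpha, lambda = Inf, beta = beta)
}

# exact TV denoising through the dual: min_{|u| <= w} 1/2||v - F'u||^2,
# y* = v - F'u* (strictly convex primal => unique)
oracle_tv <- function(v, w) {
  n <- length(v)
  if (n == 1L || w == 0) return(v)
  ft <- function(u) c(-u, 0) + c(0, u)
  fn <- function(u) { r <- v - ft(u); 0.5 * sum(r^2) }
  gr <- function(u) { r <- v - ft(u); -diff(r) }
  res <- optim(rep(0, n - 1), fn, gr, method = "L-BFGS-B",
               lower = -w, upper = w,
               control = list(maxit = 5000, factr = 1e1))
  v - ft(res$par)
}

# subgradient optimality violation of a claimed TV-denoising solution:
# residual r = v - y must satisfy r = w F' s with s_t in sign(y_{t+1}-y_t)
# (any value in [-1,1] on flat stretches); equivalently the partial sums
# of r stay inside [-w, w], hit +-w with the matching sign at every jump
# of y, and sum to zero overall.  Returns the worst violation.
oracle_tv_optimality <- function(v, w, y) {
  n <- length(v)
  r <- v - y
  cs <- cumsum(r)
  viol <- abs(cs[n])                      # total balance
  if (n >= 2) {
    inner <- cs[seq_len(n - 1)]
    viol <- max(viol, max(abs(inner)) - w, 0)
    jumps <- diff(y)
    at <- which(jumps != 0)
    if (length(at))
      viol <- max(viol, max(abs(-inner[at] - w * sign(jumps[at]))))
  }
  viol
}

# elementwise prox oracle: min_s 1/2 (x - s)^2 + tau |s| by 1-D search
oracle_soft_threshold <- function(x, tau) {
  vapply(as.vector(x), function(xi) {
    optimize(function(s) 0.5 * (xi - s)^2 + tau * abs(s),
             lower = min(xi, 0) - 1, upper = max(xi, 0) + 1,
             tol = 1e-12)$minimum
  }, numeric(1))
}

# exact optimality certificate for the nuclear-norm prox
#   L* = argmin 1/2||X - L||_F^2 + tau ||L||_*
# iff  G = X - L* lies in tau * subdiff(||.||_*)(L*), i.e.
#   ||G||_2 <= tau  and  <G, L*> = tau ||L*||_*.
# Returns c(spectral_excess, alignment_gap); both ~0 at the optimum.
oracle_nuclear_prox_certificate <- function(X, tau, L) {
  G <- X - L
  spec <- max(svd(G, nu = 0, nv = 0)$d)
  nuc <- sum(svd(L, nu = 0, nv = 0)$d)
  c(spectral_excess = max(spec - tau, 0),
    alignment_gap = abs(sum(G * L) - tau * nuc))
}
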