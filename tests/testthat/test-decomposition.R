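test_that("sparse update is the exact l1-prox of the residual", {
  d <- matrix(runif(12), 4, 3)
  expect_equal(update_sparse(d, d, 0.5), matrix(0, 4, 3))
  l <- d - matrix(runif(12, -0.05, 0.05), 4, 3)
  expect_equal(update_sparse(d, l, 0.1), matrix(0, 4, 3))  # all below lam
  expect_error(update_sparse(d, matrix(0, 3, 4), 0.1), "dimension")
  # 3x3 vs elementwise prox oracle
  set.seed(31)
  d <- matrix(rnorm(9), 3, 3); l <- matrix(rnorm(9), 3, 3)
  expect_equal(as.vector(update_sparse(d, l, 0.1)),
               oracle_soft_threshold(d - l, 0.1), tolerance = 1e-6)
})

test_that("objective evaluates all four terms", {
  z <- matrix(0, 3, 4)
  ctrl <- reglrsd_control(lambda = 0.3)
  expect_equal(reglrsd_objective(z, z, z, ctrl), 0)
  d <- matrix(runif(12), 3, 4)
  expect_equal(reglrsd_objective(d, z, d, ctrl), 0.3 * sum(abs(d)))
  # independent term-by-term recomputation on a 4x3 instance
  set.seed(37)
  d <- matrix(rnorm(12), 4, 3)
  l <- matrix(rnorm(12), 4, 3); s <- matrix(rnorm(12), 4, 3)
  ctrl <- reglrsd_control(alpha = 1.3, lambda = 0.4, beta = 0.2)
  expected <- 0.5 * norm(d - l - s, "F")^2 +
    1.3 * sum(svd(l)$d) + 0.4 * sum(abs(s)) +
    0.2 * sum(apply(l, 1, function(r) sum(abs(diff(r)))))
  expect_equal(reglrsd_objective(d, l, s, ctrl), expected)
  expect_error(reglrsd_objective(d, l, matrix(0, 3, 4), ctrl), "dimension")
})

test_that("ADMM low-rank step solves the regularized subproblem", {
  ctrl <- reglrsd_control(admm_tol = 1e-9, admm_max_iter = 1000)
  d <- matrix(runif(20), 5, 4)
  # zero residual: L = 0 is a fixed point from zero initialization
  expect_equal(admm_low_rank(d, d, ctrl)$L, matrix(0, 5, 4))
  # beta = 0 reduces to the nuclear-norm prox of D - S (closed form built
  # here directly from the SVD, independent of the package's svt path)
  set.seed(41)
  d <- matrix(rnorm(20), 5, 4); s <- matrix(rnorm(20, sd = 0.3), 5, 4)
  ctrl0 <- reglrsd_control(beta = 0, admm_tol = 1e-10,
                           admm_max_iter = 2000)
  got <- admm_low_rank(d, s, ctrl0)$L
  sv <- svd(d - s)
  want <- sv$u %*% (pmax(sv$d - ctrl0$alpha, 0) * t(sv$v))
  expect_lt(sqrt(sum((got - want)^2)), 1e-4)
  # general 6x5 instance against the smoothed-BFGS oracle on the same
  # subproblem objective
  d <- matrix(rnorm(30), 6, 5); s <- matrix(rnorm(30, sd = 0.3), 6, 5)
  ctrl1 <- reglrsd_control(alpha = 1, beta = 0.1, rho = 1,
                           admm_tol = 1e-10, admm_max_iter = 3000)
  L <- admm_low_rank(d, s, ctrl1)$L
  obj <- function(l) 0.5 * sum((d - s - l)^2) + sum(svd(l)$d) +
    0.1 * sum(apply(l, 1, function(r) sum(abs(diff(r)))))
  orc <- oracle_low_rank_min(d - s, alpha = 1, beta = 0.1)
  expect_lt(obj(L) - orc$objective, 1e-5)
})

test_that("the alternating solver reaches the convex optimum", {
  set.seed(43)
  for (i in 1:5) {
    p <- sample(4:8, 1); n <- sample(4:8, 1)
    d <- matrix(abs(rnorm(p * n)), p, n)
    lam <- 1 / sqrt(max(p, n))
    fit <- suppressWarnings(
      reglrsd(d, outer_tol = 1e-10, outer_max_iter = 2000,
              admm_tol = 1e-9, admm_max_iter = 500))
    orc <- oracle_reglrsd_min(d, 1, lam, 0.1)
    rel <- abs(tail(fit$objective, 1) - orc$objective) /
      max(1e-12, abs(orc$objective))
    expect_lt(rel, 1e-4)
  }
})

test_that("beta = 0 recovers the plain robust-PCA relaxation optimum", {
  set.seed(47)
  for (i in 1:3) {
    p <- sample(4:7, 1); n <- sample(4:7, 1)
    d <- matrix(abs(rnorm(p * n)), p, n)
    lam <- 1 / sqrt(max(p, n))
    fit <- suppressWarnings(
      reglrsd(d, beta = 0, outer_tol = 1e-10, outer_max_iter = 2000,
              admm_tol = 1e-9, admm_max_iter = 500))
    orc <- oracle_reglrsd_min(d, 1, lam, 0)
    rel <- abs(tail(fit$objective, 1) - orc$objective) /
      max(1e-12, abs(orc$objective))
    expect_lt(rel, 1e-4)
  }
})

test_that("objective trace is non-increasing across outer iterations", {
  set.seed(53)
  for (i in 1:8) {
    p <- sample(5:15, 1); n <- sample(4:10, 1)
    d <- matrix(abs(rnorm(p * n)) * sample(c(0.5, 1, 4), 1), p, n)
    fit <- suppressWarnings(reglrsd(d))
    tr <- fit$objective
    if (length(tr) > 1)
      expect_true(all(diff(tr) <= 1e-10 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("degenerate and edge inputs behave as documented", {
  # zero matrix: zero fixed point
  fit <- reglrsd(matrix(0, 4, 3))
  expect_equal(fit$L, matrix(0, 4, 3, dimnames = dimnames(fit$L)))
  expect_equal(fit$S, matrix(0, 4, 3, dimnames = dimnames(fit$S)))
  expect_equal(tail(fit$objective, 1), 0)
  expect_true(fit$converged)
  # all-zero rows pass through as zero rows of both components
  set.seed(59)
  d <- matrix(abs(rnorm(24)), 8, 3); d[c(2, 5), ] <- 0
  fit <- suppressWarnings(reglrsd(d))
  expect_equal(fit$L[c(2, 5), ], matrix(0, 2, 3),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(fit$S[c(2, 5), ], matrix(0, 2, 3),
               ignore_attr = TRUE, tolerance = 1e-8)
  # non-convergence is a warning plus converged = FALSE, not an error
  d <- matrix(abs(rnorm(40)), 8, 5)
  expect_warning(fit <- reglrsd(d, outer_max_iter = 2), "converge")
  expect_false(fit$converged)
  # empty input is rejected
  expect_error(reglrsd(matrix(numeric(0), 0, 0)), "sample")
  # default lambda honors 1/sqrt(max(n, p))
  fit <- suppressWarnings(reglrsd(matrix(runif(50), 10, 5)))
  expect_equal(fit$lambda, 1 / sqrt(10))
})

test_that("positive rescaling of the data keeps the contract intact", {
  set.seed(61)
  d <- matrix(abs(rnorm(30)), 6, 5)
  for (c0 in c(0.1, 1, 25)) {
    fit <- suppressWarnings(reglrsd(c0 * d))
    expect_identical(dim(fit$L), dim(d))
    expect_true(all(is.finite(fit$L)) && all(is.finite(fit$S)))
    tr <- fit$objective
    if (length(tr) > 1)
      expect_true(all(diff(tr) <= 1e-10 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("class-block reordering is undone in the outputs", {
  set.seed(67)
  p <- 10; n <- 8
  values <- matrix(abs(rnorm(p * n, 1, 0.2)), p, n)
  ids <- sprintf("s%d", 1:n)
  labels <- setNames(rep(c("a", "b"), length.out = n), ids)  # interleaved
  tab <- abundance_table(values, sample_ids = ids, labels = labels)
  fit <- suppressWarnings(reglrsd(tab))
  expect_identical(colnames(fit$L), ids)
  expect_identical(colnames(fit$S), ids)
  # reordering affects the smoothness penalty, so fits may differ, but
  # both must reconstruct D to the same fidelity scale
  fit0 <- suppressWarnings(reglrsd(tab, reorder_by_class = FALSE))
  expect_identical(colnames(fit0$L), ids)
  expect_equal(dim(fit0$S), dim(fit$S))
})

test_that("fit accessors expose decomposition pieces", {
  set.seed(71)
  d <- matrix(abs(rnorm(40)), 8, 5)
  fit <- suppressWarnings(reglrsd(d))
  expect_equal(fitted(fit), fit$L + fit$S, ignore_attr = TRUE)
  expect_equal(residuals(fit), fit$D - fit$L - fit$S, ignore_attr = TRUE)
  expect_equal(unname(coef(fit)), unname(rowSums(abs(fit$S))))
  expect_output(print(fit), "decomposition")
  expect_output(print(summary(fit, m = 3)), "candidate markers")
})
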