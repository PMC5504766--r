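#' Soft-thresholding (shrinkage) operator
#'
#' Applies the elementwise shrinkage operator
#' \eqn{S_\tau(x) = \mathrm{sign}(x)\,\max(|x| - \tau, 0)}, the proximal
#' operator of \eqn{\tau\|\cdot\|_1}.  For matrices it acts on each element.
#'
#' @param x A numeric vector or matrix.
#' @param tau Non-negative threshold.
#' @return An object of the same shape as `x`.
#' @examples
#' soft_threshold(3, 1)      # 2
#' soft_threshold(-0.5, 1)   # 0
#' @export
soft_threshold <- function(x, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("`tau` must be a single non-negative number", call. = FALSE)
  out <- sign(x) * pmax(abs(x) - tau, 0)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' First-order-difference seminorm
#'
#' Total variation of a vector along its index: the l1 norm of adjacent
#' differences, \eqn{\sum_{t=1}^{n-1} |x_{t+1} - x_t|}.  Used as the
#' smoothness measure for rows of the low-rank background; the difference
#' operator is never formed as a dense matrix.
#'
#' @param x Numeric vector, length at least 2.
#' @return A single non-negative number.
#' @examples
#' fod_seminorm(c(1, 2, 4))  # 3
#' @export
fod_seminorm <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("`x` must be a numeric vector of length >= 2", call. = FALSE)
  sum(abs(diff(x)))
}

#' Singular value thresholding
#'
#' Soft-thresholds the singular values of a matrix: with \eqn{X = U \Sigma
#' V^T}, returns \eqn{U\,\mathrm{diag}((\sigma_i - \tau)_+)\,V^T}.  This is
#' the proximal operator of \eqn{\tau\|\cdot\|_*} (nuclear norm), i.e. the
#' unique minimizer of \eqn{\frac12\|X - L\|_F^2 + \tau\|L\|_*}.
#'
#' @param x Numeric matrix with finite entries.
#' @param tau Non-negative threshold on the singular values.
#' @return A matrix of the same dimension as `x`.
#' @export
svt <- function(x, tau) {
  if (!is.matrix(x) || !all(is.finite(x)))
    stop("`x` must be a finite numeric matrix", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("`tau` must be a single non-negative number", call. = FALSE)
  if (tau == 0) return(x)
  # economy SVD: p >> n in the intended regime, so nu = nv = min(dim)
  sv <- svd(x, nu = min(dim(x)), nv = min(dim(x)))
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(x), ncol(x)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Exact 1-D total-variation denoising
#'
#' Computes the unique minimizer of
#' \eqn{\frac12\|v - y\|_2^2 + w \sum_t |y_{t+1} - y_t|}
#' by a direct taut-string-class algorithm (no iterative approximation).
#' This is the fused-lasso signal approximator with no sparsity term, and the
#' row subproblem of the ADMM smoothing step.
#'
#' @param v Numeric vector.
#' @param weight Non-negative regularization weight on the total variation.
#' @return Numeric vector of the same length as `v`.
#' @examples
#' tv_denoise_row(c(0, 1), 1)  # c(0.5, 0.5)
#' @export
tv_denoise_row <- function(v, weight) {
  if (!is.numeric(v) || length(v) < 1L || !all(is.finite(v)))
    stop("`v` must be a finite numeric vector", call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0)
    stop("`weight` must be a single non-negative number", call. = FALSE)
  .tv1d(as.numeric(v), weight)
}

#' Nuclear norm of a matrix
#' @param x Numeric matrix.
#' @return Sum of singular values.
#' @keywords internal
nuclear_norm <- function(x) sum(svd(x, nu = 0, nv = 0)$d)
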