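#' Control parameters for the decomposition
#'
#' Regularization weights and solver settings.  `alpha` weighs the nuclear
#' norm (rank surrogate) of the background, `lambda` the l1 sparsity of the
#' differential component, `beta` the row-wise total-variation smoothness of
#' the background, `rho` the ADMM penalty.  Defaults follow standard
#' low-rank/sparse practice: `alpha = 1`, `lambda = 1/sqrt(max(n, p))`
#' (filled in once the matrix is seen), `beta = 0.1 * alpha`, `rho = 1`.
#' Setting `beta = 0` removes the smoothness prior and reduces the model to
#' the convex robust-PCA relaxation.
#'
#' @param alpha Positive nuclear-norm weight.
#' @param lambda Positive sparsity weight, or `NULL` to use
#'   `alpha / sqrt(max(n, p))`.
#' @param beta Non-negative smoothness weight.
#' @param rho Positive ADMM penalty parameter.
#' @param outer_max_iter,outer_tol Outer alternating loop cap and relative
#'   Frobenius change tolerance.
#' @param admm_max_iter,admm_tol Inner ADMM cap and scaled primal-residual
#'   tolerance.
#' @return A list of class `reglrsd_control`.
#' @export
reglrsd_control <- function(alpha = 1, lambda = NULL, beta = 0.1 * alpha,
                            rho = 1, outer_max_iter = 200L,
                            outer_tol = 1e-6, admm_max_iter = 100L,
                            admm_tol = 1e-6) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  if (!is.null(lambda))
    stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0)
  stopifnot(outer_max_iter >= 1L, admm_max_iter >= 1L,
            outer_tol > 0, admm_tol > 0)
  structure(list(alpha = alpha, lambda = lambda, beta = beta, rho = rho,
                 outer_max_iter = as.integer(outer_max_iter),
                 outer_tol = outer_tol,
                 admm_max_iter = as.integer(admm_max_iter),
                 admm_tol = admm_tol),
            class = "reglrsd_control")
}

#' Closed-form sparse update
#'
#' Exact minimizer of \eqn{\frac12\|D - L - S\|_F^2 + \lambda\|S\|_1} in
#' `S`: elementwise soft-thresholding of the residual `D - L`.
#'
#' @param d,l Numeric matrices of equal dimension.
#' @param lambda Positive sparsity weight.
#' @return The updated sparse matrix.
#' @export
update_sparse <- function(d, l, lambda) {
  if (!is.matrix(d) || !is.matrix(l) || !identical(dim(d), dim(l)))
    stop("`d` and `l` must be matrices of identical dimension",
         call. = FALSE)
  soft_threshold(d - l, lambda)
}

#' Full decomposition objective
#'
#' \eqn{\frac12\|D - L - S\|_F^2 + \alpha\|L\|_* + \lambda\|S\|_1 +
#' \beta\sum_i \mathrm{TV}(l_i)} where \eqn{l_i} runs over rows of `L`.
#'
#' @param d,l,s Numeric matrices of identical dimension.
#' @param control A [reglrsd_control()] with `lambda` set.
#' @return A single non-negative number.
#' @export
reglrsd_objective <- function(d, l, s, control) {
  if (!is.matrix(d) || !identical(dim(d), dim(l)) ||
      !identical(dim(d), dim(s)))
    stop("`d`, `l`, `s` must be matrices of identical dimension",
         call. = FALSE)
  tv <- if (ncol(l) >= 2L) sum(abs(l[, -1, drop = FALSE] -
                                   l[, -ncol(l), drop = FALSE]))
        else 0
  0.5 * sum((d - l - s)^2) + control$alpha * nuclear_norm(l) +
    control$lambda * sum(abs(s)) + control$beta * tv
}

#' ADMM solver for the regularized low-rank subproblem
#'
#' Minimizes \eqn{\frac12\|D - S - L\|_F^2 + \alpha\|L\|_* +
#' \beta\sum_i \mathrm{TV}(l_i)} by splitting `L` from an auxiliary copy `Y`
#' carrying the smoothness penalty.  Each sweep performs (i) singular value
#' thresholding of \eqn{(D - S + \rho Y - Z)/(1+\rho)} at level
#' \eqn{\alpha/(1+\rho)}, (ii) exact row-wise TV denoising of
#' \eqn{(Z + \rho L)/\rho} at weight \eqn{\beta/\rho}, (iii) the dual ascent
#' \eqn{Z \leftarrow Z + \rho(L - Y)}.  Sweeps stop when both the scaled
#' primal residual \eqn{\|L - Y\|_F / \max(1, \|D\|_F)} and the scaled dual
#' residual \eqn{\rho\|Y - Y_{prev}\|_F / \max(1, \|D\|_F)} drop below
#' `admm_tol` (the primal residual alone is blind to progress when
#' \eqn{\beta = 0}, where the Y-step is the identity).  Returns `Y` as the
#' background estimate: it satisfies the smoothness penalty exactly, and
#' differs from `L` by at most the primal tolerance at convergence.
#'
#' @param d,s Data and (fixed) sparse matrices of equal dimension.
#' @param control A [reglrsd_control()].
#' @param warm Optional list with matrices `Y` and `Z` to warm-start the
#'   splitting variables (used by the outer loop).
#' @return A list: `L` (the smooth background, i.e. the converged `Y`),
#'   `L_raw` (the SVT iterate), `Z`, `primal_residual`, `iterations`.
#' @export
admm_low_rank <- function(d, s, control, warm = NULL) {
  if (!is.matrix(d) || !is.matrix(s) || !identical(dim(d), dim(s)))
    stop("`d` and `s` must be matrices of identical dimension",
         call. = FALSE)
  p <- nrow(d); n <- ncol(d)
  alpha <- control$alpha; beta <- control$beta; rho <- control$rho
  Y <- if (!is.null(warm)) warm$Y else matrix(0, p, n)
  Z <- if (!is.null(warm)) warm$Z else matrix(0, p, n)
  R <- d - s
  dnorm <- max(1, sqrt(sum(d^2)))
  L <- Y
  resid <- Inf
  it <- 0L
  while (it < control$admm_max_iter) {
    it <- it + 1L
    Y_prev <- Y
    L <- svt((R + rho * Y - Z) / (1 + rho), alpha / (1 + rho))
    Y <- .tv1d_rows((Z + rho * L) / rho, beta / rho)
    Z <- Z + rho * (L - Y)
    if (!all(is.finite(L)) || !all(is.finite(Y)))
      stop("ADMM produced non-finite values at inner iteration ", it,
           call. = FALSE)
    # primal (consensus) and dual (Y-step change) residuals must both be
    # small: the primal residual alone vanishes identically when beta = 0
    resid <- max(sqrt(sum((L - Y)^2)),
                 rho * sqrt(sum((Y - Y_prev)^2))) / dnorm
    if (resid <= control$admm_tol) break
  }
  list(L = Y, L_raw = L, Z = Z, primal_residual = resid, iterations = it)
}

#' Fit the regularized low-rank + sparse decomposition
#'
#' Decomposes an OTU-by-sample relative abundance matrix `D` into a smooth
#' low-rank background `L` (the non-differential community) plus a sparse
#' component `S` (candidate differentially abundant taxa) by minimizing the
#' convex objective of [reglrsd_objective()].  The solver alternates the
#' closed-form sparse update with the ADMM low-rank step, starting from
#' `L = S = 0`, and stops when the relative Frobenius change
#' \eqn{(\|\Delta L\|_F + \|\Delta S\|_F)/\max(1, \|D\|_F)} drops below
#' `outer_tol`.
#'
#' When the table carries phenotype labels and `reorder_by_class = TRUE`
#' (the default), sample columns are rearranged so that samples of the same
#' class are contiguous before the row-smoothness penalty is applied, and
#' the original order is restored in all outputs.  The smoothness prior is a
#' within-phenotype statement, so mixing classes along the sample axis would
#' penalize legitimate between-class differences.
#'
#' @param x An [abundance_table()] or a non-negative numeric matrix
#'   (rows = OTUs, columns = samples).
#' @param control A [reglrsd_control()]; individual `...` arguments override
#'   its fields (e.g. `reglrsd(x, beta = 0)`).
#' @param reorder_by_class Reorder columns into class blocks before the
#'   decomposition (only when labels are present).
#' @param renormalize Rescale each sample column to sum to one first
#'   (explicit opt-in; input tables are usually already per-sample
#'   normalized).
#' @param verbose Emit per-iteration progress messages.
#' @param ... Overrides for [reglrsd_control()] fields.
#' @return An object of class `reglrsd`: components `L`, `S` (matrices in
#'   the original column order), `objective` (trace of the objective after
#'   each outer iteration), `converged`, `iterations`, `lambda` (resolved
#'   value), `control`, `admm_gap` (final `\|L - Y\|_F` diagnostic),
#'   `otu_ids`, `sample_ids`, `labels`, `call`.
#' @examples
#' set.seed(1)
#' d <- synthetic_dataset(p = 40, n_per_class = c(8, 8), rank = 1,
#'                        marker_rows = 4, effect_size = 1, noise_sd = 0.05)
#' fit <- reglrsd(d$table)
#' head(sort(coef(fit), decreasing = TRUE))
#' @export
reglrsd <- function(x, control = reglrsd_control(), reorder_by_class = TRUE,
                    renormalize = FALSE, verbose = FALSE, ...) {
  cl <- match.call()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(formals(reglrsd_control)))
    if (length(bad)) stop("unknown control argument(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    control <- do.call(reglrsd_control,
                       utils::modifyList(unclass(control), dots))
  }
  tab <- if (inherits(x, "abundance_table")) x else abundance_table(x)
  if (renormalize) tab <- renormalize_columns(tab)
  d_full <- tab$values
  p <- nrow(d_full); n <- ncol(d_full)
  perm <- NULL
  if (reorder_by_class && !is.null(tab$labels)) {
    perm <- .class_block_order(tab)
    if (identical(perm, seq_len(n))) perm <- NULL
  }
  d <- if (is.null(perm)) d_full else d_full[, perm, drop = FALSE]
  if (is.null(control$lambda))
    control$lambda <- control$alpha / sqrt(max(n, p))

  L <- matrix(0, p, n); S <- matrix(0, p, n)
  warm <- list(Y = matrix(0, p, n), Z = matrix(0, p, n))
  dnorm <- max(1, sqrt(sum(d^2)))
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  gap <- NA_real_
  while (it < control$outer_max_iter) {
    it <- it + 1L
    S_new <- update_sparse(d, L, control$lambda)
    adm <- admm_low_rank(d, S_new, control, warm = warm)
    # descent safeguard: the S-step is an exact minimization, so the whole
    # sweep can only raise the objective through an under-solved ADMM step;
    # when that happens, resume the warm ADMM at tighter tolerance
    obj_prev <- if (it > 1L) trace[it - 1L] else Inf
    obj_new <- reglrsd_objective(d, adm$L, S_new, control)
    retry <- 0L
    ctrl_tight <- control
    while (obj_new - obj_prev > 1e-13 * max(1, abs(obj_prev)) &&
           retry < 6L) {
      retry <- retry + 1L
      ctrl_tight$admm_tol <- ctrl_tight$admm_tol / 100
      adm <- admm_low_rank(d, S_new, ctrl_tight,
                           warm = list(Y = adm$L, Z = adm$Z))
      obj_new <- reglrsd_objective(d, adm$L, S_new, control)
    }
    L_new <- adm$L
    warm <- list(Y = adm$L, Z = adm$Z)
    gap <- sqrt(sum((adm$L_raw - adm$L)^2))
    delta <- (sqrt(sum((L_new - L)^2)) + sqrt(sum((S_new - S)^2))) / dnorm
    L <- L_new; S <- S_new
    trace <- c(trace, obj_new)
    .log_msg("outer %3d: objective %.8g, rel change %.3g, admm iters %d",
             it, trace[it], delta, adm$iterations, verbose = verbose)
    if (delta <= control$outer_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("decomposition did not converge within ",
            control$outer_max_iter, " outer iterations", call. = FALSE)
  if (!is.null(perm)) {
    inv <- order(perm)
    L <- L[, inv, drop = FALSE]
    S <- S[, inv, drop = FALSE]
  }
  dimnames(L) <- dimnames(S) <- dimnames(d_full)
  structure(list(L = L, S = S, objective = trace, converged = converged,
                 iterations = it, lambda = control$lambda,
                 control = control, admm_gap = gap,
                 otu_ids = tab$otu_ids, sample_ids = tab$sample_ids,
                 labels = tab$labels, D = d_full, call = cl),
            class = "reglrsd")
}

#' @export
print.reglrsd <- function(x, ...) {
  cat("Regularized low-rank + sparse decomposition\n")
  cat(sprintf("  %d OTUs x %d samples\n", nrow(x$L), ncol(x$L)))
  cat(sprintf(
    "  alpha = %g, lambda = %g, beta = %g, rho = %g\n",
    x$control$alpha, x$lambda, x$control$beta, x$control$rho))
  cat(sprintf("  %sconverged in %d outer iterations, objective %.6g\n",
              if (x$converged) "" else "NOT ", x$iterations,
              utils::tail(x$objective, 1)))
  cat(sprintf("  nonzero sparse entries: %d (%.1f%% of cells)\n",
              sum(x$S != 0), 100 * mean(x$S != 0)))
  invisible(x)
}

#' @export
summary.reglrsd <- function(object, m = 10L, ...) {
  rk <- marker_ranking(object)
  structure(list(fit = object, ranking = rk,
                 m = min(m, length(rk$scores)),
                 rank_L = sum(svd(object$L, nu = 0, nv = 0)$d >
                                1e-8 * max(1, max(abs(object$L))))),
            class = "summary.reglrsd")
}

#' @export
print.summary.reglrsd <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  numerical rank of background: %d\n", x$rank_L))
  cat(sprintf("\nTop %d candidate markers:\n", x$m))
  ids <- top_markers(x$ranking, x$m)
  idx <- match(ids, x$ranking$otu_ids)
  print(data.frame(rank = seq_len(x$m), otu_id = ids,
                   score = x$ranking$scores[idx],
                   enrichment = x$ranking$enrichment_sign[idx]),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.reglrsd <- function(object, ...) {
  stats::setNames(rowSums(abs(object$S)), object$otu_ids)
}

#' @export
fitted.reglrsd <- function(object, ...) object$L + object$S

#' @export
residuals.reglrsd <- function(object, ...) object$D - object$L - object$S

#' Plot a fitted decomposition
#'
#' Two base-graphics panels: the objective trace across outer iterations and
#' the marker scores of the top OTUs.
#'
#' @param x A `reglrsd` fit.
#' @param m Number of top markers to display.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.reglrsd <- function(x, m = 20L, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$objective), x$objective, type = "b", pch = 20,
                 xlab = "outer iteration", ylab = "objective",
                 main = "Convergence")
  sc <- sort(coef(x), decreasing = TRUE)
  m <- min(m, length(sc))
  graphics::barplot(rev(sc[seq_len(m)]), horiz = TRUE, las = 1,
                    cex.names = 0.6, xlab = "score |S| row mass",
                    main = sprintf("Top %d markers", m), ...)
  invisible(x)
}
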