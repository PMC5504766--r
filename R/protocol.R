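#' Deterministic per-iteration seed derivation
#'
#' One master seed drives the whole protocol; iteration k draws its own
#' 32-bit seed from (master, k) so iterations are reproducible independently
#' of execution order.
#' @param master Integer master seed.
#' @param k Iteration number.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(master, k) {
  as.integer((abs(as.numeric(master)) %% 94007 * 22807 +
                as.numeric(k) * 7919) %% 2147483629)
}

#' Split a labeled table into train and test subsamples
#'
#' Draws `ceiling(r * n)` training columns without replacement; the
#' remainder form the test set.  When `stratified`, `ceiling(r * n_c)`
#' samples are drawn per class and the total is trimmed back to
#' `ceiling(r * n)` by moving samples of the larger class allocation to the
#' test set (chosen by the same RNG), so class ratios are approximately
#' preserved and no class empties at small n.
#'
#' @param table A labeled [abundance_table()].
#' @param r Train fraction in (0, 1).
#' @param seed Integer seed making the split reproducible.
#' @param stratified Preserve class proportions (default `TRUE`).
#' @return List with `train` and `test` abundance tables.
#' @export
subsample_split <- function(table, r, seed, stratified = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$labels)) stop("labels required", call. = FALSE)
  if (!is.numeric(r) || r <= 0 || r >= 1)
    stop("`r` must lie strictly between 0 and 1", call. = FALSE)
  n <- ncol(table$values)
  n_train <- ceiling(r * n)
  if (n_train >= n) n_train <- n - 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (stratified) {
    classes <- unique(table$labels)
    alloc <- lapply(classes, function(cl) {
      idx <- which(table$labels == cl)
      sample(idx, min(ceiling(r * length(idx)), length(idx) - 1L))
    })
    excess <- sum(lengths(alloc)) - n_train
    while (excess > 0) {
      big <- which.max(lengths(alloc))
      drop_i <- sample(seq_along(alloc[[big]]), 1L)
      alloc[[big]] <- alloc[[big]][-drop_i]
      excess <- excess - 1L
    }
    train_idx <- sort(unlist(alloc, use.names = FALSE))
  } else {
    train_idx <- sort(sample(n, n_train))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  out <- list(train = subset_samples(table, train_idx),
              test = subset_samples(table, test_idx))
  for (nm in names(out)) {
    gone <- setdiff(unique(table$labels), unique(out[[nm]]$labels))
    if (length(gone))
      stop("class '", gone[1], "' has no samples in the ", nm, " set",
           call. = FALSE)
  }
  out
}

#' Kuncheva index of two equal-size feature sets
#'
#' Chance-corrected overlap
#' \eqn{(|A \cap B| - s^2/p) / (s - s^2/p)} for sets of common size `s`
#' drawn from `p` features; ranges over \eqn{[-1, 1]}, with expectation 0
#' under independent uniform selection and 1 for identical sets.
#'
#' @param set_a,set_b Vectors (same type) of selected feature identifiers,
#'   equal length `s` with `0 < s < p`.
#' @param p Total number of features.
#' @return A number in \eqn{[-1, 1]}.
#' @examples
#' kuncheva_index(1:2, 3:4, 10)  # disjoint: -0.25
#' @export
kuncheva_index <- function(set_a, set_b, p) {
  s <- length(set_a)
  if (length(set_b) != s)
    stop("sets must have equal size", call. = FALSE)
  if (s == 0 || s >= p)
    stop("set size must satisfy 0 < s < p (index undefined otherwise)",
         call. = FALSE)
  ov <- length(intersect(set_a, set_b))
  (ov - s^2 / p) / (s - s^2 / p)
}

#' Mean pairwise Kuncheva index of K marker sets
#'
#' \eqn{C_{avg} = \frac{2}{K(K-1)} \sum_{i<j} KI(F_i, F_j)}; the stability
#' score of a selection procedure over K subsampling runs.
#'
#' @param sets List of K equal-size feature sets.
#' @param p Total number of features.
#' @return The average over all `K(K-1)/2` pairs.
#' @export
average_consistency <- function(sets, p) {
  k <- length(sets)
  if (k < 2L) stop("need at least two sets", call. = FALSE)
  ki <- pairwise_kuncheva(sets, p)
  mean(ki)
}

#' All pairwise Kuncheva indices
#' @inheritParams average_consistency
#' @return Numeric vector of length `K(K-1)/2` (pairs in (1,2), (1,3), ...
#'   column-major order).
#' @export
pairwise_kuncheva <- function(sets, p) {
  k <- length(sets)
  s <- unique(lengths(sets))
  if (length(s) != 1L) stop("sets must all have equal size", call. = FALSE)
  if (s == 0 || s >= p)
    stop("set size must satisfy 0 < s < p", call. = FALSE)
  univ <- unique(unlist(sets, use.names = FALSE))
  sel <- vapply(sets, function(f) univ %in% f, logical(length(univ)))
  sel <- matrix(sel, ncol = k)
  ov <- crossprod(sel * 1)          # k x k intersection sizes
  corr <- s^2 / p
  ki <- (ov - corr) / (s - corr)
  ki[upper.tri(ki)]
}

#' Build a decomposition-based marker detector
#'
#' Returns a detector closure for [run_protocol()]: given a labeled
#' training table it fits [reglrsd()] and returns the [marker_ranking()].
#'
#' @param control A [reglrsd_control()] for the per-subsample fits.
#' @param ... Passed on to [reglrsd()] (e.g. `beta = 0` for the plain
#'   robust-PCA variant, `reorder_by_class = FALSE`).
#' @return A function `function(table) -> marker_ranking`.
#' @export
reglrsd_detector <- function(control = reglrsd_control(), ...) {
  force(control)
  dots <- list(...)
  function(table) {
    fit <- do.call(reglrsd, c(list(x = table, control = control), dots))
    marker_ranking(fit)
  }
}

#' Run the subsampling stability / classification protocol
#'
#' Repeats K times: split the labeled table into train (fraction `r`,
#' without replacement) and test; run the detector on the training table
#' only; record its top-`m` marker set and ranking; fit nearest-centroid
#' classifiers on the training samples restricted to that marker set and
#' score them on the held-out samples.  Afterwards computes all
#' `K(K-1)/2` pairwise Kuncheva indices and their mean, the rank of each
#' full-data top-`m` marker within every subsample ranking, per-OTU
#' selection frequencies, and averaged accuracy / sensitivity /
#' specificity per classifier norm.
#'
#' @param table A labeled [abundance_table()].
#' @param detector Function mapping a training [abundance_table()] to a
#'   [marker_ranking()] (see [reglrsd_detector()]).
#' @param m Number of markers selected per run.
#' @param K Number of subsampling iterations (at least 2).
#' @param r Train fraction in (0, 1).
#' @param seed Master seed; iteration k uses a seed derived from (seed, k).
#' @param stratified Preserve class ratios in the splits.
#' @param norms Classifier norms to evaluate, subset of `c("l1", "l2")`.
#' @param positive_label Class treated as positive for sensitivity /
#'   specificity; defaults to the second class in label order with a
#'   message.
#' @param verbose Progress messages.
#' @return An object of class `reglrsd_protocol` with components
#'   `stability` (class `stability_report`: `ki_values`, `c_avg`,
#'   `rank_matrix`, `selection_frequency`, `reference_markers`) and
#'   `classification` (class `classification_report`: `per_iteration`
#'   confusion counts and `summary` averaged metrics), plus `m`, `K`, `r`,
#'   `seed`, `failures`.
#' @export
run_protocol <- function(table, detector, m, K = 500L, r = 0.8,
                         seed = 1L, stratified = TRUE,
                         norms = c("l1", "l2"), positive_label = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$labels)) stop("labels required", call. = FALSE)
  if (K < 2L) stop("`K` must be at least 2", call. = FALSE)
  if (!is.numeric(r) || r <= 0 || r >= 1)
    stop("`r` must lie strictly between 0 and 1", call. = FALSE)
  p <- nrow(table$values)
  if (m < 1 || m >= p)
    stop("`m` must satisfy 1 <= m < p", call. = FALSE)
  norms <- match.arg(norms, c("l1", "l2"), several.ok = TRUE)
  classes <- unique(table$labels)
  if (is.null(positive_label)) {
    positive_label <- classes[2]
    .log_msg("positive class defaulting to '%s'", positive_label,
             verbose = verbose)
  }
  if (!positive_label %in% classes)
    stop("`positive_label` not among table classes", call. = FALSE)

  # protocol-owned RNG discipline: ambient stream saved/restored, every
  # stage (including a stochastic detector) seeded from (seed, k)
  old_rng <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                        globalenv()))
  set.seed(derive_seed(seed, 0L))
  reference <- detector(table)
  ref_top <- top_markers(reference, m)

  sets <- vector("list", K)
  rank_matrix <- matrix(NA_integer_, K, m,
                        dimnames = list(NULL, ref_top))
  conf <- expand.grid(iteration = seq_len(K), norm = norms,
                      stringsAsFactors = FALSE)
  conf$TP <- conf$TN <- conf$FP <- conf$FN <- NA_integer_
  failures <- integer(0)

  for (k in seq_len(K)) {
    res <- tryCatch({
      split <- subsample_split(table, r, derive_seed(seed, k), stratified)
      set.seed(derive_seed(seed, k))
      rk <- detector(split$train)
      fk <- top_markers(rk, m)
      truth <- split$test$labels
      cc <- lapply(norms, function(nrm) {
        model <- fit_ncc(split$train, features = fk, norm = nrm)
        pred <- predict(model, split$test)
        c(TP = sum(pred == positive_label & truth == positive_label),
          TN = sum(pred != positive_label & truth != positive_label),
          FP = sum(pred == positive_label & truth != positive_label),
          FN = sum(pred != positive_label & truth == positive_label))
      })
      list(fk = fk, rk = rk, cc = cc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, k)
      if (length(failures) > max(1, 0.01 * K))
        stop("protocol aborted: more than 1% of iterations failed; last error: ",
             conditionMessage(res), call. = FALSE)
      next
    }
    sets[[k]] <- res$fk
    sub_top <- res$fk
    rank_matrix[k, ] <- match(ref_top, sub_top)
    for (j in seq_along(norms)) {
      row <- which(conf$iteration == k & conf$norm == norms[j])
      conf[row, c("TP", "TN", "FP", "FN")] <- as.list(res$cc[[j]])
    }
    .log_msg("iteration %d/%d done", k, K, verbose = verbose)
  }
  ok <- !vapply(sets, is.null, logical(1))
  sets_ok <- sets[ok]
  ki <- pairwise_kuncheva(sets_ok, p)
  selection_frequency <- tabulate(
    match(unlist(sets_ok), table$otu_ids), nbins = p) / length(sets_ok)
  names(selection_frequency) <- table$otu_ids

  conf <- conf[conf$iteration %in% which(ok), , drop = FALSE]
  summ <- do.call(rbind, lapply(norms, function(nrm) {
    rows <- conf[conf$norm == nrm, , drop = FALSE]
    mets <- t(apply(rows[, c("TP", "TN", "FP", "FN")], 1, function(x)
      classification_metrics(x[1], x[2], x[3], x[4])))
    data.frame(norm = nrm, m = m,
               accuracy = mean(mets[, "accuracy"], na.rm = TRUE),
               sensitivity = mean(mets[, "sensitivity"], na.rm = TRUE),
               specificity = mean(mets[, "specificity"], na.rm = TRUE))
  }))

  structure(list(
    stability = structure(list(ki_values = ki, c_avg = mean(ki),
                               rank_matrix = rank_matrix[ok, , drop = FALSE],
                               selection_frequency = selection_frequency,
                               reference_markers = ref_top),
                          class = "stability_report"),
    classification = structure(list(per_iteration = conf, summary = summ),
                               class = "classification_report"),
    m = m, K = K, r = r, seed = seed, positive_label = positive_label,
    failures = failures),
    class = "reglrsd_protocol")
}

#' @export
print.reglrsd_protocol <- function(x, ...) {
  cat(sprintf("Subsampling evaluation: K = %d, r = %g, m = %d markers\n",
              x$K, x$r, x$m))
  cat(sprintf("  pairwise comparisons: %d\n", length(x$stability$ki_values)))
  cat(sprintf("  stability C_avg: %.4f\n", x$stability$c_avg))
  cat("  classification (averaged over subsamples):\n")
  print(x$classification$summary, row.names = FALSE)
  if (length(x$failures))
    cat(sprintf("  failed iterations: %s\n",
                paste(x$failures, collapse = ", ")))
  invisible(x)
}

#' Write protocol reports as TSV files
#'
#' Emits `ki_values.tsv`, `rank_matrix.tsv` (long format: iteration,
#' otu_id, rank — NA rank means the marker left the subsample's top-m),
#' `selection_frequency.tsv` and `classification_summary.tsv` under
#' `dir`.  Each file begins with a `#` header comment documenting its
#' columns.
#'
#' @param protocol A [run_protocol()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_protocol_reports <- function(protocol, dir) {
  stopifnot(inherits(protocol, "reglrsd_protocol"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .tsv <- function(df, file, comment) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(paste0("# ", comment), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  st <- protocol$stability
  .tsv(data.frame(ki = st$ki_values), "ki_values.tsv",
       "ki: pairwise Kuncheva index over all subsample pairs")
  rm <- st$rank_matrix
  long <- data.frame(
    iteration = rep(seq_len(nrow(rm)), times = ncol(rm)),
    otu_id = rep(colnames(rm), each = nrow(rm)),
    rank = as.vector(rm))
  .tsv(long, "rank_matrix.tsv",
       "iteration, otu_id (full-data top-m marker), rank within that subsample's top-m (NA = not selected)")
  .tsv(data.frame(otu_id = names(st$selection_frequency),
                  frequency = st$selection_frequency),
       "selection_frequency.tsv",
       "frequency: fraction of subsamples selecting the OTU")
  .tsv(protocol$classification$summary, "classification_summary.tsv",
       "averaged NCC metrics per norm; positive class as configured")
  invisible(dir)
}
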