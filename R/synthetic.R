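#' Generate a synthetic abundance table with planted structure
#'
#' Emulates the additive model behind the decomposition: a non-negative
#' low-rank background whose rows vary smoothly across samples, plus a
#' sparse differential component confined to a few marker rows, plus dense
#' Gaussian noise, clipped at zero (abundances are non-negative while the
#' additive model is unconstrained).
#'
#' The background is `L0 = A %*% t(B)` with non-negative `A` (p x rank) and
#' each column of `B` (n x rank) smoothed by a centered moving average of
#' width `smoothness_span`, so the total variation of every background row
#' is small.  Each of the `marker_rows` planted rows of `S0` receives a
#' constant shift of magnitude `effect_size` on the columns of exactly one
#' class, with the sign (enrichment vs depletion) and the affected class
#' drawn per row — whole-OTU class effects, mirroring how differential taxa
#' shift between phenotypes.
#'
#' @param p Number of OTU rows.
#' @param n_per_class Two positive integers: samples per class.
#' @param rank Rank of the background (`<= min(p, n)`).
#' @param marker_rows Number of planted differential OTUs (`<= p`).
#' @param effect_size Magnitude of the class shift in marker rows.
#' @param noise_sd Standard deviation of the dense Gaussian noise.
#' @param smoothness_span Width of the moving average applied along the
#'   sample axis of the background (larger = smoother rows; `n` makes every
#'   background row constant).
#' @param normalize Renormalize each sample column to sum to one at the end.
#' @param seed Optional integer seed (uses and restores the global RNG
#'   state).
#' @param class_labels Two class names.
#' @return A list of class `synthetic_dataset`: `table` (a labeled
#'   [abundance_table()]), `true_L`, `true_S`, `true_markers` (row indices),
#'   `marker_sign` (per planted row, +1 enriched in class 2 / -1 depleted).
#' @export
synthetic_dataset <- function(p, n_per_class, rank = 2L, marker_rows = 10L,
                              effect_size = 1, noise_sd = 0.1,
                              smoothness_span = NULL, normalize = FALSE,
                              seed = NULL,
                              class_labels = c("control", "case")) {
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 1L))
  n <- sum(n_per_class)
  if (rank > min(p, n))
    stop("`rank` must not exceed min(p, n)", call. = FALSE)
  if (marker_rows > p)
    stop("`marker_rows` must not exceed `p`", call. = FALSE)
  if (effect_size < 0 || noise_sd < 0)
    stop("`effect_size` and `noise_sd` must be non-negative", call. = FALSE)
  if (is.null(smoothness_span)) smoothness_span <- max(2L, n %/% 2L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  # smooth non-negative low-rank background
  A <- matrix(runif(p * rank, 0.2, 1), p, rank)
  B <- matrix(runif(n * rank, 0.5, 1.5), n, rank)
  B <- apply(B, 2, .moving_average, span = smoothness_span)
  B <- matrix(B, n, rank)
  L0 <- A %*% t(B)

  # planted class-dependent shifts on whole marker rows
  S0 <- matrix(0, p, n)
  markers <- sort(sample(p, marker_rows))
  labels <- rep(class_labels, n_per_class)
  sign_row <- integer(0)
  if (marker_rows > 0) {
    sign_row <- sample(c(-1, 1), marker_rows, replace = TRUE)
    target_class <- sample(class_labels, marker_rows, replace = TRUE)
    for (i in seq_len(marker_rows)) {
      cols <- which(labels == target_class[i])
      if (sign_row[i] < 0) {
        # a taxon can only be depleted by as much as it is present: raise
        # the background of depleted markers so the planted shift survives
        # the non-negativity clip at its full nominal size
        floor_needed <- effect_size + 2 * noise_sd
        row_min <- min(L0[markers[i], ])
        if (row_min < floor_needed && row_min > 0)
          L0[markers[i], ] <- L0[markers[i], ] * (floor_needed / row_min)
      }
      S0[markers[i], cols] <- sign_row[i] * effect_size
    }
  }
  noise <- matrix(rnorm(p * n, sd = noise_sd), p, n)
  values <- pmax(L0 + S0 + noise, 0)
  tab <- abundance_table(values,
                         otu_ids = sprintf("OTU%03d", seq_len(p)),
                         sample_ids = sprintf("S%03d", seq_len(n)),
                         labels = stats::setNames(labels,
                                                  sprintf("S%03d",
                                                          seq_len(n))))
  if (normalize) tab <- renormalize_columns(tab)
  structure(list(table = tab, true_L = L0, true_S = S0,
                 true_markers = markers, marker_sign = sign_row),
            class = "synthetic_dataset")
}

# centered moving average with edge truncation; span >= n gives the
# overall-mean (constant) vector
.moving_average <- function(x, span) {
  n <- length(x)
  if (span >= n) return(rep(mean(x), n))
  half <- span %/% 2L
  vapply(seq_len(n), function(t) {
    mean(x[max(1L, t - half):min(n, t + half)])
  }, numeric(1))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d OTUs x %d samples, %d planted markers\n",
    nrow(x$true_L), ncol(x$true_L), length(x$true_markers)))
  invisible(x)
}

#' Precision and recall of a selected marker set
#'
#' Set-level recovery metrics against planted ground truth: precision
#' `|selected & truth| / |selected|` (NA for an empty selection), recall
#' `|selected & truth| / |truth|`.
#'
#' @param selected Selected identifiers or indices.
#' @param truth Non-empty ground-truth identifiers or indices (same type).
#' @return Named numeric vector `c(precision, recall)`.
#' @export
recovery_metrics <- function(selected, truth) {
  if (!length(truth)) stop("`truth` must be non-empty", call. = FALSE)
  hit <- length(intersect(selected, truth))
  c(precision = if (length(selected)) hit / length(selected) else NA_real_,
    recall = hit / length(truth))
}

#' Write a synthetic dataset to disk
#'
#' Emits the abundance table and label file in the formats the readers
#' accept, plus a ground-truth TSV (`row_index`, `otu_id`, `is_marker`,
#' `sign`).
#'
#' @param dataset A [synthetic_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(dataset$table, file.path(dir, "abundance.tsv"))
  write_labels(dataset$table$labels, file.path(dir, "labels.tsv"))
  p <- nrow(dataset$true_L)
  is_marker <- seq_len(p) %in% dataset$true_markers
  sgn <- integer(p)
  sgn[dataset$true_markers] <- dataset$marker_sign
  utils::write.table(
    data.frame(row_index = seq_len(p),
               otu_id = dataset$table$otu_ids,
               is_marker = as.integer(is_marker), sign = sgn),
    file.path(dir, "ground_truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
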