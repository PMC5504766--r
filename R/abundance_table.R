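#' Construct an abundance table
#'
#' Container for an OTU-by-sample relative abundance matrix: non-negative
#' values, unique OTU and sample identifiers, and optionally a binary
#' phenotype label per sample (required by the evaluation protocol, not by
#' the decomposition itself).
#'
#' @param values Non-negative numeric matrix, rows = OTUs, columns = samples.
#' @param otu_ids Character vector of unique row identifiers (defaults to
#'   rownames).
#' @param sample_ids Character vector of unique column identifiers (defaults
#'   to colnames).
#' @param labels Optional named character vector or factor mapping every
#'   sample id to one of exactly two class labels.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, otu_ids = rownames(values),
                            sample_ids = colnames(values), labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  p <- nrow(values); n <- ncol(values)
  if (p < 1L || n < 2L)
    stop("abundance table needs >= 1 OTU row and >= 2 sample columns",
         call. = FALSE)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  otu_ids <- as.character(otu_ids); sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != p || anyDuplicated(otu_ids))
    stop("`otu_ids` must be ", p, " unique strings", call. = FALSE)
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop("`sample_ids` must be ", n, " unique strings", call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "abundance values must be finite and non-negative; first offender at OTU '%s', sample '%s'",
      otu_ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  }
  dimnames(values) <- list(otu_ids, sample_ids)
  if (!is.null(labels)) labels <- .check_labels(labels, sample_ids)
  structure(list(values = values, otu_ids = otu_ids,
                 sample_ids = sample_ids, labels = labels),
            class = "abundance_table")
}

.check_labels <- function(labels, sample_ids) {
  labels <- vapply(labels, as.character, character(1))
  if (is.null(names(labels)))
    stop("`labels` must be named by sample id", call. = FALSE)
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("unlabeled samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  labels <- labels[sample_ids]
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("exactly two class labels required, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  labels
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d OTUs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("Labels: ", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table by sample columns
#' @param table An `abundance_table`.
#' @param samples Character vector of sample ids (or integer indices).
#' @return An `abundance_table` restricted to those samples (order kept as
#'   given).
#' @keywords internal
subset_samples <- function(table, samples) {
  stopifnot(inherits(table, "abundance_table"))
  idx <- if (is.character(samples)) match(samples, table$sample_ids)
         else as.integer(samples)
  if (anyNA(idx)) stop("unknown sample id", call. = FALSE)
  abundance_table(table$values[, idx, drop = FALSE],
                  otu_ids = table$otu_ids,
                  sample_ids = table$sample_ids[idx],
                  labels = if (is.null(table$labels)) NULL
                           else table$labels[idx])
}

#' Rescale each sample column to sum to one
#'
#' Explicit per-sample renormalization (never applied silently).  All-zero
#' columns are left untouched.
#'
#' @param table An `abundance_table`.
#' @return A renormalized `abundance_table`.
#' @export
renormalize_columns <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  cs <- colSums(table$values)
  scale <- ifelse(cs > 0, 1 / cs, 1)
  table$values <- sweep(table$values, 2, scale, `*`)
  table
}

# Column order putting samples of the same class contiguously: class blocks
# in first-appearance order, samples in input order within blocks.  Returns
# an index permutation, or NULL when there are no labels.
.class_block_order <- function(table) {
  if (is.null(table$labels)) return(NULL)
  classes <- unique(table$labels)
  unlist(lapply(classes, function(cl) which(table$labels == cl)),
         use.names = FALSE)
}
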