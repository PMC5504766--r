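#' Score OTUs from the sparse component
#'
#' The score of OTU i is the absolute row mass of the sparse component,
#' \eqn{v_i = \sum_j |s_{ij}|}.  Only magnitudes matter: entries of `S` may
#' be positive (enriched) or negative (depleted) depending on the role the
#' taxon plays, so `S` and `-S` score identically.
#'
#' @param s Numeric matrix (the sparse component, rows = OTUs).
#' @return Non-negative numeric vector of length `nrow(s)`.
#' @export
score_markers <- function(s) {
  if (!is.matrix(s) || !is.numeric(s) || !length(s))
    stop("`s` must be a non-empty numeric matrix", call. = FALSE)
  if (!all(is.finite(s))) stop("`s` must be finite", call. = FALSE)
  rowSums(abs(s))
}

#' Rank OTUs as candidate biomarkers
#'
#' Builds the ranked marker list from a fitted decomposition (or a raw
#' sparse matrix): scores, a descending score ordering with deterministic
#' tie-break (ascending original row index), and an enrichment direction
#' per OTU for reporting which phenotype a marker is elevated in.
#'
#' When the fit carries phenotype labels, the direction is the sign of the
#' between-class difference of the sparse row means (`+1` = elevated in the
#' second class in label order).  The plain sign of the row mean — used as
#' the fallback when no labels are available — is unreliable in practice:
#' nuclear-norm and TV shrinkage make the background underestimate the
#' data, so the sparse component inherits a common non-negative offset
#' that swamps the class contrast in the overall mean.
#'
#' @param x A `reglrsd` fit or a numeric matrix interpreted as `S`.
#' @param otu_ids Row identifiers (taken from the fit when available).
#' @return An object of class `marker_ranking` with fields `scores`,
#'   `order`, `enrichment_sign`, `otu_ids`.
#' @export
marker_ranking <- function(x, otu_ids = NULL) {
  s <- if (inherits(x, "reglrsd")) x$S else x
  if (is.null(otu_ids))
    otu_ids <- if (inherits(x, "reglrsd")) x$otu_ids
               else if (!is.null(rownames(s))) rownames(s)
               else paste0("OTU", seq_len(nrow(s)))
  scores <- score_markers(s)
  ord <- order(-scores, seq_along(scores))
  labels <- if (inherits(x, "reglrsd")) x$labels else NULL
  enrich <- if (!is.null(labels)) {
    classes <- unique(labels)
    sign(rowMeans(s[, labels == classes[2], drop = FALSE]) -
           rowMeans(s[, labels == classes[1], drop = FALSE]))
  } else {
    sign(rowMeans(s))
  }
  structure(list(scores = scores, order = ord,
                 enrichment_sign = enrich,
                 otu_ids = as.character(otu_ids)),
            class = "marker_ranking")
}

#' @export
print.marker_ranking <- function(x, m = 10L, ...) {
  cat(sprintf("Marker ranking over %d OTUs\n", length(x$scores)))
  m <- min(m, length(x$scores))
  idx <- x$order[seq_len(m)]
  print(data.frame(rank = seq_len(m), otu_id = x$otu_ids[idx],
                   score = x$scores[idx],
                   enrichment = x$enrichment_sign[idx]),
        row.names = FALSE)
  invisible(x)
}

#' Select the top-m ranked markers
#'
#' @param ranking A [marker_ranking()].
#' @param m Number of markers, `1 <= m <= p`.
#' @return Character vector of `m` OTU identifiers in rank order.
#' @export
top_markers <- function(ranking, m) {
  stopifnot(inherits(ranking, "marker_ranking"))
  p <- length(ranking$scores)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m > p)
    stop("`m` must be an integer in [1, ", p, "]", call. = FALSE)
  ranking$otu_ids[ranking$order[seq_len(as.integer(m))]]
}

#' Write a ranked marker list as TSV
#'
#' Columns: `rank`, `otu_id`, `score`, `enrichment_sign`.
#'
#' @param ranking A [marker_ranking()].
#' @param path Output path.
#' @param m Number of markers to write (default: all).
#' @return `path`, invisibly.
#' @export
write_marker_list <- function(ranking, path, m = length(ranking$scores)) {
  stopifnot(inherits(ranking, "marker_ranking"))
  idx <- ranking$order[seq_len(min(m, length(ranking$scores)))]
  utils::write.table(
    data.frame(rank = seq_along(idx),
               otu_id = ranking$otu_ids[idx],
               score = ranking$scores[idx],
               enrichment_sign = ranking$enrichment_sign[idx]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
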