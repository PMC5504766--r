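#' Fit a nearest-centroid classifier
#'
#' Computes the per-class mean profile (centroid) over the supplied feature
#' rows.  Prediction assigns a sample to the class with the nearest centroid
#' under the chosen norm: `"l1"` (NCC-1) or `"l2"` (NCC-2).  Ties in
#' distance go to the first class in label order.
#'
#' @param train An [abundance_table()] with labels (typically already
#'   restricted to the selected marker rows).
#' @param features Optional character vector of OTU ids to restrict to.
#' @param norm `"l1"` or `"l2"`.
#' @return An object of class `ncc` with `centroids` (features x 2 matrix),
#'   `classes`, `norm`, `features`.
#' @export
fit_ncc <- function(train, features = NULL, norm = c("l1", "l2")) {
  stopifnot(inherits(train, "abundance_table"))
  norm <- match.arg(norm)
  if (is.null(train$labels))
    stop("training table must carry class labels", call. = FALSE)
  v <- train$values
  if (!is.null(features)) {
    idx <- match(features, train$otu_ids)
    if (anyNA(idx)) stop("unknown feature id", call. = FALSE)
    v <- v[idx, , drop = FALSE]
  }
  classes <- unique(train$labels)
  cents <- vapply(classes, function(cl) {
    cols <- train$labels == cl
    if (!any(cols)) stop("class '", cl, "' has no training samples",
                         call. = FALSE)
    rowMeans(v[, cols, drop = FALSE])
  }, numeric(nrow(v)))
  cents <- matrix(cents, nrow = nrow(v), dimnames = list(rownames(v),
                                                         classes))
  structure(list(centroids = cents, classes = classes, norm = norm,
                 features = rownames(v)),
            class = "ncc")
}

#' @export
print.ncc <- function(x, ...) {
  cat(sprintf("Nearest-centroid classifier (%s norm), %d features, classes: %s\n",
              x$norm, nrow(x$centroids), paste(x$classes, collapse = " / ")))
  invisible(x)
}

#' Predict classes with a nearest-centroid model
#'
#' @param object A fitted [fit_ncc()] model.
#' @param newdata Numeric matrix (features x samples), a numeric vector for
#'   a single sample, or an [abundance_table()] (restricted to the model's
#'   features by id when possible).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.ncc <- function(object, newdata, ...) {
  if (inherits(newdata, "abundance_table")) {
    idx <- match(object$features, newdata$otu_ids)
    if (anyNA(idx)) stop("test table lacks model features", call. = FALSE)
    newdata <- newdata$values[idx, , drop = FALSE]
  }
  if (is.vector(newdata)) newdata <- matrix(newdata, ncol = 1)
  if (nrow(newdata) != nrow(object$centroids))
    stop("feature dimension mismatch: model has ", nrow(object$centroids),
         ", data has ", nrow(newdata), call. = FALSE)
  apply(newdata, 2, function(z) {
    d <- apply(object$centroids, 2, function(mu) {
      if (object$norm == "l1") sum(abs(z - mu)) else sqrt(sum((z - mu)^2))
    })
    object$classes[which.min(d)]  # which.min: first class wins ties
  })
}

#' Confusion-count classification metrics
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`.  An empty positive (or negative) class makes sensitivity
#' (specificity) `NA` rather than an error.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp)[1]; tn <- as.numeric(tn)[1]
  fp <- as.numeric(fp)[1]; fn <- as.numeric(fn)[1]
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || sum(counts) < 1)
    stop("counts must be non-negative and sum to >= 1", call. = FALSE)
  c(accuracy = (tp + tn) / (tp + fn + tn + fp),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
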