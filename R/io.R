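#' Read an OTU abundance table from delimited text
#'
#' Expects a header row of sample identifiers and a first column of OTU
#' identifiers; remaining cells must be non-negative numbers.  Negative,
#' missing or non-numeric cells are reported with their OTU/sample
#' coordinates.  The `biom` format (JSON variant) is read through the
#' \pkg{biomformat} package when installed.
#'
#' @param path Path to the file.
#' @param format One of `"tsv"` (default), `"csv"`, `"biom"`.
#' @param labels Optional path to a label file (see [read_labels()]) whose
#'   labels are attached to the returned table.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, format = c("tsv", "csv", "biom"),
                                 labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package",
           call. = FALSE)
    b <- biomformat::read_biom(path)
    values <- as.matrix(biomformat::biom_data(b))
    df <- data.frame(id = rownames(values), values, check.names = FALSE)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.delim(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 3L)
      stop("expected an OTU id column plus >= 2 sample columns in ", path,
           call. = FALSE)
  }
  otu_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifier: ",
         otu_ids[duplicated(otu_ids)][1], call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier: ",
         sample_ids[duplicated(sample_ids)][1], call. = FALSE)
  raw <- as.matrix(df[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "cell (OTU '%s', sample '%s') is missing, non-numeric or negative",
      otu_ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  }
  lab <- if (!is.null(labels)) read_labels(labels) else NULL
  abundance_table(values, otu_ids = otu_ids, sample_ids = sample_ids,
                  labels = lab)
}

#' Write an abundance table as delimited text
#' @param table An [abundance_table()].
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, format = c("tsv", "csv")) {
  stopifnot(inherits(table, "abundance_table"))
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(otu_id = table$otu_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample label file
#'
#' TSV with columns `sample_id` and `label` (header optional but
#' recommended); exactly two distinct labels are required.
#'
#' @param path Path to the label file.
#' @return A named character vector, names = sample ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("label file must have two columns (sample_id, label)",
         call. = FALSE)
  ids <- df[[1]]; lab <- df[[2]]
  if (anyDuplicated(ids))
    stop("duplicate sample id in label file: ", ids[duplicated(ids)][1],
         call. = FALSE)
  if (length(unique(lab)) != 2L)
    stop("label file must contain exactly two distinct class labels",
         call. = FALSE)
  stats::setNames(lab, ids)
}

#' Write a sample label file
#' @param labels Named character vector (names = sample ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored.  Values are converted to numeric or
#' logical where possible.
#'
#' @param path Path to the file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: ", ln, call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
      else val
  }
  out
}
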