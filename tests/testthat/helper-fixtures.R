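# Small in-code fixtures shared across test files.

# labeled toy table with mild class structure; deterministic given seed
toy_table <- function(p = 12, n_per_class = c(5, 5), seed = 101,
                      shift_rows = 2, shift = 0.8) {
  set.seed(seed)
  n <- sum(n_per_class)
  values <- matrix(abs(rnorm(p * n, mean = 1, sd = 0.2)), p, n)
  labels <- rep(c("healthy", "disease"), n_per_class)
  if (shift_rows > 0)
    values[seq_len(shift_rows), labels == "disease"] <-
      values[seq_len(shift_rows), labels == "disease"] + shift
  sample_ids <- sprintf("samp%02d", seq_len(n))
  abundance_table(values,
                  otu_ids = sprintf("otu%02d", seq_len(p)),
                  sample_ids = sample_ids,
                  labels = setNames(labels, sample_ids))
}

# detector returning a fixed marker set (rows 1..p ranked by index)
constant_detector <- function(table) {
  p <- nrow(table$values)
  s <- matrix(0, p, ncol(table$values))
  s[, 1] <- rev(seq_len(p))   # scores p, p-1, ..., 1
  marker_ranking(s, otu_ids = table$otu_ids)
}

# detector selecting uniformly at random (reads the current RNG stream)
random_detector <- function(table) {
  p <- nrow(table$values)
  s <- matrix(0, p, ncol(table$values))
  s[, 1] <- runif(p)
  marker_ranking(s, otu_ids = table$otu_ids)
}
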