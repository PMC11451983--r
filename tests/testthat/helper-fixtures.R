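# Shared fixtures, built in code at test time.

write_toy_gct <- function(values, path = tempfile(fileext = ".gct"),
                          descr = NULL) {
  descr <- descr %||% rep(".", nrow(values))
  lines <- c("#1.2", paste(nrow(values), ncol(values), sep = "\t"),
             paste(c("Name", "Description", colnames(values)), collapse = "\t"),
             vapply(seq_len(nrow(values)), function(i)
               paste(c(rownames(values)[i], descr[i], values[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_matrix <- function(n_genes = 2, n_samples = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(round(abs(rnorm(n_genes * n_samples, 5, 2)), 3),
              n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S-%03d-01", seq_len(n_samples))))
  m
}

# one mid-sized cohort with all planted scenarios, shared across test files
scenario_pairs <- function() {
  rbind(planted_pair(1, 2, "SYS_ONLY"),
        planted_pair(3, 4, "SYS_ONLY"),
        planted_pair(5, 6, "TISSUE_ONLY"),
        planted_pair(7, 8, "TISSUE_ONLY"),
        planted_pair(9, 10, "XOR"),
        planted_pair(11, 12, "NONLINEAR"),
        planted_pair(13, 14, "TISSUE_EXCEPTION"),
        planted_pair(15, 16, "NULL_PAIR"))
}

shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cc <- cohort_config(n_tissues = 12, samples_per_tissue = 75,
                          n_genes = 120, planted_pairs = scenario_pairs(),
                          seed = 42)
      cache <<- generate_cohort(cc)
    }
    cache
  }
})

# quantile normalization reference oracle: column-sorted values replaced by
# the row means of the sorted matrix; ties get the mean of the reference
# values they span
qn_oracle <- function(m) {
  ranks <- apply(m, 2, rank, ties.method = "average")
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- ranks[, j]
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    out[, j] <- (lo + hi) / 2
  }
  out
}

# direct G-statistic oracle from two code vectors, optionally floored
g_oracle <- function(a, b, floored = TRUE) {
  keep <- !is.na(a) & !is.na(b)
  O <- as.matrix(table(factor(a[keep], 1:3), factor(b[keep], 1:3)))
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  if (floored) E <- pmax(E, ifelse(O > 4, 1, 0.5))
  2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
}
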