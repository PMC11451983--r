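#' Coexpression result container
#'
#' A symmetric gene-by-gene association matrix tagged by the metric that
#' produced it (`pearson`, `spearman`, `g`), the modality it was computed in
#' (`tpm` = system level on log10(TPM+1); `zscore` = tissue level on
#' within-cluster z-scores), its aggregation (`per_rep` for a single
#' subsample replicate, `min` for the pessimistic minimum over replicates),
#' and the covariate stratum (`ALL` unless stratified).
#'
#' @param values symmetric numeric matrix with identical row/column gene ids.
#' @param metric,modality,aggregation,stratum tags, see above.
#' @param rep replicate index for `per_rep` results.
#' @param flags named list of diagnostic matrices/vectors (e.g. constant
#'   genes, sign disagreements).
#' @return object of class `coex_result`.
#' @export
coex_result <- function(values, metric = c("pearson", "spearman", "g"),
                        modality = c("tpm", "zscore"),
                        aggregation = c("per_rep", "min"),
                        stratum = "ALL", rep = NA_integer_, flags = list()) {
  metric <- match.arg(metric)
  modality <- match.arg(modality)
  aggregation <- match.arg(aggregation)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            identical(rownames(values), colnames(values)))
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("coexpression matrix must be symmetric", call. = FALSE)
  if (metric != "g") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1 - 1e-8 || rng[2] > 1 + 1e-8)
      stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(values = values, metric = metric, modality = modality,
                 aggregation = aggregation, stratum = stratum,
                 rep = rep, flags = flags),
            class = "coex_result")
}

#' @export
print.coex_result <- function(x, ...) {
  cat(sprintf("<coex_result> %s / %s / %s%s, %d genes, stratum %s\n",
              x$metric, x$modality, x$aggregation,
              if (!is.na(x$rep)) paste0(" rep ", x$rep) else "",
              nrow(x$values), x$stratum))
  invisible(x)
}

#' Persist / load a coexpression result
#'
#' A result is stored as a documented pair: `<name>.genes.txt` (one gene id
#' per line, the row/column order of the matrix), `<name>.mat.bin` (dense
#' row-major doubles), and `<name>.meta.json` (tags and dimensions). Full
#' matrices at production scale are impractical as TSV; for readable exports
#' use [export_coex_long()].
#'
#' @param result a [coex_result()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return (invisibly) the paths written.
#' @export
write_coex_result <- function(result, dir, name) {
  stopifnot(inherits(result, "coex_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_genes <- file.path(dir, paste0(name, ".genes.txt"))
  p_mat <- file.path(dir, paste0(name, ".mat.bin"))
  p_meta <- file.path(dir, paste0(name, ".meta.json"))
  writeLines(rownames(result$values), p_genes)
  con <- file(p_mat, "wb")
  writeBin(as.vector(t(result$values)), con, size = 8)
  close(con)
  jsonlite::write_json(
    list(metric = result$metric, modality = result$modality,
         aggregation = result$aggregation, stratum = result$stratum,
         rep = result$rep, n_genes = nrow(result$values)),
    p_meta, auto_unbox = TRUE, null = "null")
  invisible(c(genes = p_genes, matrix = p_mat, meta = p_meta))
}

#' @rdname write_coex_result
#' @export
read_coex_result <- function(dir, name) {
  genes <- readLines(file.path(dir, paste0(name, ".genes.txt")))
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".meta.json")))
  n <- length(genes)
  if (!identical(as.integer(meta$n_genes), n))
    stop_format(file.path(dir, name), "gene index length %d != declared %d", n, meta$n_genes)
  con <- file(file.path(dir, paste0(name, ".mat.bin")), "rb")
  v <- readBin(con, "double", n = n * n, size = 8)
  close(con)
  m <- matrix(v, n, n, byrow = TRUE, dimnames = list(genes, genes))
  coex_result(m, meta$metric, meta$modality, meta$aggregation,
              stratum = meta$stratum, rep = meta$rep %||% NA_integer_)
}

#' Export a coexpression result as a long-format TSV
#'
#' @param result a [coex_result()].
#' @param path output TSV (`gene_a`, `gene_b`, `metric`, `modality`, `value`),
#'   one row per unordered pair.
#' @param pairs optional 2-column matrix/data.frame of gene id pairs to
#'   restrict the export.
#' @export
export_coex_long <- function(result, path, pairs = NULL) {
  v <- result$values
  if (is.null(pairs)) {
    idx <- which(upper.tri(v), arr.ind = TRUE)
    df <- data.frame(gene_a = rownames(v)[idx[, 1]], gene_b = colnames(v)[idx[, 2]],
                     metric = result$metric, modality = result$modality,
                     value = v[idx])
  } else {
    pairs <- as.matrix(pairs)
    df <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                     metric = result$metric, modality = result$modality,
                     value = v[pairs])
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
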