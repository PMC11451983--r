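#' Read a GCT v1.2 expression file
#'
#' Parses the GCT dialect distributed with GTEx TPM matrices: a `#1.2`
#' version line, a dimensions line (`n_genes<TAB>n_samples`), a header row
#' `Name<TAB>Description<TAB><sample ids...>`, then one row per gene. The
#' Description column is kept as gene annotation but plays no further role.
#' Ensembl version suffixes (e.g. `ENSG00000141510.16`) are stripped by
#' default so that gene ids join cleanly with gene-set and edge-list files.
#'
#' @param path path to an uncompressed or gzipped GCT file.
#' @param strip_versions drop a trailing `.N` version from gene ids.
#' @return an [expr_matrix()] with scale `"TPM"`.
#' @export
read_gct <- function(path, strip_versions = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3) stop_format(path, "fewer than 3 lines")
  if (!identical(trimws(lines[1]), "#1.2"))
    stop_format(path, "first line must be the GCT version token '#1.2', got '%s'", lines[1])
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    stop_format(path, "second line must give '<n_genes>\\t<n_samples>'")
  n_genes <- as.integer(dims[1]); n_samples <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_samples + 2)
    stop_format(path, "header has %d sample columns but dims line declares %d",
                length(header) - 2, n_samples)
  samples <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != n_genes)
    stop_format(path, "dims line declares %d genes but %d data rows found",
                n_genes, length(body))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != n_samples + 2)) {
    bad <- which(nf != n_samples + 2)[1]
    stop_format(path, "data row %d has %d fields, expected %d", bad, nf[bad], n_samples + 2)
  }
  genes <- vapply(fields, `[[`, character(1), 1L)
  descr <- vapply(fields, `[[`, character(1), 2L)
  if (strip_versions) genes <- sub("\\.[0-9]+$", "", genes)
  if (anyDuplicated(genes))
    stop_format(path, "duplicated gene id '%s'", genes[duplicated(genes)][1])
  vals <- matrix(NA_real_, n_genes, n_samples, dimnames = list(genes, samples))
  for (i in seq_len(n_genes)) {
    v <- suppressWarnings(as.numeric(fields[[i]][-(1:2)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop_format(path, "non-numeric cell '%s' at gene row %d (%s), sample column %d (%s)",
                  fields[[i]][j + 2], i, genes[i], j, samples[j])
    }
    vals[i, ] <- v
  }
  expr_matrix(vals, "TPM", description = descr)
}

#' Write a GCT v1.2 file
#'
#' Inverse of [read_gct()]; round-trips values at full double precision.
#'
#' @param expr an [expr_matrix()].
#' @param path output path.
#' @export
write_gct <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  descr <- expr$description %||% rep(".", nrow(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t"),
               paste(c("Name", "Description", colnames(v)), collapse = "\t")), con)
  body <- cbind(rownames(v), descr,
                matrix(sprintf("%.17g", v), nrow(v), ncol(v)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
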