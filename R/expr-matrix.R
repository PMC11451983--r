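#' Construct an expression matrix
#'
#' A thin validated container for a dense genes-by-samples expression matrix
#' with a declared scale. The scale records where the values sit in the
#' processing chain: raw `TPM`, normalized `LOG10P1` (log10(TPM + 1), quantile
#' normalized and batch corrected), or `ZSCORE` (standardized within tissue
#' clusters).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param scale one of `"TPM"`, `"LOG10P1"`, `"ZSCORE"`.
#' @param description optional per-gene annotation (e.g. the GCT Description
#'   column), recycled against the genes.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("TPM", "LOG10P1", "ZSCORE"),
                        description = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene (row) and sample (column) names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene id: ",
         rownames(values)[duplicated(rownames(values))][1], call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample id: ",
         colnames(values)[duplicated(colnames(values))][1], call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  if (scale == "TPM" && any(values < 0))
    stop("TPM values must be non-negative", call. = FALSE)
  structure(
    list(values = values, scale = scale,
         description = if (!is.null(description)) rep_len(description, nrow(values))),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

# subset helper keeping class/scale; i = genes, j = samples
subset_expr <- function(x, i = NULL, j = NULL) {
  v <- x$values
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  d <- x$description
  if (!is.null(d) && !is.null(i)) d <- d[if (is.character(i)) match(i, gene_ids(x)) else i]
  expr_matrix(v, x$scale, d)
}

check_scale <- function(x, expected) {
  if (!inherits(x, "expr_matrix"))
    stop("expected an `expr_matrix`", call. = FALSE)
  if (!x$scale %in% expected)
    stop(sprintf("expression scale is %s; expected %s", x$scale,
                 paste(expected, collapse = " or ")), call. = FALSE)
  invisible(x)
}
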