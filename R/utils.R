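`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a root seed
#'
#' All randomised steps in the package draw their seeds from a single root
#' seed through this function, so that an entire run is reproducible from one
#' integer while distinct steps (subsample replicates, permutations,
#' embeddings) use distinct, non-overlapping streams.
#'
#' @param seed root integer seed.
#' @param offset non-negative integer identifying the stream.
#' @return an integer seed strictly below 2^31.
#' @export
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483629)
}

#' Number of unordered gene pairs
#'
#' @param n_genes number of genes.
#' @return `n_genes * (n_genes - 1) / 2`, the number of entries in one
#'   triangle of a coexpression matrix.
#' @examples
#' count_gene_pairs(4) # 6
#' @export
count_gene_pairs <- function(n_genes) {
  stopifnot(n_genes >= 0)
  n_genes * (n_genes - 1) / 2
}

#' Size of a top/bottom fraction of a ranking
#'
#' @param n number of ranked items.
#' @param frac fraction in (0, 1]; defaults to the 5% used for enrichment
#'   gene sets.
#' @return `floor(frac * n)`.
#' @export
top_fraction_size <- function(n, frac = 0.05) {
  stopifnot(frac > 0, frac <= 1)
  floor(frac * n)
}

# canonical unordered pair key, used to join coexpression values with
# external edge lists
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

stop_format <- function(path, msg, ...) {
  stop(sprintf("format error in '%s': %s", path, sprintf(msg, ...)), call. = FALSE)
}
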