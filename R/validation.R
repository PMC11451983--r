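#' Rank all genes by coexpression with an anchor gene
#'
#' Orders the anchor's partners by absolute coexpression, strongest first;
#' the "bottom" of this ranking holds the genes closest to zero
#' coexpression. The anchor is excluded from its own ranking and ties are
#' broken by gene id for determinism.
#'
#' @param result a [coex_result()] or symmetric named matrix.
#' @param anchor anchor gene id.
#' @return object of class `gene_ranking`: `anchor`, `genes` (ordered),
#'   `values` (raw signed values in that order).
#' @export
gene_ranking <- function(result, anchor) {
  v <- if (inherits(result, "coex_result")) result$values else result
  if (!anchor %in% rownames(v)) stop("anchor gene not in matrix", call. = FALSE)
  row <- v[anchor, setdiff(colnames(v), anchor)]
  ord <- order(-abs(row), names(row))
  structure(list(anchor = anchor, genes = names(row)[ord],
                 values = unname(row[ord])), class = "gene_ranking")
}

#' Count enriched pathways for a top or bottom coexpression set
#'
#' The gene universe is the intersection of the ranked genes and the
#' collection's genes. The query set is the top (or bottom) `frac` of the
#' ranking by absolute coexpression, restricted to the universe. Each
#' pathway is tested for over-representation with the one-sided
#' hypergeometric tail `P(X >= observed overlap)`; the function returns how
#' many pathways fall below `alpha`.
#'
#' @param ranking a [gene_ranking()].
#' @param pathways a `gene_set_collection` (named list of gene id vectors).
#' @param frac fraction of the ranking taken as the query set.
#' @param alpha significance threshold on the hypergeometric p-value.
#' @param side `"top"` (strongest) or `"bottom"` (closest to zero).
#' @return integer count, with attribute `p_values` (named per pathway).
#' @export
enrichment_counts <- function(ranking, pathways, frac = 0.05, alpha = 0.05,
                              side = c("top", "bottom")) {
  side <- match.arg(side)
  stopifnot(inherits(ranking, "gene_ranking"))
  universe <- intersect(ranking$genes, unique(unlist(pathways)))
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  n_set <- top_fraction_size(length(ranking$genes), frac)
  set <- if (side == "top") head(ranking$genes, n_set) else
    utils::tail(ranking$genes, n_set)
  set <- intersect(set, universe)
  N <- length(universe)
  k <- length(set)
  p <- vapply(pathways, function(pw) {
    m <- length(intersect(pw, universe))
    if (m == 0) return(1)
    q <- length(intersect(set, pw))
    phyper(q - 1, m, N - m, k, lower.tail = FALSE)
  }, numeric(1))
  structure(sum(p < alpha), p_values = p)
}

#' ROC / AUROC of coexpression against a probabilistic gene network
#'
#' Positives are network edges with probability above `pos_thresh`;
#' negatives are an equal-sized random draw (seeded) from edges with
#' probability below `neg_thresh`. The ROC is traced over `n_points`
#' operating thresholds placed at quantiles of the absolute coexpression
#' values (so the curve, and the AUROC, are invariant to any strictly
#' monotone transform of the values); AUROC is the trapezoidal area.
#'
#' @param values data.frame (`gene_a`, `gene_b`, `value`) of coexpression
#'   values per unordered pair.
#' @param edges data.frame from [read_edge_list()].
#' @param pos_thresh,neg_thresh probability cut-offs (defaults 0.8 and
#'   0.005).
#' @param n_points number of operating thresholds.
#' @param seed seed for the negative draw.
#' @return object of class `roc_result`: `thresholds`, `tpr`, `fpr`,
#'   `auroc`, `n_pos`, `n_neg`.
#' @export
network_auroc <- function(values, edges, pos_thresh = 0.8, neg_thresh = 0.005,
                          n_points = 1000, seed = 1L) {
  stopifnot(all(c("gene_a", "gene_b", "value") %in% names(values)))
  vkey <- pair_key(values$gene_a, values$gene_b)
  score <- abs(values$value)
  names(score) <- vkey
  pos_edges <- edges[edges$probability > pos_thresh, , drop = FALSE]
  neg_pool <- edges[edges$probability < neg_thresh, , drop = FALSE]
  if (nrow(pos_edges) == 0) stop("zero positive edges", call. = FALSE)
  set.seed(child_seed(seed, 555))
  n_draw <- min(nrow(pos_edges), nrow(neg_pool))
  if (n_draw < nrow(pos_edges))
    warning("negative pool smaller than positives; using all ", n_draw)
  if (n_draw == 0) stop("no negative edges below neg_thresh", call. = FALSE)
  neg_edges <- neg_pool[sample.int(nrow(neg_pool), n_draw), , drop = FALSE]
  s_pos <- score[pair_key(pos_edges$gene_a, pos_edges$gene_b)]
  s_neg <- score[pair_key(neg_edges$gene_a, neg_edges$gene_b)]
  if (anyNA(s_pos) || anyNA(s_neg)) {
    warning(sum(is.na(s_pos)) + sum(is.na(s_neg)),
            " edge(s) without a coexpression value dropped")
    s_pos <- s_pos[!is.na(s_pos)]; s_neg <- s_neg[!is.na(s_neg)]
    if (!length(s_pos)) stop("zero scored positives", call. = FALSE)
  }
  thr <- quantile(c(s_pos, s_neg), probs = seq(0, 1, length.out = n_points),
                  names = FALSE, type = 1)
  tpr <- vapply(thr, function(t) mean(s_pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s_neg >= t), numeric(1))
  tpr <- c(1, tpr, 0); fpr <- c(1, fpr, 0)
  ord <- order(fpr, tpr)
  fpr_s <- fpr[ord]; tpr_s <- tpr[ord]
  auroc <- sum(diff(fpr_s) * (head(tpr_s, -1) + tpr_s[-1]) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auroc = auroc,
                 n_pos = length(s_pos), n_neg = length(s_neg)),
            class = "roc_result")
}

#' Overlap and median rank between two gene rankings
#'
#' `topn_overlap` counts the genes shared by the two top-n lists.
#' `median_rank_of_top` reports the median position, in ranking b over the
#' shared universe, of ranking a's top n genes (for identical rankings of n
#' = 100 this is 50.5; the idealized expectation is the middle of the top
#' list).
#'
#' @param rank_a,rank_b ordered character vectors over the same gene
#'   universe (or `gene_ranking` objects).
#' @param n list depth.
#' @return an integer overlap / a numeric median rank.
#' @export
topn_overlap <- function(rank_a, rank_b, n = 100) {
  a <- ranking_genes(rank_a); b <- ranking_genes(rank_b)
  if (n > length(a) || n > length(b)) stop("n exceeds the universe", call. = FALSE)
  length(intersect(head(a, n), head(b, n)))
}

#' @rdname topn_overlap
#' @export
median_rank_of_top <- function(rank_a, rank_b, n = 100) {
  a <- ranking_genes(rank_a); b <- ranking_genes(rank_b)
  if (n > length(a) || n > length(b)) stop("n exceeds the universe", call. = FALSE)
  pos <- match(head(a, n), b)
  if (anyNA(pos)) stop("rankings do not share a universe", call. = FALSE)
  median(pos)
}

ranking_genes <- function(x) {
  if (inherits(x, "gene_ranking")) x$genes else as.character(x)
}

#' Peak-ordering D-score
#'
#' Given genes ranked by absolute coexpression with a regulator and a flag
#' for whether each gene carries a binding peak of that regulator, the
#' D-score measures how front-loaded the peaks are: with `O_i` the
#' cumulative observed peak count and `E_i = i * P / N` the uniform
#' expectation line, `D = sum |O_i - E_i| / (N * P / 2)` — the area between
#' the observed and expected cumulative curves normalized by the triangle
#' area a peak-first perfect ordering would approach. A permutation null
#' (mean D over `n_null` random orderings) calibrates the scale.
#'
#' @param ranked_genes character vector, most coexpressed first.
#' @param peaks named logical vector (from [read_peak_table()]) covering all
#'   ranked genes.
#' @param n_null number of random orderings for the null (0 to skip).
#' @param seed seed for the permutations.
#' @return object of class `d_score_result`: `N`, `P_total`, `D`,
#'   `null_mean`, `null_D`, `O`, `E`.
#' @export
d_score <- function(ranked_genes, peaks, n_null = 100, seed = 1L) {
  miss <- setdiff(ranked_genes, names(peaks))
  if (length(miss))
    stop("no peak flag for gene(s): ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  flag <- unname(peaks[ranked_genes])
  N <- length(flag)
  P <- sum(flag)
  if (P == 0) stop("no genes with peaks among the ranked genes", call. = FALSE)
  O <- cumsum(flag)
  E <- seq_len(N) * P / N
  D <- sum(abs(O - E)) / (N * P / 2)
  null_D <- numeric(0)
  if (n_null > 0) {
    set.seed(child_seed(seed, 444))
    null_D <- vapply(seq_len(n_null), function(b) {
      f <- sample(flag)
      sum(abs(cumsum(f) - E)) / (N * P / 2)
    }, numeric(1))
  }
  structure(list(N = N, P_total = P, D = D,
                 null_mean = if (n_null > 0) mean(null_D) else NA_real_,
                 null_D = null_D, O = O, E = E),
            class = "d_score_result")
}
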