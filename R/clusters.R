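#' Purity score of a cluster for a tissue
#'
#' `P = (I/T) * (I/C)`: the product of the cluster's recall and precision
#' for the tissue, where `I` is the intersection size, `T` the tissue size
#' and `C` the cluster size. `P = 1` exactly when tissue and cluster
#' coincide.
#'
#' @param I,T,C intersection, tissue and cluster sizes.
#' @return purity in `[0, 1]`.
#' @export
purity_score <- function(I, T, C) {
  stopifnot(I >= 0, T > 0, C > 0, I <= T, I <= C)
  (I / T) * (I / C)
}

#' Build a Jaccard-weighted kNN graph
#'
#' Each sample is connected to its k nearest neighbours under Euclidean
#' distance; the graph is symmetrized by union and each edge is weighted by
#' the Jaccard index of the two endpoints' closed neighbour sets (the sample
#' together with its k neighbours, as in shared-nearest-neighbour graphs) —
#' so two mutual neighbours sharing all their neighbours get weight 1.
#' Edges whose endpoints share no neighbours keep a tiny positive weight so
#' connectivity is preserved for the community search.
#'
#' @param scores samples-by-dimensions coordinate matrix.
#' @param k number of neighbours (`k < n`).
#' @return an undirected weighted [igraph::graph].
#' @export
knn_jaccard_graph <- function(scores, k) {
  scores <- pc_scores(scores)
  n <- nrow(scores)
  stopifnot(k >= 1, k < n)
  nn <- FNN::get.knn(scores, k = k)$nn.index
  B <- matrix(0L, n, n)
  B[cbind(rep(seq_len(n), k), as.vector(nn))] <- 1L
  A <- (B + t(B)) > 0                    # union symmetrization
  diag(B) <- 1L                          # closed neighbour sets
  inter <- tcrossprod(B)
  sz <- rowSums(B)                       # < k+1 only for degenerate ties
  jac <- inter / (outer(sz, sz, "+") - inter)
  edges <- which(A & upper.tri(A), arr.ind = TRUE)
  w <- pmax(jac[edges], 1e-6)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  g
}

#' Louvain partitions over a range of neighbourhood sizes
#'
#' For each k in `k_range`, builds the Jaccard-weighted kNN graph and runs
#' Louvain community detection; values of k at or above the sample count are
#' skipped with a warning.
#'
#' @param pcs a `pc_embedding` or coordinate matrix.
#' @param k_range integer vector of neighbourhood sizes (production default
#'   1..100).
#' @param seed seed for the (seeded) Louvain runs.
#' @return object of class `partition_sweep`: list `partitions` keyed by k
#'   with `membership` and `modularity`.
#' @export
louvain_sweep <- function(pcs, k_range = 1:100, seed = 1L) {
  scores <- pc_scores(pcs)
  n <- nrow(scores)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  usable <- k_range[k_range < n]
  if (length(usable) < length(k_range))
    warning("k >= n_samples skipped: ",
            paste(setdiff(k_range, usable), collapse = ", "))
  partitions <- list()
  for (k in usable) {
    g <- knn_jaccard_graph(scores, k)
    set.seed(child_seed(seed, 2000 + k))
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    partitions[[as.character(k)]] <-
      list(k = k, membership = igraph::membership(cl),
           modularity = igraph::modularity(cl))
  }
  structure(list(partitions = partitions, n = n), class = "partition_sweep")
}

#' Flag mixed and divergent samples from the partition sweep
#'
#' For each tissue, the (k, cluster) pair maximizing the purity
#' `P = (I/T)(I/C)` is selected. At that tissue's best k, samples of the
#' tissue falling outside its best cluster are inspected: if the cluster
#' they sit in is dominated by another tissue (that tissue's purity for the
#' cluster is at least `p_min`) they are flagged `DIVERGENT`; if no tissue
#' dominates the cluster (max purity below `p_min`) they are flagged
#' `MIXED`. Samples in a cluster dominated by their own tissue stay `KEPT`.
#'
#' @param partitions a `partition_sweep`.
#' @param tissues per-sample tissue labels, named by sample id.
#' @param p_min dominance threshold on the purity score.
#' @return a `cluster_assignment` data.frame (`sample_id`, `tissue`,
#'   `cluster`, `status`, `P`, `k`) with attributes `tissue_map` (per-tissue
#'   best k / cluster / purity) and `cross_purity` (purity of each tissue
#'   against every other tissue's best cluster).
#' @export
flag_mixed_and_divergent <- function(partitions, tissues, p_min = 0.5) {
  stopifnot(inherits(partitions, "partition_sweep"))
  if (is.null(names(tissues))) stop("`tissues` must be named by sample id")
  n <- partitions$n
  stopifnot(length(tissues) == n)
  tiss_levels <- unique(tissues)
  if (any(table(tissues) == 0) || length(tiss_levels) == 0)
    stop("tissue absent from all partitions", call. = FALSE)

  # best (k, cluster) per tissue
  best <- data.frame(tissue = tiss_levels, k = NA_integer_,
                     cluster = NA_integer_, P = -1, stringsAsFactors = FALSE)
  for (part in partitions$partitions) {
    mem <- part$membership
    for (ti in seq_along(tiss_levels)) {
      t <- tiss_levels[ti]
      in_t <- tissues == t
      Tn <- sum(in_t)
      tab <- table(mem[in_t])
      for (cl in names(tab)) {
        I <- tab[[cl]]
        Cn <- sum(mem == as.integer(cl))
        P <- purity_score(I, Tn, Cn)
        if (P > best$P[ti]) {
          best$P[ti] <- P; best$k[ti] <- part$k; best$cluster[ti] <- as.integer(cl)
        }
      }
    }
  }

  sample_ids <- names(tissues)
  status <- rep("KEPT", n)
  P_col <- best$P[match(tissues, best$tissue)]
  k_col <- best$k[match(tissues, best$tissue)]
  cluster_col <- tissues   # cluster named by its matched tissue

  for (ti in seq_along(tiss_levels)) {
    t <- tiss_levels[ti]
    mem <- partitions$partitions[[as.character(best$k[ti])]]$membership
    in_t <- which(tissues == t)
    outside <- in_t[mem[in_t] != best$cluster[ti]]
    for (s in outside) {
      cl <- mem[s]
      Cn <- sum(mem == cl)
      doms <- vapply(tiss_levels, function(tt)
        purity_score(sum(mem == cl & tissues == tt), sum(tissues == tt), Cn),
        numeric(1))
      top <- which.max(doms)
      if (doms[top] < p_min) {
        status[s] <- "MIXED"
      } else if (tiss_levels[top] != t) {
        status[s] <- "DIVERGENT"
      } # dominated by own tissue (tissue split over clusters): stays KEPT
    }
  }

  # cross purity: tissue A against tissue B's best cluster (at B's best k)
  cross <- matrix(0, length(tiss_levels), length(tiss_levels),
                  dimnames = list(tiss_levels, tiss_levels))
  for (bi in seq_along(tiss_levels)) {
    mem <- partitions$partitions[[as.character(best$k[bi])]]$membership
    cl <- best$cluster[bi]
    Cn <- sum(mem == cl)
    for (ai in seq_along(tiss_levels)) {
      Ta <- sum(tissues == tiss_levels[ai])
      I <- sum(mem == cl & tissues == tiss_levels[ai])
      cross[ai, bi] <- purity_score(I, Ta, Cn)
    }
  }

  out <- data.frame(sample_id = sample_ids, tissue = unname(tissues),
                    cluster = unname(cluster_col), status = status,
                    P = unname(P_col), k = unname(k_col),
                    stringsAsFactors = FALSE)
  structure(out, class = c("cluster_assignment", "data.frame"),
            tissue_map = best, cross_purity = cross)
}

#' Merge tissue pairs whose samples share one cluster
#'
#' Two tissues are merged into a single tissue cluster (named from both)
#' when each tissue's purity against the other's best cluster reaches
#' `mix_threshold` — the signature of two tissue labels co-occupying one
#' expression cluster. Chains of more than two tissues are merged
#' transitively with a warning.
#'
#' @param assignment a `cluster_assignment` from
#'   [flag_mixed_and_divergent()].
#' @param mix_threshold mutual-purity threshold.
#' @return the updated `cluster_assignment`, with attribute `merges` (list
#'   of merged tissue groups).
#' @export
merge_mixed_tissue_pairs <- function(assignment, mix_threshold = 0.25) {
  cross <- attr(assignment, "cross_purity")
  if (is.null(cross)) stop("assignment lacks cross-purity information", call. = FALSE)
  tiss <- rownames(cross)
  parent <- seq_along(tiss)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(tiss)) for (j in seq_along(tiss)) {
    if (i < j && cross[i, j] >= mix_threshold && cross[j, i] >= mix_threshold)
      parent[find(j)] <- find(i)
  }
  groups <- split(tiss, vapply(seq_along(tiss), find, integer(1)))
  merges <- groups[lengths(groups) > 1]
  if (any(lengths(merges) > 2))
    warning("tissue chain of more than 2 merged transitively: ",
            paste(vapply(merges[lengths(merges) > 2], paste, "", collapse = "+"),
                  collapse = "; "))
  for (grp in merges) {
    nm <- paste(sort(grp), collapse = "+")
    assignment$cluster[assignment$tissue %in% grp] <- nm
  }
  attr(assignment, "merges") <- unname(merges)
  assignment
}

#' Apply a manual exclusion list
#'
#' Visual outliers that survive the automated stages can be listed in a
#' plain-text file (one sample id per line) and are marked `MANUAL`; they are
#' never inferred.
#'
#' @param assignment a `cluster_assignment`.
#' @param sample_ids character vector or path to a file of sample ids.
#' @return updated assignment.
#' @export
apply_manual_exclusions <- function(assignment, sample_ids) {
  if (length(sample_ids) == 1 && file.exists(sample_ids))
    sample_ids <- readLines(sample_ids)
  sample_ids <- trimws(sample_ids)
  sample_ids <- sample_ids[nzchar(sample_ids)]
  assignment$status[assignment$sample_id %in% sample_ids] <- "MANUAL"
  assignment
}
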