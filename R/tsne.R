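#' 2-D t-SNE embedding of the PC scores
#'
#' Exact (theta = 0) t-SNE with the stage-two defaults: perplexity 30,
#' learning rate 200, 1000 iterations, no internal PCA and no input
#' normalization. Deterministic given `seed`.
#'
#' @param pcs a `pc_embedding` or coordinate matrix (samples in rows).
#' @param perplexity,learning_rate,theta,max_iter t-SNE parameters.
#' @param seed seed for the embedding initialization.
#' @return object of class `tsne_embedding`: `coords` (n x 2, rownames =
#'   sample ids) and `params`.
#' @export
tsne_embed <- function(pcs, perplexity = 30, learning_rate = 200, theta = 0,
                       max_iter = 1000, seed = 1L) {
  scores <- pc_scores(pcs)
  n <- nrow(scores)
  if (perplexity >= (n - 1) / 3)
    stop(sprintf("perplexity %g too large for %d samples (needs < (n-1)/3)",
                 perplexity, n), call. = FALSE)
  set.seed(child_seed(seed, 777))
  fit <- Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity,
                      theta = theta, eta = learning_rate, max_iter = max_iter,
                      pca = FALSE, normalize = FALSE, check_duplicates = FALSE,
                      verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- rownames(scores)
  structure(list(coords = coords,
                 params = list(perplexity = perplexity,
                               learning_rate = learning_rate, theta = theta,
                               max_iter = max_iter, seed = seed)),
            class = "tsne_embedding")
}

#' Medoid-kNN outlier removal on the t-SNE embedding
#'
#' Stage two of the purification. For every cluster of KEPT samples, a
#' medoid is computed as the coordinate-wise median over samples that are
#' not boxplot outliers (outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`) in either
#' t-SNE dimension (clusters smaller than 4 skip the trim, with a warning).
#' Each sample is then assigned its nearest medoid (ties broken toward the
#' larger cluster) and its cluster membership is predicted by majority vote
#' among its k nearest samples in the embedding, with k equal to the size of
#' the nearest-medoid's cluster. Samples whose predicted cluster differs
#' from their assigned cluster are flagged `TSNE_OUTLIER`; vote ties keep
#' the sample.
#'
#' @param embedding a `tsne_embedding` covering all KEPT samples.
#' @param assignment a `cluster_assignment`.
#' @return the updated `cluster_assignment`.
#' @export
medoid_knn_outlier_removal <- function(embedding, assignment) {
  stopifnot(inherits(embedding, "tsne_embedding"))
  kept <- assignment$status == "KEPT"
  ids <- assignment$sample_id[kept]
  miss <- setdiff(ids, rownames(embedding$coords))
  if (length(miss))
    stop("embedding lacks KEPT sample(s): ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  Y <- embedding$coords[ids, , drop = FALSE]
  cl <- assignment$cluster[kept]
  clusters <- unique(cl)

  medoids <- matrix(NA_real_, length(clusters), 2,
                    dimnames = list(clusters, NULL))
  sizes <- setNames(integer(length(clusters)), clusters)
  for (cc in clusters) {
    pts <- Y[cl == cc, , drop = FALSE]
    sizes[cc] <- nrow(pts)
    if (nrow(pts) < 4) {
      warning("cluster ", cc, " has fewer than 4 samples; medoid without outlier trim")
      keep_pts <- rep(TRUE, nrow(pts))
    } else {
      keep_pts <- rep(TRUE, nrow(pts))
      for (d in 1:2) {
        q <- quantile(pts[, d], c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        keep_pts <- keep_pts & pts[, d] >= q[1] - 1.5 * iqr &
          pts[, d] <= q[2] + 1.5 * iqr
      }
      if (!any(keep_pts)) keep_pts <- rep(TRUE, nrow(pts))
    }
    medoids[cc, ] <- apply(pts[keep_pts, , drop = FALSE], 2, median)
  }

  d_med <- outer(rowSums(Y^2), rowSums(medoids^2), "+") - 2 * Y %*% t(medoids)
  # nearest medoid, ties toward the larger cluster
  nearest <- apply(d_med, 1, function(dr) {
    cand <- which(dr <= min(dr) + 1e-12)
    cand[which.max(sizes[cand])]
  })
  nearest_cluster <- clusters[nearest]

  D <- as.matrix(dist(Y))
  diag(D) <- Inf
  n <- nrow(Y)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    k <- min(sizes[nearest_cluster[i]], n - 1)
    nb <- order(D[i, ])[seq_len(k)]
    votes <- table(cl[nb])
    topv <- names(votes)[votes == max(votes)]
    if (length(topv) == 1 && topv != cl[i]) flagged[i] <- TRUE
    # tie -> sample kept (innocent until proven outlier)
  }
  assignment$status[match(ids[flagged], assignment$sample_id)] <- "TSNE_OUTLIER"
  assignment
}

#' Two-stage tissue-cluster purification
#'
#' Runs the whole purification chain: permutation-tested PCA, Louvain sweep
#' over the k grid, mixed/divergent flagging with purity matching, merging
#' of co-occupying tissue pairs, and t-SNE medoid-kNN outlier removal.
#' When fewer than 2 components pass the permutation test, the first 2 are
#' used for the downstream geometry (with a warning), since the clustering
#' and embedding need coordinates.
#'
#' @param expr [expr_matrix()] (normalized scale recommended).
#' @param tissues per-sample tissue labels, named by sample id (defaults to
#'   names taken from the expression columns).
#' @param k_range Louvain neighbourhood sizes (production default 1..100).
#' @param n_perm PCA permutations.
#' @param p_min,mix_threshold purity thresholds for flagging and merging.
#' @param perplexity,learning_rate,max_iter t-SNE parameters.
#' @param manual_exclusions optional sample ids (or file) marked `MANUAL`.
#' @param seed root seed.
#' @return the final `cluster_assignment`, with attribute `pcs` (the
#'   `pc_embedding`) and `tsne` (the embedding).
#' @export
purify_tissue_clusters <- function(expr, tissues, k_range = 1:100,
                                   n_perm = 100, p_min = 0.5,
                                   mix_threshold = 0.25, perplexity = 30,
                                   learning_rate = 200, max_iter = 1000,
                                   manual_exclusions = NULL, seed = 1L) {
  if (is.null(names(tissues))) names(tissues) <- sample_ids(expr)
  tissues <- tissues[sample_ids(expr)]
  pcs <- retain_significant_pcs(expr, n_perm = n_perm, seed = seed)
  if (pcs$n_retained < 2) {
    warning("fewer than 2 significant components; using the first 2 for geometry")
    v <- if (inherits(expr, "expr_matrix")) expr$values else expr
    sds <- apply(v, 1, sd)
    X <- t((v[sds > 0, , drop = FALSE] - rowMeans(v[sds > 0, , drop = FALSE])) /
             sds[sds > 0])
    sv <- svd(X, nu = 2, nv = 0)
    pcs$scores <- sv$u %*% diag(sv$d[1:2], 2)
    rownames(pcs$scores) <- rownames(X)
  }
  sweep <- louvain_sweep(pcs, k_range = k_range, seed = seed)
  assignment <- flag_mixed_and_divergent(sweep, tissues, p_min = p_min)
  assignment <- merge_mixed_tissue_pairs(assignment, mix_threshold = mix_threshold)
  emb <- tsne_embed(pcs, perplexity = min(perplexity,
                                          floor((nrow(pcs$scores) - 2) / 3)),
                    learning_rate = learning_rate, max_iter = max_iter,
                    seed = seed)
  assignment <- medoid_knn_outlier_removal(emb, assignment)
  if (!is.null(manual_exclusions))
    assignment <- apply_manual_exclusions(assignment, manual_exclusions)
  attr(assignment, "pcs") <- pcs
  attr(assignment, "tsne") <- emb
  assignment
}

#' Write / read a cluster assignment TSV
#'
#' @param assignment a `cluster_assignment`.
#' @param path TSV path.
#' @export
write_cluster_assignment <- function(assignment, path) {
  data.table::fwrite(as.data.frame(assignment), path, sep = "\t")
  invisible(path)
}

#' @rdname write_cluster_assignment
#' @export
read_cluster_assignment <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("sample_id", "tissue", "cluster", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format(path, "missing required column(s): %s", paste(miss, collapse = ", "))
  class(df) <- c("cluster_assignment", "data.frame")
  df
}
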