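#' Retain statistically significant principal components
#'
#' Genes are standardized (mean 0, sd 1; constant genes are excluded with a
#' warning), then samples are decomposed by PCA. Components are tested
#' sequentially against a permutation null: component i is kept if its
#' explained share of the residual variance (after removing the previously
#' retained components) exceeds the chosen summary — by default the maximum —
#' of `n_perm` first-component shares computed on the residual matrix with
#' each gene's values independently permuted. The test stops at the first
#' failure, yielding the leading block of components that carry more
#' structure than gene-wise-scrambled data.
#'
#' @param expr [expr_matrix()] or genes-by-samples numeric matrix.
#' @param n_perm permutations per component (100 by default).
#' @param seed seed for the permutation streams.
#' @param rule `"max"` (exceed every permuted share) or `"q95"` (exceed the
#'   95th percentile).
#' @param max_pcs cap on the number of components tested.
#' @return object of class `pc_embedding`: `scores` (samples x retained
#'   components), `explained_variance` (share of total variance per retained
#'   component), `n_retained`, `n_perm`.
#' @export
retain_significant_pcs <- function(expr, n_perm = 100, seed = 1L,
                                   rule = c("max", "q95"), max_pcs = NULL) {
  rule <- match.arg(rule)
  v <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (ncol(v) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from standardization")
    v <- v[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- t((v - rowMeans(v)) / sds)        # samples x genes, genes standardized
  n <- nrow(X); p <- ncol(X)
  kmax <- min(max_pcs %||% Inf, n - 1, p)
  sv <- svd(X, nu = kmax, nv = 0)
  d2 <- sv$d^2
  total <- sum(d2)

  retained <- 0L
  R <- X
  for (i in seq_len(kmax)) {
    resid_total <- sum(d2[i:length(d2)])
    obs_share <- d2[i] / resid_total
    set.seed(child_seed(seed, 1000 + i))
    null_shares <- vapply(seq_len(n_perm), function(b) {
      Rp <- apply(R, 2, sample)
      first_share(Rp)
    }, numeric(1))
    crit <- if (rule == "max") max(null_shares) else
      quantile(null_shares, 0.95, names = FALSE)
    if (obs_share <= crit) break
    retained <- i
    # residualize: remove component i before permuting for the next test
    R <- R - sv$d[i] * sv$u[, i] %*% t(svd_v(sv, X, i))
  }
  scores <- if (retained > 0)
    sv$u[, seq_len(retained), drop = FALSE] %*% diag(sv$d[seq_len(retained)],
                                                     retained)
  else matrix(numeric(0), n, 0)
  rownames(scores) <- rownames(X)
  structure(list(scores = scores,
                 explained_variance = d2[seq_len(retained)] / total,
                 n_retained = retained, n_perm = n_perm, rule = rule),
            class = "pc_embedding")
}

# right singular vector i, recomputed cheaply from u and d (nv = 0 above)
svd_v <- function(sv, X, i) {
  vi <- crossprod(X, sv$u[, i]) / sv$d[i]
  as.vector(vi)
}

# share of variance carried by the first singular value
first_share <- function(M) {
  tot <- sum(M^2)
  if (tot == 0) return(0)
  k <- min(dim(M))
  d1 <- if (k > 6) {
    RSpectra::svds(M, k = 1, nu = 0, nv = 0)$d
  } else {
    svd(M, nu = 0, nv = 0)$d[1]
  }
  d1^2 / tot
}

pc_scores <- function(x) {
  if (inherits(x, "pc_embedding")) x$scores else as.matrix(x)
}
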