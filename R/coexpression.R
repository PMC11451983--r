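#' Build the subsample design
#'
#' For each replicate, draws `n_per` samples uniformly at random without
#' repetition from every tissue cluster (70 is roughly 80% of the smallest
#' production cluster). A cluster of exactly `n_per` samples contributes the
#' same selection in every replicate. Replicate `r` uses the derived seed
#' `child_seed(base_seed, r)`, so the whole design is reproducible from
#' `base_seed`.
#'
#' @param assignment a `cluster_assignment` (only KEPT samples are used) or a
#'   named character vector mapping sample id to cluster.
#' @param n_per samples per cluster per replicate.
#' @param n_reps number of replicates.
#' @param base_seed root seed.
#' @param strict if TRUE, a cluster with fewer than `n_per` kept samples is
#'   an error; if FALSE it contributes all its samples with a warning.
#' @return object of class `subsample_design`: a list of replicates, each a
#'   named list of sample-id vectors per cluster.
#' @export
make_subsample_design <- function(assignment, n_per = 70, n_reps = 20,
                                  base_seed = 1L, strict = TRUE) {
  cl <- kept_cluster_map(assignment)
  by_cluster <- split(names(cl), cl)
  sizes <- lengths(by_cluster)
  if (any(sizes < n_per)) {
    small <- names(sizes)[sizes < n_per]
    if (strict)
      stop("cluster(s) with fewer than ", n_per, " kept samples: ",
           paste(small, collapse = ", "), call. = FALSE)
    warning("undersized cluster(s) use all samples: ", paste(small, collapse = ", "))
  }
  reps <- lapply(seq_len(n_reps), function(r) {
    set.seed(child_seed(base_seed, r))
    lapply(by_cluster, function(ids) {
      if (length(ids) <= n_per) sort(ids) else sort(sample(ids, n_per))
    })
  })
  structure(list(reps = reps, n_per = n_per, n_reps = n_reps,
                 base_seed = base_seed, clusters = names(by_cluster)),
            class = "subsample_design")
}

kept_cluster_map <- function(assignment) {
  if (inherits(assignment, "cluster_assignment") || is.data.frame(assignment)) {
    kept <- assignment[assignment$status == "KEPT", , drop = FALSE]
    return(setNames(kept$cluster, kept$sample_id))
  }
  if (!is.null(names(assignment))) return(assignment)
  stop("`assignment` must be a cluster_assignment or a named cluster vector",
       call. = FALSE)
}

#' Correlation matrix under Pearson or Spearman
#'
#' Spearman uses average ranks for ties (via [stats::cor()]). A constant
#' gene, whose correlation is undefined, gets zeros in its row and column
#' (diagonal 1) and is listed in the `constant_genes` flag.
#'
#' @param x [expr_matrix()] or genes-by-samples matrix with at least 3
#'   samples.
#' @param metric `"pearson"` or `"spearman"`.
#' @param modality,stratum,rep tags forwarded to [coex_result()].
#' @return a [coex_result()].
#' @export
correlation_matrix <- function(x, metric = c("pearson", "spearman"),
                               modality = "tpm", stratum = "ALL",
                               rep = NA_integer_) {
  metric <- match.arg(metric)
  v <- if (inherits(x, "expr_matrix")) x$values else x
  if (ncol(v) < 3) stop("need at least 3 samples", call. = FALSE)
  r <- suppressWarnings(cor(t(v), method = metric))
  const <- rownames(v)[apply(v, 1, function(z) max(z) == min(z))]
  if (length(const)) {
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  coex_result(r, metric, modality, "per_rep", stratum = stratum, rep = rep,
              flags = list(constant_genes = const))
}

#' Z-score expression within tissue clusters
#'
#' Transforms log10-scale expression to the tissue-level modality:
#' `z = (x - m) / s` per gene, where `m` and `s` are the gene's mean and
#' sample standard deviation inside the sample's tissue cluster. Genes with
#' `s = 0` in a cluster get `z = 0` there and are flagged.
#'
#' @param expr [expr_matrix()] on the `LOG10P1` scale.
#' @param clusters per-sample cluster labels, or a `cluster_assignment`
#'   (KEPT samples only; `expr` is subset accordingly).
#' @return [expr_matrix()] with scale `ZSCORE`; attribute
#'   `zero_sd` records flagged (gene, cluster) combinations.
#' @export
zscore_by_cluster <- function(expr, clusters) {
  check_scale(expr, c("LOG10P1", "TPM"))
  if (inherits(clusters, "cluster_assignment") || is.data.frame(clusters)) {
    map <- kept_cluster_map(clusters)
    expr <- subset_expr(expr, j = intersect(sample_ids(expr), names(map)))
    clusters <- unname(map[sample_ids(expr)])
  }
  stopifnot(length(clusters) == ncol(expr$values))
  v <- expr$values
  out <- v
  zero_sd <- list()
  for (cl in unique(clusters)) {
    j <- which(clusters == cl)
    sub <- v[, j, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1, sd)
    flat <- s == 0 | is.na(s)
    if (any(flat)) zero_sd[[cl]] <- rownames(v)[flat]
    s[flat] <- Inf
    out[, j] <- (sub - m) / s
  }
  res <- expr_matrix(out, "ZSCORE", expr$description)
  attr(res, "zero_sd") <- zero_sd
  res
}

#' Estimate per-replicate coexpression matrices
#'
#' Runs every requested metric on every subsample replicate of the design.
#' The `tpm` (system-level) modality requires `LOG10P1` input; the `zscore`
#' (tissue-level) modality requires `ZSCORE` input (see
#' [zscore_by_cluster()]) — a mismatch is an error, never silently fixed.
#' The G-statistic discretization is fitted per replicate on the subset by
#' default; `fit_codes_once = TRUE` fits on all samples and reuses the codes.
#'
#' @param expr [expr_matrix()] in the scale matching `modality`.
#' @param design a [make_subsample_design()].
#' @param metrics subset of `c("pearson", "spearman", "g")`.
#' @param modality `"tpm"` or `"zscore"`.
#' @param stratum stratum tag.
#' @param fit_codes_once reuse one discretization across replicates.
#' @param floor_rule forwarded to [g_matrix()].
#' @return list of [coex_result()] (aggregation `per_rep`), one per
#'   (replicate, metric).
#' @export
estimate_all <- function(expr, design, metrics = c("pearson", "spearman", "g"),
                         modality = c("tpm", "zscore"), stratum = "ALL",
                         fit_codes_once = FALSE, floor_rule = "gt4_1") {
  modality <- match.arg(modality)
  metrics <- match.arg(metrics, several.ok = TRUE)
  expected <- if (modality == "tpm") "LOG10P1" else "ZSCORE"
  if (expr$scale != expected)
    stop(sprintf("modality '%s' requires scale %s but expression is %s",
                 modality, expected, expr$scale), call. = FALSE)
  stopifnot(inherits(design, "subsample_design"))
  all_codes <- if ("g" %in% metrics && fit_codes_once)
    discretize_matrix(expr$values)
  results <- list()
  for (r in seq_along(design$reps)) {
    ids <- unlist(design$reps[[r]], use.names = FALSE)
    missing <- setdiff(ids, sample_ids(expr))
    if (length(missing))
      stop("design sample(s) absent from expression: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    sub <- expr$values[, ids, drop = FALSE]
    for (m in metrics) {
      res <- if (m == "g") {
        codes <- if (fit_codes_once) all_codes[, ids, drop = FALSE]
        gm <- g_matrix(sub, floor_rule = floor_rule, codes = codes)
        diag_na <- gm; diag(diag_na) <- 0  # symmetric container; diag flagged
        cr <- coex_result(diag_na, "g", modality, "per_rep", stratum, rep = r,
                          flags = list(diagonal_undefined = TRUE))
        cr$values[cbind(seq_len(nrow(gm)), seq_len(nrow(gm)))] <- NA_real_
        cr
      } else {
        correlation_matrix(sub, m, modality = modality, stratum = stratum,
                           rep = r)
      }
      results[[length(results) + 1]] <- res
    }
  }
  results
}

#' Pessimistic minimum aggregation over replicates
#'
#' For the correlation metrics, the retained value for a pair is the
#' replicate value of smallest absolute magnitude with its sign preserved —
#' the weakest association the pair ever showed; pairs whose sign disagrees
#' across replicates are flagged. For the G-statistic, the smallest G. With
#' `raw_signed = TRUE` the plain signed minimum is taken instead.
#'
#' @param per_rep list of per-replicate [coex_result()]s with one metric,
#'   modality and stratum.
#' @param raw_signed take the raw signed minimum for correlations.
#' @return a [coex_result()] with aggregation `"min"`; for correlations the
#'   flag `sign_disagreement` marks pairs with both signs across replicates.
#' @export
aggregate_minimum <- function(per_rep, raw_signed = FALSE) {
  stopifnot(length(per_rep) >= 1)
  metrics <- unique(vapply(per_rep, `[[`, character(1), "metric"))
  if (length(metrics) != 1)
    stop("mixed metrics in per-replicate results: ",
         paste(metrics, collapse = ", "), call. = FALSE)
  modality <- unique(vapply(per_rep, `[[`, character(1), "modality"))
  stratum <- unique(vapply(per_rep, `[[`, character(1), "stratum"))
  stopifnot(length(modality) == 1, length(stratum) == 1)
  arr <- vapply(per_rep, function(r) r$values,
                per_rep[[1]]$values)  # p x p x R
  p <- dim(arr)[1]
  dn <- dimnames(per_rep[[1]]$values)
  flags <- list()
  if (metrics == "g") {
    vals <- apply(arr, c(1, 2), min)
  } else if (raw_signed) {
    vals <- apply(arr, c(1, 2), min)
    diag(vals) <- 1
  } else {
    flat <- matrix(arr, nrow = p * p)
    pick <- max.col(-abs(flat), ties.method = "first")
    vals <- matrix(flat[cbind(seq_len(p * p), pick)], p, p)
    pos <- matrix(apply(flat > 0, 1, any) & apply(flat < 0, 1, any), p, p)
    diag(pos) <- FALSE
    dimnames(pos) <- dn
    flags$sign_disagreement <- pos
    diag(vals) <- 1
  }
  dimnames(vals) <- dn
  coex_result(vals, metrics, modality, "min", stratum = stratum, flags = flags)
}

#' Enumerate the matrices a configuration produces
#'
#' The inventory counts per-replicate matrices (modalities x replicates x
#' metrics), covariate-stratum matrices (modalities x strata, Pearson only),
#' and minimum-aggregated matrices (metrics x modalities). The default
#' configuration — 2 modalities, 20 replicates, 3 metrics, 7 covariate
#' strata — yields 120 + 14 + 6 = 140 matrices.
#'
#' @param n_reps,n_metrics,n_modalities,n_strata configuration counts.
#' @return list with `manifest` (one row per matrix) and `total`.
#' @export
matrix_inventory <- function(n_reps = 20, n_metrics = 3, n_modalities = 2,
                             n_strata = 7) {
  metrics <- head(c("pearson", "spearman", "g"), n_metrics)
  modalities <- head(c("tpm", "zscore"), n_modalities)
  per_rep <- expand.grid(modality = modalities, rep = seq_len(n_reps),
                         metric = metrics, stratum = "ALL",
                         aggregation = "per_rep", stringsAsFactors = FALSE)
  strata <- if (n_strata > 0)
    expand.grid(modality = modalities, rep = NA_integer_, metric = "pearson",
                stratum = paste0("stratum", seq_len(n_strata)),
                aggregation = "per_rep", stringsAsFactors = FALSE)
  mins <- expand.grid(modality = modalities, rep = NA_integer_,
                      metric = metrics, stratum = "ALL", aggregation = "min",
                      stringsAsFactors = FALSE)
  manifest <- rbind(per_rep, strata, mins)
  list(manifest = manifest, total = nrow(manifest),
       counts = c(per_rep = nrow(per_rep),
                  covariate = if (is.null(strata)) 0L else nrow(strata),
                  minimum = nrow(mins)))
}
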