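blob_coords <- function(centers, n_each, sd = 0.5, seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_each, centers[i, 1], sd), rnorm(n_each, centers[i, 2], sd))))
  rownames(out) <- sprintf("S-%03d-01", seq_len(nrow(out)))
  out
}

test_that("purity score is the recall-precision product and is 1 iff sets coincide", {
  expect_equal(purity_score(10, 10, 10), 1)
  expect_equal(purity_score(10, 20, 10), 0.5)
  expect_equal(purity_score(5, 10, 20), (5 / 10) * (5 / 20))
  expect_lt(purity_score(9, 10, 10), 1)   # any mismatch drops below 1
  expect_lt(purity_score(10, 10, 11), 1)
  expect_error(purity_score(11, 10, 10))
})

test_that("pc retention keeps noise out and planted structure in", {
  # pure iid noise: at most 2 components survive the permutation test
  for (s in 1:3) {
    set.seed(s)
    noise <- matrix(rnorm(100 * 150), 100, 150,
                    dimnames = list(paste0("g", 1:100), paste0("s", 1:150)))
    pcs <- retain_significant_pcs(noise, n_perm = 30, seed = s)
    expect_lte(pcs$n_retained, 2)
  }
  # one strong planted factor is retained and recovered by PC1
  set.seed(7)
  fac <- rnorm(150)
  load <- rnorm(100)
  sig <- outer(load, fac) * 1.5 + matrix(rnorm(100 * 150), 100, 150)
  dimnames(sig) <- dimnames(noise)
  pcs <- retain_significant_pcs(sig, n_perm = 30, seed = 7)
  expect_gte(pcs$n_retained, 1)
  expect_gt(abs(cor(pcs$scores[, 1], fac)), 0.9)
  expect_true(all(diff(pcs$explained_variance) <= 1e-12))
  # constant gene excluded with a warning
  sig2 <- rbind(sig, flat = rep(1, 150))
  expect_warning(retain_significant_pcs(sig2, n_perm = 5, seed = 1), "constant")
  expect_error(retain_significant_pcs(sig[, 1, drop = FALSE]), "2 samples")
})

test_that("jaccard edge weights follow the shared-neighbour definition", {
  pts <- rbind(c(0, 0), c(0, 0.01), c(0, 0.02), c(0, 0.05),
               c(10, 0), c(10, 0.01), c(10, 0.02), c(10, 0.05))
  rownames(pts) <- paste0("s", 1:8)
  g <- knn_jaccard_graph(pts, k = 3)
  w <- igraph::E(g)$weight
  ends <- igraph::ends(g, igraph::E(g))
  # brute-force oracle on the closed neighbour sets
  nn <- FNN::get.knn(pts, k = 3)$nn.index
  closed <- lapply(seq_len(nrow(pts)), function(i) unique(c(i, nn[i, ])))
  for (e in seq_len(nrow(ends))) {
    i <- as.integer(ends[e, 1]); j <- as.integer(ends[e, 2])
    inter <- length(intersect(closed[[i]], closed[[j]]))
    uni <- length(union(closed[[i]], closed[[j]]))
    expect_equal(w[e], max(inter / uni, 1e-6))
  }
  # mutual neighbours sharing all their neighbours get weight 1: within a
  # tight quadruplet, closed sets of the four points coincide
  expect_true(any(abs(w - 1) < 1e-12))
})

test_that("louvain sweep separates clean blobs and collapses identical points", {
  pts <- blob_coords(rbind(c(0, 0), c(20, 20)), 15, seed = 3)
  sw <- louvain_sweep(pts, k_range = 10, seed = 1)
  mem <- sw$partitions[["10"]]$membership
  truth <- rep(1:2, each = 15)
  expect_equal(length(unique(mem)), 2)
  expect_true(all(table(mem, truth) %in% c(0, 15)))
  # identical points with a complete graph form one community
  same <- matrix(0, 8, 2, dimnames = list(paste0("s", 1:8), NULL))
  sw2 <- louvain_sweep(same, k_range = 7, seed = 1)
  expect_equal(length(unique(sw2$partitions[["7"]]$membership)), 1)
  # k >= n is skipped with a warning
  expect_warning(louvain_sweep(pts[1:5, ], k_range = c(2, 10), seed = 1),
                 "skipped")
})

test_that("perfectly separated tissues are fully kept with purity 1", {
  pts <- blob_coords(rbind(c(0, 0), c(30, 0), c(0, 30)), 30, seed = 5)
  tissues <- setNames(rep(c("A", "B", "C"), each = 30), rownames(pts))
  sw <- louvain_sweep(pts, k_range = c(15, 20, 25), seed = 2)
  asg <- flag_mixed_and_divergent(sw, tissues)
  expect_true(all(asg$status == "KEPT"))
  expect_true(all(asg$P == 1))
  # conservation: n_input = n_kept + n_flagged
  expect_equal(nrow(asg), sum(asg$status == "KEPT"))
  # no merges among distinct tissues
  merged <- merge_mixed_tissue_pairs(asg)
  expect_length(attr(merged, "merges"), 0)
})

test_that("divergent labels and self-clustering mixtures are flagged", {
  pts <- blob_coords(rbind(c(0, 0), c(30, 0)), 40, seed = 6)
  tissues <- setNames(rep(c("A", "B"), each = 40), rownames(pts))
  # five A-labelled samples actually sit in B's blob: divergent
  divergent <- paste0("S-00", 1:5, "-01")
  set.seed(9)
  pts[divergent, ] <- cbind(rnorm(5, 30, 0.5), rnorm(5, 0, 0.5))
  # ten samples midway between the blobs with mixed labels: own cluster
  mid <- matrix(c(rnorm(10, 15, 0.4), rnorm(10, 0, 0.4)), 10, 2)
  rownames(mid) <- sprintf("S-9%02d-01", 1:10)
  pts2 <- rbind(pts, mid)
  tissues2 <- c(tissues, setNames(rep(c("A", "B"), 5), rownames(mid)))
  sw <- louvain_sweep(pts2, k_range = c(25, 30), seed = 3)
  asg <- flag_mixed_and_divergent(sw, tissues2)
  st <- setNames(asg$status, asg$sample_id)
  expect_gte(mean(st[divergent] == "DIVERGENT"), 0.9)
  expect_true(all(st[rownames(mid)] == "MIXED"))
  expect_equal(nrow(asg),
               sum(asg$status == "KEPT") + sum(asg$status != "KEPT"))
})

test_that("tissues sharing one expression cluster are merged", {
  pts <- blob_coords(rbind(c(0, 0), c(0, 0), c(40, 40)), 30, seed = 8)
  tissues <- setNames(rep(c("A", "B", "C"), each = 30), rownames(pts))
  sw <- louvain_sweep(pts, k_range = c(30, 45), seed = 4)
  asg <- flag_mixed_and_divergent(sw, tissues)
  merged <- merge_mixed_tissue_pairs(asg)
  expect_equal(attr(merged, "merges"), list(c("A", "B")))
  expect_true(all(merged$cluster[merged$tissue %in% c("A", "B")] == "A+B"))
  expect_true(all(merged$cluster[merged$tissue == "C"] == "C"))
})

test_that("tsne embedding is deterministic, separates blobs, validates perplexity", {
  pts <- blob_coords(rbind(c(0, 0), c(25, 0), c(0, 25)), 40, sd = 1, seed = 10)
  e1 <- tsne_embed(pts, perplexity = 10, max_iter = 300, seed = 6)
  e2 <- tsne_embed(pts, perplexity = 10, max_iter = 300, seed = 6)
  expect_identical(e1$coords, e2$coords)
  labels <- rep(1:3, each = 40)
  sil <- cluster::silhouette(labels, dist(e1$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(tsne_embed(pts[1:10, ], perplexity = 30), "perplexity")
})

test_that("medoid-kNN flags relocated samples, keeps compact clusters and ties", {
  coords <- rbind(a1 = c(0, 0), a2 = c(1, 0), a3 = c(2, 0), a4 = c(0.5, 1),
                  b1 = c(20, 0), b2 = c(21, 0), b3 = c(22, 0), b4 = c(20.5, 1))
  asg <- data.frame(sample_id = rownames(coords),
                    tissue = rep(c("A", "B"), each = 4),
                    cluster = rep(c("A", "B"), each = 4),
                    status = "KEPT", P = 1, k = 5)
  class(asg) <- c("cluster_assignment", "data.frame")
  emb <- structure(list(coords = coords, params = list()),
                   class = "tsne_embedding")
  out <- medoid_knn_outlier_removal(emb, asg)
  expect_true(all(out$status == "KEPT"))   # untouched clusters: zero flagged
  # relocate one A sample into B territory
  coords2 <- coords; coords2["a4", ] <- c(21.5, 0.5)
  emb2 <- structure(list(coords = coords2, params = list()),
                    class = "tsne_embedding")
  out2 <- medoid_knn_outlier_removal(emb2, asg)
  expect_equal(out2$status[out2$sample_id == "a4"], "TSNE_OUTLIER")
  expect_true(all(out2$status[out2$sample_id != "a4"] == "KEPT"))
  # an exact vote tie keeps the sample
  coords3 <- rbind(a1 = c(0, 0), a2 = c(1, 0), a3 = c(2, 0),
                   b1 = c(8, 0), b2 = c(9, 0), b3 = c(10, 0),
                   p = c(5, 0))
  asg3 <- data.frame(sample_id = rownames(coords3),
                     tissue = c(rep("A", 3), rep("B", 3), "A"),
                     cluster = c(rep("A", 3), rep("B", 3), "A"),
                     status = "KEPT", P = 1, k = 5)
  class(asg3) <- c("cluster_assignment", "data.frame")
  emb3 <- structure(list(coords = coords3, params = list()),
                    class = "tsne_embedding")
  expect_warning(out3 <- medoid_knn_outlier_removal(emb3, asg3), "fewer than 4")
  expect_equal(out3$status[out3$sample_id == "p"], "KEPT")
})

test_that("manual exclusions are applied from a file, never inferred", {
  asg <- data.frame(sample_id = c("s1", "s2", "s3"), tissue = "T",
                    cluster = "T", status = "KEPT", P = 1, k = 5)
  class(asg) <- c("cluster_assignment", "data.frame")
  f <- tempfile(); writeLines(c("s2", ""), f)
  out <- apply_manual_exclusions(asg, f)
  expect_equal(out$status, c("KEPT", "MANUAL", "KEPT"))
})

test_that("end-to-end purification recovers injected outliers at 0.8 precision/recall", {
  cc <- cohort_config(n_tissues = 6, samples_per_tissue = 50, n_genes = 60,
                      seed = 7)
  coh <- inject_outliers(generate_cohort(cc), n_mixed = 6, n_divergent = 4,
                         seed = 11)
  nx <- log_quantile_normalize(coh$expr)
  asg <- suppressWarnings(purify_tissue_clusters(
    nx, setNames(coh$samples$tissue, coh$samples$sample_id),
    k_range = seq(5, 30, by = 5), n_perm = 20, seed = 5))
  inj <- coh$truth$injected$sample_id
  flagged <- asg$sample_id[asg$status != "KEPT"]
  recall <- length(intersect(inj, flagged)) / length(inj)
  precision <- length(intersect(inj, flagged)) / max(1, length(flagged))
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)
  # removal bookkeeping is conserved
  expect_equal(nrow(asg), sum(asg$status == "KEPT") + length(flagged))
})
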