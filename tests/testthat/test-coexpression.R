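kept_map_from <- function(coh) setNames(coh$samples$tissue, coh$samples$sample_id)

test_that("subsample design is deterministic, exhaustive at size 70, strict below", {
  set.seed(1)
  cl <- setNames(rep(c("A", "B"), c(70, 100)), sprintf("S-%03d-01", 1:170))
  d1 <- make_subsample_design(cl, n_per = 70, n_reps = 4, base_seed = 5)
  d2 <- make_subsample_design(cl, n_per = 70, n_reps = 4, base_seed = 5)
  expect_identical(d1, d2)
  # cluster of exactly 70 contributes the same selection in every rep
  selA <- lapply(d1$reps, `[[`, "A")
  expect_true(all(vapply(selA, identical, logical(1), selA[[1]])))
  # larger cluster varies across reps, always 70 unique samples
  selB <- lapply(d1$reps, `[[`, "B")
  expect_true(all(vapply(selB, function(x) length(unique(x)) == 70, logical(1))))
  expect_gt(length(unique(unlist(selB))), 70)
  # undersized cluster: strict errors by name, lenient warns and uses all
  cl2 <- setNames(rep(c("A", "B"), c(69, 100)), sprintf("S-%03d-01", 1:169))
  expect_error(make_subsample_design(cl2, strict = TRUE), "A")
  expect_warning(d3 <- make_subsample_design(cl2, strict = FALSE), "A")
  expect_length(d3$reps[[1]]$A, 69)
})

test_that("correlation metrics behave on canonical inputs", {
  x <- seq(0.1, 3, length.out = 20)
  v <- rbind(x = x, lin = 2 * x + 1, expo = exp(x))
  colnames(v) <- sprintf("S-%02d-01", 1:20)
  p <- correlation_matrix(v, "pearson")$values
  s <- correlation_matrix(v, "spearman")$values
  expect_equal(p["x", "lin"], 1)
  expect_equal(s["x", "expo"], 1)
  expect_lt(p["x", "expo"], 1)
  expect_equal(diag(p), setNames(rep(1, 3), rownames(v)))
  expect_error(correlation_matrix(v[, 1:2]), "3 samples")
  # constant gene zeroed and flagged
  v2 <- rbind(v, flat = rep(2, 20))
  res <- correlation_matrix(v2, "pearson")
  expect_equal(res$flags$constant_genes, "flat")
  expect_true(all(res$values["flat", colnames(res$values) != "flat"] == 0))
})

test_that("zscore modality is invariant to per-cluster constants, tpm is not", {
  coh <- shared_cohort()
  nx <- log_quantile_normalize(coh$expr)
  small <- nx$values[1:10, ]
  cl <- coh$samples$tissue
  shifted <- small
  for (t in unique(cl)) shifted[3, cl == t] <- shifted[3, cl == t] +
    match(t, unique(cl)) * 2
  za <- zscore_by_cluster(expr_matrix(small, "LOG10P1"), cl)
  zb <- zscore_by_cluster(expr_matrix(shifted, "LOG10P1"), cl)
  expect_equal(za$values, zb$values, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cor(t(small))[3, 1], cor(t(shifted))[3, 1])))
  # zero-sd genes are flagged and zeroed
  flat <- small; flat[2, cl == cl[1]] <- 7
  zf <- zscore_by_cluster(expr_matrix(flat, "LOG10P1"), cl)
  expect_true(all(zf$values[2, cl == cl[1]] == 0))
  expect_true(rownames(small)[2] %in% attr(zf, "zero_sd")[[cl[1]]])
})

test_that("opposite within-cluster slopes with shared cluster means split the modalities", {
  set.seed(8)
  n <- 120
  cl <- rep(c("A", "B"), each = n)
  x <- c(rnorm(n), rnorm(n) + 10)
  y <- c(x[1:n] + rnorm(n, 0, 0.3), 10 - (x[n + 1:n] - 10) + rnorm(n, 0, 0.3))
  v <- rbind(gx = x, gy = y)
  colnames(v) <- sprintf("S-%03d-01", seq_len(2 * n))
  tpm_r <- cor(x, y)
  z <- zscore_by_cluster(expr_matrix(v - min(v), "LOG10P1"), cl)
  z_r <- cor(z$values["gx", ], z$values["gy", ])
  expect_gt(tpm_r, 0.9)
  expect_lt(abs(z_r), 0.15)
})

test_that("estimate_all validates modality/scale and reduces to correlation_matrix", {
  coh <- shared_cohort()
  nx <- log_quantile_normalize(coh$expr)
  small <- expr_matrix(nx$values[1:8, ], "LOG10P1")
  cl <- kept_map_from(coh)
  des <- make_subsample_design(cl, n_per = 50, n_reps = 1, base_seed = 2)
  expect_error(estimate_all(small, des, metrics = "pearson", modality = "zscore"),
               "ZSCORE")
  res <- estimate_all(small, des, metrics = "pearson", modality = "tpm")
  expect_length(res, 1)
  ids <- unlist(des$reps[[1]], use.names = FALSE)
  direct <- correlation_matrix(small$values[, ids], "pearson")
  expect_equal(res[[1]]$values, direct$values)
  # determinism
  res2 <- estimate_all(small, des, metrics = "pearson", modality = "tpm")
  expect_identical(res[[1]]$values, res2[[1]]$values)
})

test_that("minimum aggregation keeps the weakest magnitude with its sign", {
  mk <- function(val) {
    m <- matrix(c(1, val, val, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    coex_result(m, "pearson", "tpm", "per_rep")
  }
  expect_equal(aggregate_minimum(list(mk(0.9), mk(0.8), mk(0.85)))$values["a", "b"], 0.8)
  expect_equal(aggregate_minimum(list(mk(-0.9), mk(-0.7)))$values["a", "b"], -0.7)
  res <- aggregate_minimum(list(mk(0.5), mk(-0.4)))
  expect_equal(res$values["a", "b"], -0.4)
  expect_true(res$flags$sign_disagreement["a", "b"])
  # raw signed minimum as an option
  expect_equal(aggregate_minimum(list(mk(0.5), mk(-0.4)),
                                 raw_signed = TRUE)$values["a", "b"], -0.4)
  expect_equal(aggregate_minimum(list(mk(0.5), mk(0.4)),
                                 raw_signed = TRUE)$values["a", "b"], 0.4)
  expect_error(aggregate_minimum(list(mk(0.5),
    coex_result(mk(0.5)$values, "spearman", "tpm", "per_rep"))), "mixed")
})

test_that("the minimum matrix is dominated in magnitude by every replicate", {
  coh <- shared_cohort()
  nx <- log_quantile_normalize(coh$expr)
  small <- expr_matrix(nx$values[1:15, ], "LOG10P1")
  des <- make_subsample_design(kept_map_from(coh), n_per = 40, n_reps = 5,
                               base_seed = 9)
  for (metric in c("pearson", "g")) {
    per_rep <- estimate_all(small, des, metrics = metric, modality = "tpm")
    mn <- aggregate_minimum(per_rep)
    for (r in per_rep) {
      off <- upper.tri(mn$values)
      if (metric == "g") {
        expect_true(all(mn$values[off] <= r$values[off] + 1e-12))
      } else {
        expect_true(all(abs(mn$values[off]) <= abs(r$values[off]) + 1e-12))
      }
    }
  }
})

test_that("covariate strata follow the stated boundaries", {
  samples <- data.frame(
    sample_id = paste0("s", 1:7), subject_id = paste0("u", 1:7),
    tissue = "T", extraction_batch = "b", sequencing_batch = "b",
    sex = c("male", "female", "male", "female", "male", "female", "male"),
    age = c(30, 55, 70, 50, 59, 49, 60),
    ischemia_time = c(10, 12, 300, 310, 11, 305, 12))
  st <- covariate_strata(samples)
  expect_setequal(st$age_lt50, c("s1", "s6"))
  expect_setequal(st$age_50_59, c("s2", "s4", "s5"))  # 50 and 59 inclusive
  expect_setequal(st$age_gt59, c("s3", "s7"))
  expect_setequal(st$ischemia_low, c("s1", "s2", "s5", "s7"))
  expect_setequal(st$ischemia_high, c("s3", "s4", "s6"))
  # strata partition the samples within each covariate
  expect_setequal(c(st$sex_male, st$sex_female), samples$sample_id)
  expect_setequal(c(st$age_lt50, st$age_50_59, st$age_gt59), samples$sample_id)
})

test_that("2-means ischemia split separates the two regimes", {
  sp <- split_ischemia_2means(c(10, 12, 300, 310))
  expect_equal(as.character(sp$level), c("low", "low", "high", "high"))
  expect_true(sp$boundary > 12 && sp$boundary < 300)
  sp2 <- split_ischemia_2means(c(NA, 5, 5, 900))
  expect_true(is.na(sp2$level[1]))
})

test_that("stratified estimation yields one matrix per stratum and modality", {
  coh <- shared_cohort()
  nx <- log_quantile_normalize(coh$expr)
  small <- expr_matrix(nx$values[1:8, ], "LOG10P1")
  suppressWarnings(
    st <- stratify_covariates(small, coh$samples, kept_map_from(coh),
                              n_per = 20, base_seed = 3))
  expect_length(st$results, 14)   # 7 strata x 2 modalities
  expect_s3_class(st$results[["sex_male.tpm"]], "coex_result")
  expect_equal(st$results[["age_lt50.zscore"]]$modality, "zscore")
  expect_equal(st$results[["age_lt50.zscore"]]$stratum, "age_lt50")
})

test_that("matrix inventory reproduces the configured counts", {
  inv <- matrix_inventory()
  expect_equal(inv$total, 140)
  expect_equal(unname(inv$counts), c(120, 14, 6))
  expect_equal(matrix_inventory(n_reps = 1, n_metrics = 1, n_modalities = 1,
                                n_strata = 0)$total, 2)
  expect_equal(matrix_inventory(n_strata = 0)$total, 126)
})
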