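test_that("low-expression filter counts and boundaries follow the inclusive rule", {
  expect_identical(required_expressed_samples(16651, 0.20), 3331L)
  # 10 samples -> required count 2
  v <- rbind(all_zero = rep(0, 10),
             at_threshold = c(0.1, 0.1, rep(0, 8)),
             below = c(0.1, 0.09, rep(0, 8)),
             high = rep(5, 10))
  colnames(v) <- sprintf("S-%02d-01", 1:10)
  ex <- expr_matrix(v, "TPM")
  rep <- filter_low_expressed(ex)
  expect_equal(attr(rep, "required_count"), 2L)
  st <- setNames(rep$status, rep$gene_id)
  expect_equal(st[["all_zero"]], "FAIL")
  expect_equal(st[["at_threshold"]], "PASS")   # inclusive "at least"
  expect_equal(st[["below"]], "FAIL")
  expect_equal(st[["high"]], "PASS")
})

test_that("tissue-specific rescue requires both conditions strictly", {
  tissues <- rep(c("A", "B"), each = 10)
  mk <- function(a_vals, b_vals) {
    v <- matrix(c(a_vals, b_vals), nrow = 1)
    colnames(v) <- sprintf("S-%02d-01", 1:20); rownames(v) <- "g"
    expr_matrix(v, "TPM")
  }
  # 10 TPM mean and 80% expressed in tissue A, silent in B -> rescued
  ex <- mk(c(rep(12, 8), 1e-3, 1e-3), rep(1e-3, 10))
  expect_identical(rescue_tissue_specific(ex, tissues, "g"), "g")
  # max mean only 4 TPM -> not rescued
  ex <- mk(rep(4, 10), rep(1e-3, 10))
  expect_length(rescue_tissue_specific(ex, tissues, "g"), 0)
  # mean 8 TPM but only 50% of samples at 1 TPM anywhere -> not rescued
  ex <- mk(c(rep(16, 5), rep(1e-3, 5)), rep(1e-3, 10))
  expect_length(rescue_tissue_specific(ex, tissues, "g"), 0)
  # unknown gene id
  expect_error(rescue_tissue_specific(ex, tissues, "nope"), "nope")
})

test_that("filter + rescue is a disjoint union and idempotent", {
  coh <- shared_cohort()
  f1 <- apply_gene_filter(coh$expr, coh$samples$tissue)
  st <- f1$report$status
  expect_setequal(unique(st), intersect(c("PASS", "FAIL", "RESCUED"), st))
  expect_equal(sum(st == "PASS") + sum(st == "RESCUED"), nrow(f1$expr$values))
  expect_equal(length(st), nrow(coh$expr$values))
  f2 <- apply_gene_filter(f1$expr, coh$samples$tissue)
  expect_identical(sort(gene_ids(f2$expr)), sort(gene_ids(f1$expr)))
})

test_that("quantile normalization matches the sorted-means oracle", {
  # two already-logged samples collapse onto the sorted means
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
  # random matrices with ties
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(sample(1:6, 48, replace = TRUE) / 2, 8, 6,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
    expect_equal(quantile_normalize(m), qn_oracle(m), tolerance = 1e-12)
  }
  # single sample unchanged
  one <- m[, 1, drop = FALSE]
  expect_identical(quantile_normalize(one), one)
})

test_that("after normalization every sample has the same sorted values and ranks are preserved", {
  coh <- shared_cohort()
  nx <- log_quantile_normalize(coh$expr)
  v <- nx$values
  ref <- sort(v[, 1])
  for (j in seq(2, ncol(v), by = 97))
    expect_equal(unname(sort(v[, j])), unname(ref))
  L <- log10(coh$expr$values + 1)
  for (j in c(1, 50))
    expect_equal(order(v[, j]), order(L[, j]))
  expect_equal(nx$scale, "LOG10P1")
  expect_error(log_quantile_normalize(nx), "scale")
})

test_that("combat collapses a pure additive batch shift", {
  # batch 2 is an exact copy of batch 1 plus a constant; empirical-Bayes
  # shrinkage pools per-gene estimates, so equalization is strong but not
  # exact gene-by-gene — asserted at the level the estimator delivers
  set.seed(7)
  n <- 200
  half <- matrix(rnorm(40 * n, 5), 40, n)
  v <- cbind(half, half + 0.7)
  dimnames(v) <- list(paste0("g", 1:40), sprintf("S-%03d-01", 1:(2 * n)))
  ex <- expr_matrix(v, "LOG10P1")
  samples <- data.frame(sample_id = colnames(v),
                        subject_id = colnames(v),
                        tissue = "T", sex = "male", age = 50,
                        extraction_batch = rep(c("b1", "b2"), each = n),
                        sequencing_batch = "s1",
                        ischemia_time = 0)
  out <- combat_serial(ex, samples, preserve = character(0))
  d <- abs(rowMeans(out$values[, 1:n]) - rowMeans(out$values[, n + (1:n)]))
  expect_lt(mean(d), 0.7 / 20)
  expect_lt(max(d), 0.7 / 10)
})

test_that("combat is the identity with a single batch and gentle without batch effects", {
  coh0 <- generate_cohort(cohort_config(n_tissues = 4, samples_per_tissue = 40,
                                        n_genes = 60, batch_shift_sd = 0,
                                        n_batches_extraction = 1,
                                        n_batches_sequencing = 1, seed = 13))
  nx <- log_quantile_normalize(coh0$expr)
  out <- combat_serial(nx, coh0$samples)
  expect_identical(out$values, nx$values)   # single batch: no adjustment
  # several batch labels but zero injected effect: perturbation well under
  # a tenth of the within-tissue noise
  coh1 <- generate_cohort(cohort_config(n_tissues = 4, samples_per_tissue = 40,
                                        n_genes = 60, batch_shift_sd = 0,
                                        seed = 13))
  nx1 <- log_quantile_normalize(coh1$expr)
  out1 <- combat_serial(nx1, coh1$samples)
  expect_lt(mean(abs(out1$values - nx1$values)),
            coh1$truth$within_tissue_sd / 10)
})

test_that("combat shrinks planted batch effects by an order of magnitude", {
  coh <- generate_cohort(cohort_config(n_tissues = 4, samples_per_tissue = 100,
                                       n_genes = 80, batch_shift_sd = 0.4,
                                       n_batches_extraction = 2,
                                       n_batches_sequencing = 2, seed = 17))
  nx <- log_quantile_normalize(coh$expr)
  out <- combat_serial(nx, coh$samples)
  batch_effect <- function(v) {
    # residual batch means after removing per-tissue gene means
    res <- v
    for (t in unique(coh$samples$tissue)) {
      j <- coh$samples$tissue == t
      res[, j] <- v[, j] - rowMeans(v[, j, drop = FALSE])
    }
    eff <- 0; nb <- 0
    for (b in unique(coh$samples$extraction_batch)) {
      j <- coh$samples$extraction_batch == b
      eff <- eff + sum(abs(rowMeans(res[, j, drop = FALSE]))); nb <- nb + 1
    }
    eff / (nb * nrow(v))
  }
  before <- batch_effect(nx$values)
  after <- batch_effect(out$values)
  expect_gte(before / after, 10)
})

test_that("a batch confounded with a preserved covariate is refused by name", {
  v <- matrix(rnorm(40, 5), 4, 10,
              dimnames = list(paste0("g", 1:4), sprintf("S-%02d-01", 1:10)))
  samples <- data.frame(sample_id = colnames(v), subject_id = colnames(v),
                        tissue = rep(c("A", "B"), each = 5),
                        sex = "male", age = 50,
                        extraction_batch = rep(c("b1", "b2"), each = 5),
                        sequencing_batch = "s1", ischemia_time = 0)
  ex <- expr_matrix(v, "LOG10P1")
  expect_error(combat_serial(ex, samples), "extraction_batch.*tissue")
})

test_that("placeholder pooling covers missing and singleton batches", {
  b <- c("x", "x", "y", NA, "z", "z")
  out <- assign_placeholder(b)
  expect_equal(out[4], ".placeholder")
  expect_equal(out[3], ".placeholder")   # singleton batch y pooled
  expect_true(all(table(out) >= 2))
})
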