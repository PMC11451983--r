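#' Flag low-expressed genes
#'
#' A gene passes when it reaches `tpm_min` TPM in at least
#' `ceiling(frac_samples * n_samples)` samples ("at least" is inclusive, and
#' the required count uses the ceiling, so 20% of 16,651 samples is 3,331).
#'
#' @param expr an [expr_matrix()] on the TPM scale.
#' @param tpm_min expression threshold, TPM.
#' @param frac_samples required fraction of samples at or above `tpm_min`.
#' @return a `gene_filter_report` data.frame (`gene_id`, `n_expressed`,
#'   `status` PASS/FAIL) with attributes `thresholds` and `required_count`.
#' @export
filter_low_expressed <- function(expr, tpm_min = 0.1, frac_samples = 0.20) {
  check_scale(expr, "TPM")
  v <- expr$values
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty expression matrix", call. = FALSE)
  required <- required_expressed_samples(ncol(v), frac_samples)
  n_exp <- rowSums(v >= tpm_min)
  rep <- data.frame(gene_id = rownames(v), n_expressed = n_exp,
                    status = ifelse(n_exp >= required, "PASS", "FAIL"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(rep, class = c("gene_filter_report", "data.frame"),
            thresholds = list(tpm_min = tpm_min, frac_samples = frac_samples),
            required_count = required)
}

#' @rdname filter_low_expressed
#' @param n_samples total sample count.
#' @export
required_expressed_samples <- function(n_samples, frac_samples = 0.20) {
  as.integer(ceiling(frac_samples * n_samples))
}

#' Rescue tissue-specific genes from the low-expression filter
#'
#' A gene that failed the global filter only because it is expressed in few
#' tissues is rescued when its maximum per-tissue mean TPM exceeds
#' `rescue_mean_tpm` AND its maximum per-tissue fraction of samples at
#' `rescue_tpm` or more exceeds `rescue_frac` (both strictly "greater
#' than"). By default the two maxima may come from different tissues;
#' `same_tissue = TRUE` requires one tissue to satisfy both.
#'
#' @param expr TPM [expr_matrix()].
#' @param tissues per-sample tissue labels (aligned with the columns).
#' @param failed_genes gene ids to evaluate (typically the FAIL set of
#'   [filter_low_expressed()]).
#' @param rescue_mean_tpm,rescue_frac,rescue_tpm thresholds (defaults 5 TPM,
#'   66%, 1 TPM).
#' @param same_tissue require both conditions in a single tissue.
#' @return character vector of rescued gene ids.
#' @export
rescue_tissue_specific <- function(expr, tissues, failed_genes,
                                   rescue_mean_tpm = 5, rescue_frac = 0.66,
                                   rescue_tpm = 1, same_tissue = FALSE) {
  check_scale(expr, "TPM")
  stopifnot(length(tissues) == ncol(expr$values))
  unknown <- setdiff(failed_genes, gene_ids(expr))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!length(failed_genes)) return(character(0))
  v <- expr$values[failed_genes, , drop = FALSE]
  tiss <- unique(tissues)
  means <- sapply(tiss, function(t) rowMeans(v[, tissues == t, drop = FALSE]))
  fracs <- sapply(tiss, function(t) rowMeans(v[, tissues == t, drop = FALSE] >= rescue_tpm))
  means <- matrix(means, nrow = length(failed_genes))
  fracs <- matrix(fracs, nrow = length(failed_genes))
  if (same_tissue) {
    ok <- rowSums(means > rescue_mean_tpm & fracs > rescue_frac) > 0
  } else {
    ok <- apply(means, 1, max) > rescue_mean_tpm & apply(fracs, 1, max) > rescue_frac
  }
  failed_genes[ok]
}

#' Filter genes with the tissue-specific rescue rule
#'
#' Convenience wrapper: runs [filter_low_expressed()], then
#' [rescue_tissue_specific()] on the failures, and returns the retained
#' matrix (PASS plus RESCUED, in the input gene order) together with the full
#' per-gene report.
#'
#' @inheritParams rescue_tissue_specific
#' @param ... passed to the two stages.
#' @return list with `expr` (retained [expr_matrix()]) and `report`
#'   (statuses PASS / FAIL / RESCUED).
#' @export
apply_gene_filter <- function(expr, tissues, tpm_min = 0.1, frac_samples = 0.20,
                              ...) {
  rep <- filter_low_expressed(expr, tpm_min, frac_samples)
  failed <- rep$gene_id[rep$status == "FAIL"]
  rescued <- rescue_tissue_specific(expr, tissues, failed, ...)
  rep$status[rep$gene_id %in% rescued] <- "RESCUED"
  keep <- rep$gene_id[rep$status != "FAIL"]
  list(expr = subset_expr(expr, keep), report = rep)
}

#' Quantile-normalize a matrix across samples
#'
#' Each sample's sorted values are replaced by the mean of the sorted values
#' across samples; ties receive the mean of the reference values they span
#' (delegated to `limma::normalizeQuantiles(ties = TRUE)`).
#'
#' @param m numeric matrix, samples in columns.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' log10(TPM + 1) transform followed by quantile normalization
#'
#' @param expr TPM [expr_matrix()].
#' @return an [expr_matrix()] on the `LOG10P1` scale in which every sample
#'   carries the same sorted value vector.
#' @export
log_quantile_normalize <- function(expr) {
  check_scale(expr, "TPM")
  if (any(expr$values < 0)) stop("negative TPM input", call. = FALSE)
  L <- log10(expr$values + 1)
  expr_matrix(quantile_normalize(L), "LOG10P1", expr$description)
}

#' Serial empirical-Bayes batch correction
#'
#' Runs parametric ComBat (location/scale adjustment, `sva::ComBat`) once for
#' the extraction batch and then again for the sequencing batch, preserving
#' tissue, sex and age effects through the model matrix. Samples with a
#' missing batch label, or in a batch with fewer than two samples, are first
#' pooled into one shared placeholder batch per batch variable. A batch
#' variable with a single level after placeholder assignment is skipped (the
#' data pass through unchanged). Genes with zero variance are excluded from
#' the adjustment and passed through with a warning.
#'
#' @param expr [expr_matrix()] on the `LOG10P1` scale.
#' @param samples `sample_table` aligned with the columns of `expr`.
#' @param preserve covariate columns to protect (categorical or numeric).
#' @param placeholder label used for the pooled placeholder batch.
#' @return corrected [expr_matrix()], same scale.
#' @export
combat_serial <- function(expr, samples,
                          preserve = c("tissue", "sex", "age"),
                          placeholder = ".placeholder") {
  check_scale(expr, "LOG10P1")
  stopifnot(nrow(samples) == ncol(expr$values))
  mod <- preserve_model_matrix(samples, preserve)
  v <- expr$values
  for (bv in c("extraction_batch", "sequencing_batch")) {
    batch <- assign_placeholder(samples[[bv]], placeholder)
    if (length(unique(batch)) < 2) next
    check_confounding(batch, samples, preserve, bv)
    sds <- apply(v, 1, sd)
    flat <- sds == 0
    if (any(flat))
      warning(sum(flat), " zero-variance gene(s) passed through ", bv, " correction")
    act <- v[!flat, , drop = FALSE]
    log <- utils::capture.output(
      adj <- suppressMessages(
        sva::ComBat(dat = act, batch = batch, mod = mod, par.prior = TRUE,
                    prior.plots = FALSE)))
    v[!flat, ] <- adj
  }
  expr_matrix(v, "LOG10P1", expr$description)
}

#' @rdname combat_serial
#' @param batch raw batch labels (character, `NA` allowed).
#' @export
assign_placeholder <- function(batch, placeholder = ".placeholder") {
  batch <- as.character(batch)
  batch[is.na(batch)] <- placeholder
  tab <- table(batch)
  single <- names(tab)[tab < 2]
  batch[batch %in% setdiff(single, placeholder)] <- placeholder
  # the placeholder itself may still be a singleton; merge it into the
  # largest batch rather than leave a 1-sample batch
  tab <- table(batch)
  if (!is.na(tab[placeholder]) && tab[placeholder] == 1 && length(tab) > 1) {
    batch[batch == placeholder] <- names(which.max(tab[names(tab) != placeholder]))
  }
  batch
}

preserve_model_matrix <- function(samples, preserve) {
  if (!length(preserve)) return(NULL)
  miss <- setdiff(preserve, names(samples))
  if (length(miss))
    stop("preserve covariate(s) not in sample table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- samples[preserve]
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  # drop covariates with a single level (no effect to preserve)
  keep <- vapply(df, function(x) !is.factor(x) || nlevels(droplevels(x)) > 1,
                 logical(1))
  df <- df[keep]
  if (!ncol(df)) return(NULL)
  model.matrix(~ ., data = df)
}

check_confounding <- function(batch, samples, preserve, batch_name) {
  bmat <- model.matrix(~ 0 + factor(batch))
  for (nm in preserve) {
    x <- samples[[nm]]
    if (!is.character(x) && !is.factor(x)) next
    x <- droplevels(factor(x))
    if (nlevels(x) < 2) next
    cmat <- model.matrix(~ 0 + x)
    full <- cbind(1, bmat[, -1, drop = FALSE], cmat[, -1, drop = FALSE])
    if (qr(full)$rank < ncol(full))
      stop(sprintf("batch variable '%s' is perfectly confounded with covariate '%s'",
                   batch_name, nm), call. = FALSE)
  }
  invisible(TRUE)
}
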