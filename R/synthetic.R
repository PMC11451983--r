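#' Configure a synthetic multi-tissue cohort
#'
#' Describes a GTEx-like cohort: several tissues with distinct per-gene mean
#' expression profiles, log-normal noise, two nested multiplicative batch
#' effects (additive on the log10 scale), a fraction of tissue-specific
#' genes, per-subject covariates, and planted gene pairs realizing the
#' canonical coexpression scenarios (see [planted_pair()]).
#'
#' Defaults are chosen to mimic the qualitative structure of a multi-tissue
#' bulk RNA-seq compendium at desk scale: between-tissue spread of gene means
#' (`tissue_mean_sd`, log10 units) well above within-tissue noise
#' (`within_tissue_sd`), and batch shifts (`batch_shift_sd`) detectable but
#' not dominant.
#'
#' @param n_tissues number of tissues.
#' @param samples_per_tissue scalar or per-tissue vector of sample counts.
#' @param n_genes number of genes.
#' @param n_batches_extraction,n_batches_sequencing numbers of batch levels,
#'   assigned to samples uniformly at random (so batches cut across tissues).
#' @param batch_shift_sd sd of per-gene-per-batch additive shifts on log10.
#' @param within_tissue_sd sd of within-tissue residual noise on log10.
#' @param tissue_mean_sd sd of per-gene tissue-mean profiles around the gene
#'   baseline, log10 units.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log10
#'   expression.
#' @param fraction_tissue_specific fraction of genes expressed essentially in
#'   a single home tissue (high there, near zero elsewhere).
#' @param n_residual_factors number of latent within-tissue factors loaded by
#'   background genes, giving the cohort a realistic backbone of
#'   tissue-level coexpression (real transcriptomes are pervasively
#'   co-regulated; without this, any nonzero within-tissue correlation would
#'   be extreme relative to the background).
#' @param residual_factor_sd loading scale of those factors, as a fraction of
#'   `within_tissue_sd`.
#' @param planted_pairs a data.frame from [planted_pair()], or NULL.
#' @param seed root seed; every stream of randomness derives from it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_tissues = 10, samples_per_tissue = 90,
                          n_genes = 300,
                          n_batches_extraction = 4, n_batches_sequencing = 3,
                          batch_shift_sd = 0.15, within_tissue_sd = 0.25,
                          tissue_mean_sd = 0.6,
                          baseline_mean = 1.0, baseline_sd = 0.5,
                          fraction_tissue_specific = 0.1,
                          n_residual_factors = 3, residual_factor_sd = 0.5,
                          planted_pairs = NULL, seed = 1L) {
  spt <- rep_len(samples_per_tissue, n_tissues)
  stopifnot(n_tissues >= 1, all(spt >= 1), n_genes >= 2,
            n_batches_extraction >= 1, n_batches_sequencing >= 1,
            batch_shift_sd >= 0, within_tissue_sd > 0, tissue_mean_sd >= 0,
            fraction_tissue_specific >= 0, fraction_tissue_specific <= 1)
  structure(list(
    n_tissues = n_tissues, samples_per_tissue = spt, n_genes = n_genes,
    n_batches_extraction = n_batches_extraction,
    n_batches_sequencing = n_batches_sequencing,
    batch_shift_sd = batch_shift_sd, within_tissue_sd = within_tissue_sd,
    tissue_mean_sd = tissue_mean_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    fraction_tissue_specific = fraction_tissue_specific,
    n_residual_factors = n_residual_factors,
    residual_factor_sd = residual_factor_sd,
    planted_pairs = planted_pairs, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Declare planted coexpression scenarios
#'
#' Each scenario fixes the generative rule linking the pair on the log10
#' scale:
#' * `SYS_ONLY` — the two genes share one (widened) tissue-mean profile but
#'   have independent within-tissue residuals: coexpressed at the system
#'   level only.
#' * `SYS_POS` — shared profile plus mildly correlated residuals; a generic
#'   positive system-level association.
#' * `TISSUE_ONLY` — independent tissue-mean profiles but correlated
#'   within-tissue residuals: coexpressed at the tissue level only.
#' * `BOTH` — shared profile and strongly correlated residuals.
#' * `XOR` — mutually exclusive expression: each gene is "on" in its own
#'   disjoint set of tissues and both are "off" elsewhere, residuals
#'   independent; linear metrics see little, the G-statistic much.
#' * `NONLINEAR` — the second gene follows a monotone saturating function of
#'   the first.
#' * `TISSUE_EXCEPTION` — linear relation shared across tissues except one
#'   tissue where the second gene is offset.
#' * `NULL_PAIR` — the pair is generated independently (background).
#'
#' @param gene_a,gene_b 1-based gene indices into the cohort.
#' @param scenario one of the scenario codes above.
#' @param effect_size strength in `[0, 1]`: residual correlation where the
#'   scenario uses one, and the relative widening of shared profiles.
#' @return a data.frame, rows concatenable with `rbind()`.
#' @export
planted_pair <- function(gene_a, gene_b,
                         scenario = c("SYS_ONLY", "SYS_POS", "TISSUE_ONLY",
                                      "BOTH", "XOR", "NONLINEAR",
                                      "TISSUE_EXCEPTION", "NULL_PAIR"),
                         effect_size = 0.9) {
  scenario <- match.arg(scenario)
  stopifnot(gene_a != gene_b, effect_size >= 0, effect_size <= 1)
  data.frame(gene_a = gene_a, gene_b = gene_b, scenario = scenario,
             effect_size = effect_size, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic given `config$seed`: all internal streams are derived with
#' [child_seed()]. Emits raw TPM values (`10^log10value`, so strictly
#' positive), a [read_sample_attributes()]-compatible sample table, and a
#' ground-truth record holding the true tissue of every sample, per-gene
#' tissue-specificity, the planted pairs with their realized population-level
#' correlations in both modalities, the injected batch shifts, and the
#' tissue-mean profiles.
#'
#' @param config a [cohort_config()].
#' @return list with elements `expr` ([expr_matrix()], scale TPM), `samples`
#'   (`sample_table`), `truth` (list).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  tissues <- sprintf("T%02d", seq_len(cf$n_tissues))
  genes <- sprintf("G%04d", seq_len(cf$n_genes))
  n_total <- sum(cf$samples_per_tissue)

  if (!is.null(cf$planted_pairs)) {
    idx <- c(cf$planted_pairs$gene_a, cf$planted_pairs$gene_b)
    if (any(idx < 1 | idx > cf$n_genes))
      stop("planted gene index out of range (n_genes = ", cf$n_genes, ")",
           call. = FALSE)
  }

  # samples: subject j donates at most one sample per tissue
  tissue_of <- rep(tissues, cf$samples_per_tissue)
  subj_idx <- unlist(lapply(cf$samples_per_tissue, seq_len))
  subject_id <- sprintf("SYN-%04d", subj_idx)
  sample_id <- sprintf("%s-%02d%02d", subject_id, match(tissue_of, tissues), 1L)

  # gene baselines and tissue-mean profiles
  set.seed(child_seed(cf$seed, 1))
  base <- rnorm(cf$n_genes, cf$baseline_mean, cf$baseline_sd)
  mu <- base + matrix(rnorm(cf$n_genes * cf$n_tissues, 0, cf$tissue_mean_sd),
                      cf$n_genes, cf$n_tissues)
  dimnames(mu) <- list(genes, tissues)

  # tissue-specific genes: on in one home tissue, near-silent elsewhere;
  # planted pairs are reserved so a scenario's profile is never overwritten
  set.seed(child_seed(cf$seed, 2))
  planted_idx <- if (!is.null(cf$planted_pairs))
    c(cf$planted_pairs$gene_a, cf$planted_pairs$gene_b) else integer(0)
  ts_pool <- setdiff(seq_len(cf$n_genes), planted_idx)
  n_ts <- min(round(cf$fraction_tissue_specific * cf$n_genes), length(ts_pool))
  ts_genes <- if (n_ts > 0) sort(sample(ts_pool, n_ts)) else integer(0)
  home <- rep(NA_character_, cf$n_genes)
  if (n_ts > 0) {
    home_idx <- sample.int(cf$n_tissues, n_ts, replace = TRUE)
    home[ts_genes] <- tissues[home_idx]
    for (i in seq_along(ts_genes)) {
      g <- ts_genes[i]
      mu[g, ] <- -1.5
      mu[g, home_idx[i]] <- base[g] + 1.5
    }
  }

  # covariates (per subject) and per-sample batches
  set.seed(child_seed(cf$seed, 3))
  n_subj <- max(cf$samples_per_tissue)
  subj_sex <- sample(c("male", "female"), n_subj, replace = TRUE)
  subj_age <- sample(20:79, n_subj, replace = TRUE)
  ischemia <- round(runif(n_total, 0, 1500))
  set.seed(child_seed(cf$seed, 4))
  eb <- sprintf("EB%02d", sample.int(cf$n_batches_extraction, n_total, replace = TRUE))
  sb <- sprintf("SB%02d", sample.int(cf$n_batches_sequencing, n_total, replace = TRUE))
  shift_ext <- matrix(rnorm(cf$n_genes * cf$n_batches_extraction, 0, cf$batch_shift_sd),
                      cf$n_genes, cf$n_batches_extraction,
                      dimnames = list(genes, sprintf("EB%02d", seq_len(cf$n_batches_extraction))))
  shift_seq <- matrix(rnorm(cf$n_genes * cf$n_batches_sequencing, 0, cf$batch_shift_sd),
                      cf$n_genes, cf$n_batches_sequencing,
                      dimnames = list(genes, sprintf("SB%02d", seq_len(cf$n_batches_sequencing))))

  # within-tissue residuals, plus a latent-factor backbone of co-regulation
  # among background genes (planted genes are left out of the loadings so
  # each scenario realizes exactly its own generative rule)
  set.seed(child_seed(cf$seed, 5))
  eps <- matrix(rnorm(cf$n_genes * n_total, 0, cf$within_tissue_sd),
                cf$n_genes, n_total)
  if (cf$n_residual_factors > 0 && cf$residual_factor_sd > 0) {
    lam <- matrix(rnorm(cf$n_genes * cf$n_residual_factors, 0,
                        cf$residual_factor_sd * cf$within_tissue_sd),
                  cf$n_genes, cf$n_residual_factors)
    lam[planted_idx, ] <- 0
    fac <- matrix(rnorm(cf$n_residual_factors * n_total),
                  cf$n_residual_factors, n_total)
    eps <- eps + lam %*% fac
  }

  # planted pairs override profiles and residuals
  set.seed(child_seed(cf$seed, 6))
  pp <- cf$planted_pairs
  if (!is.null(pp)) for (i in seq_len(nrow(pp))) {
    a <- pp$gene_a[i]; b <- pp$gene_b[i]
    e <- pp$effect_size[i]; sc <- pp$scenario[i]
    mix <- function(rho) {
      eps[b, ] <<- rho * eps[a, ] +
        sqrt(max(0, 1 - rho^2)) * rnorm(n_total, 0, cf$within_tissue_sd)
    }
    shared_profile <- function(widen) {
      prof <- base[a] + rnorm(cf$n_tissues, 0, cf$tissue_mean_sd * (1 + widen))
      mu[a, ] <<- prof; mu[b, ] <<- prof
    }
    if (sc == "SYS_ONLY") {
      shared_profile(e)
    } else if (sc == "SYS_POS") {
      shared_profile(e); mix(0.5 * e)
    } else if (sc == "TISSUE_ONLY") {
      # tissue-level-only coexpression: correlated residuals, and the
      # partner's tissue-mean profile drawn orthogonal to the first gene's
      # so no system-level association arises by profile alignment
      da <- mu[a, ] - base[a]
      db <- rnorm(cf$n_tissues, 0, cf$tissue_mean_sd)
      if (sum(da^2) > 0) db <- db - sum(db * da) / sum(da^2) * da
      if (sd(db) > 0) db <- db / sd(db) * cf$tissue_mean_sd
      mu[b, ] <- base[b] + db
      mix(e)
    } else if (sc == "BOTH") {
      shared_profile(e); mix(e)
    } else if (sc == "XOR") {
      n_on <- max(1L, floor(cf$n_tissues / 3))
      on_a <- seq_len(n_on); on_b <- n_on + seq_len(n_on)
      lo <- cf$baseline_mean - 1.5 * (0.5 + e)
      hi <- cf$baseline_mean + 1.5 * (0.5 + e)
      mu[a, ] <- lo; mu[a, on_a] <- hi
      mu[b, ] <- lo; mu[b, on_b] <- hi
    } else if (sc == "NONLINEAR") {
      # realized below, once gene a's signal exists
    } else if (sc == "TISSUE_EXCEPTION") {
      shared_profile(e); mix(e)
      exc <- sample.int(cf$n_tissues, 1)
      mu[b, exc] <- mu[b, exc] + 2.5
      pp$exception_tissue <- pp$exception_tissue %||% rep(NA_character_, nrow(pp))
      pp$exception_tissue[i] <- tissues[exc]
    }
  }

  tissue_col <- match(tissue_of, tissues)
  L <- mu[, tissue_col, drop = FALSE] + eps
  dimnames(L) <- list(genes, sample_id)

  # saturating link for NONLINEAR pairs needs gene a's full signal
  if (!is.null(pp)) for (i in seq_len(nrow(pp))) {
    if (pp$scenario[i] != "NONLINEAR") next
    a <- pp$gene_a[i]; b <- pp$gene_b[i]; e <- pp$effect_size[i]
    width <- 0.35 * max(cf$tissue_mean_sd, cf$within_tissue_sd)
    L[b, ] <- base[b] + (1 + e) * tanh((L[a, ] - base[a]) / width) +
      rnorm(n_total, 0, 0.3 * cf$within_tissue_sd)
  }

  L_batched <- L + shift_ext[, match(eb, colnames(shift_ext)), drop = FALSE] +
    shift_seq[, match(sb, colnames(shift_seq)), drop = FALSE]

  expr <- expr_matrix(10^L_batched, "TPM")
  samples <- data.frame(
    sample_id = sample_id, subject_id = subject_id, tissue = tissue_of,
    extraction_batch = eb, sequencing_batch = sb,
    sex = subj_sex[subj_idx], age = subj_age[subj_idx],
    ischemia_time = ischemia, stringsAsFactors = FALSE)
  class(samples) <- c("sample_table", "data.frame")

  truth <- list(
    tissue = setNames(tissue_of, sample_id),
    genes = data.frame(gene_id = genes,
                       tissue_specific = seq_len(cf$n_genes) %in% ts_genes,
                       home_tissue = home, stringsAsFactors = FALSE),
    pairs = if (!is.null(pp)) realize_pair_correlations(pp, L, genes, tissue_of),
    tissue_means = mu, within_tissue_sd = cf$within_tissue_sd,
    batch_shifts = list(extraction = shift_ext, sequencing = shift_seq),
    injected = data.frame(sample_id = character(0), kind = character(0),
                          true_tissue = character(0), stringsAsFactors = FALSE),
    config = cf)
  list(expr = expr, samples = samples, truth = truth)
}

# population-level correlations realized by the generated (pre-batch) signal
realize_pair_correlations <- function(pp, L, genes, tissue_of) {
  pp$gene_a_id <- genes[pp$gene_a]
  pp$gene_b_id <- genes[pp$gene_b]
  z <- zscore_rows_by_group(L, tissue_of)
  pp$r_system <- vapply(seq_len(nrow(pp)), function(i)
    cor(L[pp$gene_a[i], ], L[pp$gene_b[i], ]), numeric(1))
  pp$r_tissue <- vapply(seq_len(nrow(pp)), function(i)
    cor(z[pp$gene_a[i], ], z[pp$gene_b[i], ]), numeric(1))
  pp
}

# z-score each row within groups of columns; zero-variance rows -> 0
zscore_rows_by_group <- function(m, groups) {
  out <- m
  for (g in unique(groups)) {
    j <- which(groups == g)
    sub <- m[, j, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1, sd)
    z <- (sub - mu) / ifelse(s > 0, s, Inf)
    out[, j] <- z
  }
  out
}

#' Inject outlying samples into a cohort
#'
#' Emulates the two kinds of problem sample the purification stage must
#' catch: `n_mixed` samples are re-drawn as 50/50 mixtures of the mean
#' profiles of one randomly chosen tissue pair (shared by all mixtures, and
#' each relabelled to a random parent — so injected in numbers they form
#' their own ambiguous cluster between the parents), and `n_divergent`
#' samples keep their expression but are relabeled to a wrong tissue. The
#' ground truth records which samples were touched.
#'
#' @param cohort output of [generate_cohort()].
#' @param n_mixed,n_divergent counts (must not exceed the cohort size).
#' @param seed seed for the selection and redraws.
#' @return the modified cohort.
#' @export
inject_outliers <- function(cohort, n_mixed = 0, n_divergent = 0, seed = 1L) {
  n <- ncol(cohort$expr$values)
  stopifnot(n_mixed >= 0, n_divergent >= 0, n_mixed + n_divergent <= n)
  if (n_mixed + n_divergent == 0) return(cohort)
  mu <- cohort$truth$tissue_means
  tissues <- colnames(mu)
  wsd <- cohort$truth$within_tissue_sd
  set.seed(child_seed(seed, 99))
  touched <- sample.int(n, n_mixed + n_divergent)
  mixed <- touched[seq_len(n_mixed)]
  divergent <- touched[n_mixed + seq_len(n_divergent)]
  inj <- list()
  if (n_mixed > 0) {
    pair <- sample(tissues, 2)
    for (j in mixed) {
      sid <- colnames(cohort$expr$values)[j]
      L <- 0.5 * mu[, pair[1]] + 0.5 * mu[, pair[2]] + rnorm(nrow(mu), 0, wsd)
      cohort$expr$values[, j] <- 10^L
      cohort$samples$tissue[j] <- sample(pair, 1)
      inj[[length(inj) + 1]] <- data.frame(sample_id = sid, kind = "mixed",
                                           true_tissue = paste(pair, collapse = "|"))
    }
  }
  for (j in divergent) {
    sid <- colnames(cohort$expr$values)[j]
    t1 <- cohort$samples$tissue[j]
    t2 <- sample(setdiff(tissues, t1), 1)
    cohort$samples$tissue[j] <- t2
    inj[[length(inj) + 1]] <- data.frame(sample_id = sid, kind = "divergent",
                                         true_tissue = t1)
  }
  cohort$truth$injected <- do.call(rbind, inj)
  cohort
}
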