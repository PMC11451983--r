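#' Assemble a pipeline configuration
#'
#' Collects every threshold and parameter of the pipeline in one
#' serializable list. Defaults are the production values: 0.1 TPM in 20% of
#' samples with the 5 TPM / 66% / 1 TPM rescue; 100 PCA permutations; k =
#' 1..100 for the Louvain sweep; perplexity 30 / learning rate 200 / theta 0
#' / 1000 iterations for t-SNE; 70 samples per cluster and 20 replicates;
#' 0.2 / 99.8 percentile trims and the 1 / 0.5 expected-count floors for the
#' G-statistic; sex, three age bands, and 2-means ischemia strata.
#'
#' Exactly one input source must be given: `input` (paths to a GCT matrix
#' and metadata tables) or `synthetic` (a [cohort_config()]).
#'
#' @param input list with `gct`, `attributes`, `phenotypes`, optional
#'   `clusters` (a precomputed assignment TSV).
#' @param synthetic a [cohort_config()].
#' @param out_dir output directory.
#' @param seed root seed for every randomized stage.
#' @param filter,normalize,clusters,estimate,strata stage parameter lists;
#'   values given here override the defaults field-by-field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            out_dir = "mincoex_out", seed = 1L,
                            filter = list(), normalize = list(),
                            clusters = list(), estimate = list(),
                            strata = list()) {
  if (is.null(input) == is.null(synthetic))
    stop("give exactly one of `input` or `synthetic`", call. = FALSE)
  merge_defaults <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    input = input, synthetic = synthetic, out_dir = out_dir,
    seed = as.integer(seed),
    filter = merge_defaults(filter, list(
      tpm_min = 0.1, frac_samples = 0.20, rescue_mean_tpm = 5,
      rescue_frac = 0.66, rescue_tpm = 1, same_tissue = FALSE)),
    normalize = merge_defaults(normalize, list(
      combat = TRUE, preserve = c("tissue", "sex", "age"))),
    clusters = merge_defaults(clusters, list(
      k_min = 1, k_max = 100, n_perm = 100, p_min = 0.5,
      mix_threshold = 0.25, perplexity = 30, learning_rate = 200,
      max_iter = 1000, manual_exclusions = NULL)),
    estimate = merge_defaults(estimate, list(
      n_per = 70, n_reps = 20, metrics = c("pearson", "spearman", "g"),
      modalities = c("tpm", "zscore"), strict = FALSE,
      floor_rule = "gt4_1")),
    strata = merge_defaults(strata, list(enabled = TRUE, n_per = 70))
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- raw$synthetic
  if (!is.null(syn)) syn <- do.call(cohort_config, syn)
  do.call(pipeline_config,
          c(list(input = raw$input, synthetic = syn),
            raw[setdiff(names(raw), c("input", "synthetic"))]))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

# canonical serializable form: classes stripped, NULL entries dropped (an
# absent key and a NULL key mean the same thing on read)
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x <- x[!vapply(x, is.null, logical(1))]
    lapply(x, unclass_deep)
  } else x
}

#' @rdname read_pipeline_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass_deep(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline end-to-end
#'
#' Stages, in order: load (or generate) the inputs; gene filtering with the
#' rescue rule; log10(TPM+1) + quantile normalization; serial batch
#' correction; tissue-cluster purification (or a precomputed assignment);
#' the subsample design; per-replicate estimation under each metric and
#' modality with minimum aggregation; covariate strata. Every artifact is
#' written under `config$out_dir` and listed in the returned manifest
#' (also written as `manifest.json`), which embeds the config hash.
#' Re-running with an identical config and inputs is bit-identical. A stage
#' failure aborts with the stage name after writing the partial manifest.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), stages = list(),
                   artifacts = list())
  current_stage <- "init"
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  run_stage <- function(name, fun) {
    current_stage <<- name
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  # ---- load ----
  loaded <- run_stage("load", function() {
    if (!is.null(config$synthetic)) {
      cohort <- generate_cohort(config$synthetic)
      list(expr = cohort$expr, samples = cohort$samples, truth = cohort$truth)
    } else {
      inp <- config$input
      for (f in c("gct", "attributes", "phenotypes"))
        if (is.null(inp[[f]])) stop("missing input: ", f)
      expr <- read_gct(inp$gct)
      samples <- read_sample_attributes(inp$attributes, inp$phenotypes,
                                        sample_ids = sample_ids(expr))
      list(expr = expr, samples = samples, truth = NULL)
    }
  })
  expr <- loaded$expr; samples <- loaded$samples

  # ---- filter ----
  filt <- run_stage("filter", function() {
    fc <- config$filter
    apply_gene_filter(expr, samples$tissue, tpm_min = fc$tpm_min,
                      frac_samples = fc$frac_samples,
                      rescue_mean_tpm = fc$rescue_mean_tpm,
                      rescue_frac = fc$rescue_frac, rescue_tpm = fc$rescue_tpm,
                      same_tissue = fc$same_tissue)
  })
  rep_path <- file.path(out, "gene_filter_report.tsv")
  data.table::fwrite(as.data.frame(filt$report), rep_path, sep = "\t")
  manifest$artifacts$gene_filter_report <- rep_path
  manifest$counts <- list(
    genes_in = nrow(expr$values),
    genes_pass = sum(filt$report$status == "PASS"),
    genes_rescued = sum(filt$report$status == "RESCUED"),
    genes_retained = nrow(filt$expr$values))
  expr <- filt$expr

  # ---- normalize ----
  expr <- run_stage("normalize", function() log_quantile_normalize(expr))
  if (isTRUE(config$normalize$combat))
    expr <- run_stage("combat", function()
      combat_serial(expr, samples, preserve = config$normalize$preserve))

  # ---- clusters ----
  assignment <- run_stage("clusters", function() {
    if (!is.null(config$input$clusters)) {
      if (!file.exists(config$input$clusters))
        stop("clusters file not found: ", config$input$clusters)
      read_cluster_assignment(config$input$clusters)
    } else {
      cc <- config$clusters
      purify_tissue_clusters(
        expr, setNames(samples$tissue, samples$sample_id),
        k_range = cc$k_min:cc$k_max, n_perm = cc$n_perm, p_min = cc$p_min,
        mix_threshold = cc$mix_threshold, perplexity = cc$perplexity,
        learning_rate = cc$learning_rate, max_iter = cc$max_iter,
        manual_exclusions = cc$manual_exclusions, seed = config$seed)
    }
  })
  asg_path <- file.path(out, "cluster_assignment.tsv")
  write_cluster_assignment(assignment, asg_path)
  manifest$artifacts$cluster_assignment <- asg_path
  manifest$counts$samples_in <- nrow(assignment)
  manifest$counts$samples_kept <- sum(assignment$status == "KEPT")
  manifest$counts$n_clusters <-
    length(unique(assignment$cluster[assignment$status == "KEPT"]))

  # ---- estimate ----
  ec <- config$estimate
  design <- run_stage("design", function()
    make_subsample_design(assignment, n_per = ec$n_per, n_reps = ec$n_reps,
                          base_seed = config$seed, strict = ec$strict))
  kept_ids <- assignment$sample_id[assignment$status == "KEPT"]
  expr_kept <- subset_expr(expr, j = intersect(sample_ids(expr), kept_ids))
  mats_dir <- file.path(out, "matrices")
  written <- character(0)
  run_stage("estimate", function() {
    for (mod in ec$modalities) {
      mexpr <- if (mod == "tpm") expr_kept else
        zscore_by_cluster(expr_kept, assignment)
      per_rep <- estimate_all(mexpr, design, metrics = ec$metrics,
                              modality = mod, floor_rule = ec$floor_rule)
      for (res in per_rep) {
        nm <- sprintf("%s_%s_rep%02d", res$metric, res$modality, res$rep)
        write_coex_result(res, mats_dir, nm)
        written <<- c(written, nm)
      }
      for (m in ec$metrics) {
        sub <- Filter(function(r) r$metric == m, per_rep)
        mn <- aggregate_minimum(sub)
        nm <- sprintf("%s_%s_min", m, mod)
        write_coex_result(mn, mats_dir, nm)
        written <<- c(written, nm)
      }
    }
    invisible(NULL)
  })

  # ---- strata ----
  if (isTRUE(config$strata$enabled)) {
    run_stage("strata", function() {
      st <- suppressWarnings(
        stratify_covariates(expr_kept, samples, assignment,
                            n_per = config$strata$n_per,
                            base_seed = config$seed,
                            modalities = ec$modalities))
      for (nm in names(st$results)) {
        write_coex_result(st$results[[nm]], mats_dir, nm)
        written <<- c(written, nm)
      }
      invisible(NULL)
    })
  }

  n_strata_written <- if (isTRUE(config$strata$enabled))
    sum(grepl("^(sex|age|ischemia)", written)) else 0L
  inv <- matrix_inventory(n_reps = ec$n_reps, n_metrics = length(ec$metrics),
                          n_modalities = length(ec$modalities),
                          n_strata = n_strata_written / max(1, length(ec$modalities)))
  manifest$artifacts$matrices <- written
  manifest$counts$n_matrices <- length(written)
  manifest$inventory_total <- inv$total
  write_manifest()
  invisible(manifest)
}
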