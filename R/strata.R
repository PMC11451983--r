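#' Covariate strata definitions
#'
#' Partitions samples within each covariate: sex into male / female; age into
#' `<50`, `50-59` (boundaries inclusive: "less than 50" and "more than 59"
#' leave [50, 59] closed), `>59`; ischemia time into low / high by 2-means
#' with centroids initialized at the minimum and maximum observed times.
#' Samples with a missing covariate are omitted from that covariate's strata
#' only.
#'
#' @param samples a `sample_table`.
#' @return named list of 7 character vectors of sample ids, plus attribute
#'   `ischemia_boundary` (midpoint between the two final centroids).
#' @export
covariate_strata <- function(samples) {
  sid <- samples$sample_id
  age <- samples$age
  isch <- split_ischemia_2means(samples$ischemia_time)
  out <- list(
    sex_male = sid[!is.na(samples$sex) & samples$sex == "male"],
    sex_female = sid[!is.na(samples$sex) & samples$sex == "female"],
    age_lt50 = sid[!is.na(age) & age < 50],
    age_50_59 = sid[!is.na(age) & age >= 50 & age <= 59],
    age_gt59 = sid[!is.na(age) & age > 59],
    ischemia_low = sid[!is.na(isch$level) & isch$level == "low"],
    ischemia_high = sid[!is.na(isch$level) & isch$level == "high"]
  )
  attr(out, "ischemia_boundary") <- isch$boundary
  out
}

#' Split ischemia times by 2-means
#'
#' K-means with k = 2 and centroids initialized at the minimum and maximum of
#' the observed times; the resulting clusters, ordered by centroid, define
#' the low- and high-ischemia levels.
#'
#' @param x numeric ischemia times (minutes); `NA` allowed.
#' @return list with `level` (factor low/high, `NA` preserved), `centers`,
#'   and `boundary` (midpoint of the two centers).
#' @export
split_ischemia_2means <- function(x) {
  lev <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  v <- x[ok]
  if (length(unique(v)) < 2) {
    lev[ok] <- "low"
    return(list(level = factor(lev, c("low", "high")), centers = range(v),
                boundary = NA_real_))
  }
  km <- suppressWarnings(kmeans(v, centers = c(min(v), max(v))))
  ord <- order(km$centers)
  lab <- c("low", "high")[match(km$cluster, ord)]
  lev[ok] <- lab
  list(level = factor(lev, c("low", "high")),
       centers = sort(as.vector(km$centers)),
       boundary = mean(km$centers))
}

#' Covariate-stratified coexpression
#'
#' For each of the 7 covariate strata, assembles the stratum's samples,
#' subsamples `n_per` per tissue cluster (clusters with no samples in the
#' stratum are dropped with a warning; undersized clusters contribute all
#' their samples), and computes one Pearson matrix per modality. The
#' z-score modality standardizes within cluster using the stratum's own
#' samples.
#'
#' @param expr [expr_matrix()] on the `LOG10P1` scale (all kept samples).
#' @param samples `sample_table` covering the expression samples.
#' @param assignment `cluster_assignment` (or named cluster vector).
#' @param n_per samples per cluster per stratum.
#' @param base_seed root seed; each stratum draws from its own child stream.
#' @param modalities subset of `c("tpm", "zscore")`.
#' @return list with `strata` (the sample-id lists) and `results` (named list
#'   `<stratum>.<modality>` of [coex_result()]s).
#' @export
stratify_covariates <- function(expr, samples, assignment, n_per = 70,
                                base_seed = 1L,
                                modalities = c("tpm", "zscore")) {
  check_scale(expr, "LOG10P1")
  modalities <- match.arg(modalities, several.ok = TRUE)
  strata <- covariate_strata(samples)
  map <- kept_cluster_map(assignment)
  results <- list()
  for (si in seq_along(strata)) {
    snm <- names(strata)[si]
    ids <- intersect(strata[[si]], intersect(sample_ids(expr), names(map)))
    if (!length(ids)) {
      warning("stratum ", snm, " has no samples; skipped")
      next
    }
    sub_map <- map[ids]
    empty <- setdiff(unique(map), unique(sub_map))
    if (length(empty))
      warning("stratum ", snm, ": cluster(s) dropped (no samples): ",
              paste(empty, collapse = ", "))
    design <- suppressWarnings(
      make_subsample_design(sub_map, n_per = n_per, n_reps = 1,
                            base_seed = child_seed(base_seed, 300 + si),
                            strict = FALSE))
    sel <- unlist(design$reps[[1]], use.names = FALSE)
    sub <- subset_expr(expr, j = sel)
    for (mod in modalities) {
      mat <- if (mod == "tpm") sub else
        zscore_by_cluster(sub, unname(sub_map[sel]))
      res <- correlation_matrix(mat, "pearson", modality = mod, stratum = snm)
      results[[paste(snm, mod, sep = ".")]] <- res
    }
  }
  list(strata = strata, results = results)
}
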