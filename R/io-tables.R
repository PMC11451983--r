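#' Read sample attributes and subject phenotypes
#'
#' Joins the two GTEx-style metadata tables into one row per expression
#' sample. The subject id is derived from the sample id by the GTEx prefix
#' convention (the first two dash-separated tokens). Missing batch fields are
#' kept and flagged as `NA`, never dropped; batch-correction later pools them
#' into a placeholder batch.
#'
#' Required attribute columns: `SAMPID`, `SMTSD` (tissue), `SMNABTCH`
#' (extraction batch), `SMGEBTCH` (sequencing batch), `SMTSISCH` (ischemia
#' time, minutes). Required phenotype columns: `SUBJID`, `SEX` (1/2 or
#' male/female), `AGE` (years, or a GTEx decade bracket such as `"50-59"`,
#' taken at its midpoint).
#'
#' @param attr_path sample-attribute TSV.
#' @param pheno_path subject-phenotype TSV.
#' @param sample_ids optional character vector of expression sample ids; if
#'   given, the table is restricted to (and ordered by) these, and an error
#'   lists any expression sample absent from the attribute file.
#' @return a `data.frame` of class `sample_table` with columns `sample_id`,
#'   `subject_id`, `tissue`, `extraction_batch`, `sequencing_batch`, `sex`,
#'   `age`, `ischemia_time`.
#' @export
read_sample_attributes <- function(attr_path, pheno_path, sample_ids = NULL) {
  attr <- as.data.frame(data.table::fread(attr_path, sep = "\t",
                                          na.strings = c("", "NA")))
  pheno <- as.data.frame(data.table::fread(pheno_path, sep = "\t",
                                           na.strings = c("", "NA")))
  need_a <- c("SAMPID", "SMTSD", "SMNABTCH", "SMGEBTCH", "SMTSISCH")
  miss <- setdiff(need_a, names(attr))
  if (length(miss))
    stop_format(attr_path, "missing required column(s): %s", paste(miss, collapse = ", "))
  need_p <- c("SUBJID", "SEX", "AGE")
  miss <- setdiff(need_p, names(pheno))
  if (length(miss))
    stop_format(pheno_path, "missing required column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(attr$SAMPID))
    stop_format(attr_path, "duplicated sample id '%s'",
                attr$SAMPID[duplicated(attr$SAMPID)][1])

  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, attr$SAMPID)
    if (length(absent))
      stop("expression sample(s) absent from attribute file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    attr <- attr[match(sample_ids, attr$SAMPID), , drop = FALSE]
  }

  subj <- vapply(strsplit(attr$SAMPID, "-", fixed = TRUE),
                 function(p) paste(p[seq_len(min(2, length(p)))], collapse = "-"),
                 character(1))
  ph <- pheno[match(subj, pheno$SUBJID), , drop = FALSE]

  out <- data.frame(
    sample_id = attr$SAMPID,
    subject_id = subj,
    tissue = as.character(attr$SMTSD),
    extraction_batch = as.character(attr$SMNABTCH),
    sequencing_batch = as.character(attr$SMGEBTCH),
    sex = parse_sex(ph$SEX),
    age = parse_age(ph$AGE),
    ischemia_time = as.numeric(attr$SMTSISCH),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$age) & out$age < 0))
    stop("negative age in phenotype file", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sample_table", "data.frame")
  out
}

parse_sex <- function(x) {
  out <- rep(NA_character_, length(x))
  xc <- tolower(trimws(as.character(x)))
  out[xc %in% c("1", "male", "m")] <- "male"
  out[xc %in% c("2", "female", "f")] <- "female"
  out
}

parse_age <- function(x) {
  xc <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(xc))
  br <- regmatches(xc, regexec("^([0-9]+)-([0-9]+)$", xc))
  mid <- vapply(br, function(m) {
    if (length(m) == 3) (as.numeric(m[2]) + as.numeric(m[3])) / 2 else NA_real_
  }, numeric(1))
  ifelse(is.na(num), mid, num)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines of `set name`, `description`, then member gene ids.
#' Sets smaller than `min_size` are dropped (the enrichment benchmark keeps
#' pathways with at least 2 genes); the number dropped is reported as a
#' message.
#'
#' @param path GMT file.
#' @param min_size minimum retained set size.
#' @return a named list of character vectors, class `gene_set_collection`,
#'   with attributes `min_size` and `n_dropped`.
#' @export
read_gmt <- function(path, min_size = 2) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(setNames(list(), character(0)),
                     class = "gene_set_collection", min_size = min_size, n_dropped = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop_format(path, "malformed GMT line %d: %d field(s), need at least 3", bad, nf[bad])
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop_format(path, "duplicated set name '%s'", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  keep <- lengths(sets) >= min_size
  if (any(!keep))
    message(sum(!keep), " gene set(s) below min_size = ", min_size, " dropped")
  structure(sets[keep], class = "gene_set_collection",
            min_size = min_size, n_dropped = sum(!keep))
}

#' Read a probabilistic network edge list
#'
#' TSV with header columns `gene_a`, `gene_b`, `probability`.
#'
#' @param path edge-list file.
#' @return a `data.frame` with the three columns; probabilities validated to
#'   lie in `[0, 1]` and self-edges rejected.
#' @export
read_edge_list <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("gene_a", "gene_b", "probability")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format(path, "missing required column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$probability <- as.numeric(df$probability)
  if (anyNA(df$probability) || any(df$probability < 0 | df$probability > 1))
    stop_format(path, "probabilities must lie in [0, 1]")
  if (any(df$gene_a == df$gene_b))
    stop_format(path, "self-edge on gene '%s'", df$gene_a[df$gene_a == df$gene_b][1])
  df
}

#' Read a ChIP-peak gene annotation table
#'
#' TSV with header columns `gene_id` and `has_peak` (logical or 0/1).
#'
#' @param path peak table file.
#' @return named logical vector over unique gene ids.
#' @export
read_peak_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("gene_id", "has_peak")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format(path, "missing required column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop_format(path, "duplicated gene id '%s'", df$gene_id[duplicated(df$gene_id)][1])
  flag <- df$has_peak
  if (!is.logical(flag)) flag <- as.integer(flag) != 0L
  if (anyNA(flag)) stop_format(path, "has_peak must be logical or 0/1")
  setNames(flag, df$gene_id)
}
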