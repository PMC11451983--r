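#' Discretize a gene's expression into three levels
#'
#' Values strictly below the 0.2th percentile or strictly above the 99.8th
#' percentile are trimmed (values exactly at a bound are kept). The remaining
#' values are clustered by k-means with k = 3 and deterministic initial
#' centroids at the trimmed data's 0.2th percentile, median, and 99.8th
#' percentile — the Hartigan-Wong algorithm with at most 1000 iterations,
#' falling back to Lloyd with at most 10,000 iterations if it does not
#' converge. Codes are ordered by centroid so 1/2/3 always mean low/mid/high.
#'
#' @param values numeric vector of one gene's expression.
#' @param trim_lo,trim_hi trim quantile probabilities (0.002 and 0.998).
#' @param min_kept minimum number of non-trimmed values required.
#' @return integer vector (1 = LOW, 2 = MID, 3 = HIGH, `NA` = trimmed) with
#'   attributes `centroids`, `bounds`, `variant` ("HW" or "LLOYD") and
#'   `degenerate`.
#' @export
discretize_three_levels <- function(values, trim_lo = 0.002, trim_hi = 0.998,
                                    min_kept = 10) {
  stopifnot(is.numeric(values))
  q <- quantile(values, c(trim_lo, trim_hi), names = FALSE)
  trimmed <- values < q[1] | values > q[2]
  kept <- values[!trimmed]
  if (length(kept) < min_kept)
    stop("fewer than ", min_kept, " non-trimmed values", call. = FALSE)
  codes <- rep(NA_integer_, length(values))
  if (length(unique(kept)) < 3) {
    warning("fewer than 3 distinct values; degenerate all-MID coding")
    codes[!trimmed] <- 2L
    return(structure(codes, centroids = rep(median(kept), 3), bounds = q,
                     variant = NA_character_, degenerate = TRUE))
  }
  centers <- quantile(kept, c(trim_lo, 0.5, trim_hi), names = FALSE)
  if (anyDuplicated(centers)) {
    # heavily tied data: fall back to three distinct observed values
    u <- sort(unique(kept))
    centers <- u[round(c(1, (length(u) + 1) / 2, length(u)))]
  }
  km <- suppressWarnings(kmeans(kept, centers = centers, iter.max = 1000,
                                algorithm = "Hartigan-Wong"))
  variant <- "HW"
  if (km$ifault != 0 || km$iter >= 1000) {
    km <- suppressWarnings(kmeans(kept, centers = centers, iter.max = 10000,
                                  algorithm = "Lloyd"))
    variant <- "LLOYD"
  }
  ord <- order(km$centers)
  relabel <- match(seq_along(ord), ord)
  codes[!trimmed] <- relabel[km$cluster]
  structure(codes, centroids = sort(as.vector(km$centers)), bounds = q,
            variant = variant, degenerate = FALSE)
}

#' G-statistic on a 3x3 contingency table of discretized genes
#'
#' Samples trimmed in either gene are excluded pairwise. Observed counts `O`
#' are cross-tabulated from the two codes; expected counts `E` are the
#' product of marginals over the total, as in a chi-square contingency test.
#' To tame the explosion of `O * ln(O/E)` when `E` is infinitesimal, `E` is
#' floored before the log: at 1 for cells with `O > 4`, at 0.5 otherwise
#' (`floor_rule = "swap"` reverses the mapping). Cells with `O = 0`
#' contribute nothing. Per-cell two-sided normal p-values are derived from
#' adjusted standardized residuals
#' `(O - E) / sqrt(E (1 - rowfrac)(1 - colfrac))`.
#'
#' @param codes_a,codes_b integer codes from [discretize_three_levels()] on
#'   the same sample set.
#' @param floor_rule `"gt4_1"` (default: O > 4 floors E at 1, else at 0.5)
#'   or `"swap"`.
#' @return a list of class `contingency3x3`: `O`, `E`, `E_floored`, `G`,
#'   `p_values`, `n`.
#' @export
g_statistic <- function(codes_a, codes_b, floor_rule = c("gt4_1", "swap")) {
  floor_rule <- match.arg(floor_rule)
  stopifnot(length(codes_a) == length(codes_b))
  keep <- !is.na(codes_a) & !is.na(codes_b)
  n <- sum(keep)
  if (n == 0) stop("empty contingency table", call. = FALSE)
  O <- g_crosstab(codes_a[keep], codes_b[keep])
  rs <- rowSums(O); cs <- colSums(O)
  E <- outer(rs, cs) / n
  fl <- if (floor_rule == "gt4_1") ifelse(O > 4, 1, 0.5) else ifelse(O > 4, 0.5, 1)
  Ef <- pmax(E, fl)
  terms <- ifelse(O > 0, O * log(O / Ef), 0)
  G <- 2 * sum(terms)
  denom <- sqrt(E * outer(1 - rs / n, 1 - cs / n))
  resid <- ifelse(denom > 0, (O - E) / denom, NA_real_)
  p <- 2 * pnorm(-abs(resid))
  structure(list(O = O, E = E, E_floored = Ef, G = G, p_values = p, n = n),
            class = "contingency3x3")
}

g_crosstab <- function(a, b) {
  cnt <- tabulate((a - 1L) * 3L + b, nbins = 9L)
  matrix(cnt, 3, 3, byrow = TRUE,
         dimnames = list(c("LOW", "MID", "HIGH"), c("LOW", "MID", "HIGH")))
}

#' Pairwise G-statistic matrix
#'
#' Discretizes each gene once on the given sample set, then computes the
#' floored G-statistic for every unordered gene pair with pairwise exclusion
#' of trimmed samples. The diagonal is `NA`: G of a gene with itself is not a
#' meaningful association value.
#'
#' @param x [expr_matrix()] or numeric genes-by-samples matrix.
#' @param floor_rule see [g_statistic()].
#' @param codes optional precomputed code matrix (genes x samples), as
#'   returned by [discretize_matrix()], to reuse a fit across subsets.
#' @return symmetric numeric matrix of G values.
#' @export
g_matrix <- function(x, floor_rule = "gt4_1", codes = NULL) {
  v <- if (inherits(x, "expr_matrix")) x$values else x
  if (is.null(codes)) codes <- discretize_matrix(v)
  p <- nrow(codes)
  out <- matrix(NA_real_, p, p, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      g <- g_statistic(codes[i, ], codes[j, ], floor_rule = floor_rule)$G
      out[i, j] <- g
      out[j, i] <- g
    }
  }
  out
}

#' @rdname g_matrix
#' @export
discretize_matrix <- function(v) {
  codes <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (i in seq_len(nrow(v)))
    codes[i, ] <- suppressWarnings(discretize_three_levels(v[i, ]))
  codes
}
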