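#' Counts per million
#'
#' Scales each sample (column) of a count matrix to counts per million mapped
#' reads: `1e6 * count / library size`. Library sizes default to the column
#' sums of `counts`; pass `lib_sizes` to use sizes computed before an earlier
#' subsetting step.
#'
#' @param counts numeric matrix of non-negative counts, genes x samples.
#' @param lib_sizes per-sample library sizes (> 0); default `colSums(counts)`.
#' @return matrix of CPM values, same dimensions as `counts`.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  counts <- check_counts(counts)
  if (length(lib_sizes) != ncol(counts)) {
    stop("need one library size per sample", call. = FALSE)
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Filter genes by minimum expression
#'
#' Retains genes with CPM at or above `min_cpm` in at least `min_samples`
#' samples. CPM is computed with the library sizes of the *input* matrix, so
#' filtering does not change the scale against which genes are judged.
#'
#' @param counts count matrix, genes x samples.
#' @param min_cpm CPM threshold (default 1, the conventional low-expression
#'   cutoff).
#' @param min_samples number of samples that must reach `min_cpm`; a sensible
#'   default is the smallest experimental group size.
#' @return the retained rows of `counts` (possibly zero rows), with attribute
#'   `removed` holding the dropped gene ids.
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_samples = 1) {
  counts <- check_counts(counts)
  if (min_samples > ncol(counts)) {
    stop("min_samples exceeds the number of samples", call. = FALSE)
  }
  if (min_samples < 1) stop("min_samples must be >= 1", call. = FALSE)
  keep <- rowSums(cpm(counts) >= min_cpm) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Median-of-ratios normalization
#'
#' Computes per-sample size factors as the median, over reference genes, of
#' the ratio of the sample's count to the gene's across-sample geometric
#' mean. Reference genes are those with strictly positive counts in every
#' sample (only they have a positive geometric mean). Normalized values are
#' `count / size factor`. For identical columns all size factors are 1; the
#' factors are equivariant under rescaling of any one column.
#'
#' @param counts count matrix, genes x samples; at least one gene must be
#'   positive in every sample.
#' @return list of class `normalized_counts` with elements `normalized`
#'   (matrix), `size_factors` (named numeric) and `n_reference` (number of
#'   reference genes used).
#' @export
median_of_ratios <- function(counts) {
  counts <- check_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has positive counts in every sample; cannot form reference set",
         call. = FALSE)
  }
  x <- counts[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(x)))
  sf <- apply(x / geo, 2L, stats::median)
  out <- list(
    normalized = sweep(counts, 2L, sf, "/"),
    size_factors = sf,
    n_reference = sum(ref)
  )
  class(out) <- "normalized_counts"
  out
}

#' @export
print.normalized_counts <- function(x, ...) {
  cat("Median-of-ratios normalized matrix:", nrow(x$normalized), "genes x",
      ncol(x$normalized), "samples\n")
  cat("  size factors (", x$n_reference, " reference genes): ", sep = "")
  cat(sprintf("%.3f", x$size_factors), sep = ", ")
  cat("\n")
  invisible(x)
}

#' MDS-based sample outlier screening
#'
#' Embeds samples in two dimensions by classical multidimensional scaling of
#' the correlation distance `1 - r` between `log2(CPM + pseudocount)`
#' expression profiles, then flags samples unusually far from their own group
#' centroid. A sample is flagged when its centroid distance exceeds
#' `median + k * MAD` of all within-group centroid distances (groups of size
#' one cannot define a spread and are exempt). At most `n_flag_max` samples
#' are flagged, worst first.
#'
#' The flagging rule is a documented convention: published analyses often
#' report MDS outliers without stating a criterion, so the cutoff here is
#' deliberately conservative (default `k = 3`) and capped.
#'
#' @param counts count matrix, genes x samples (>= 3 samples).
#' @param groups group label per sample (replicate groups, e.g.
#'   treatment-by-time combinations).
#' @param n_flag_max maximum number of samples to flag (default 2).
#' @param k MAD multiplier of the flagging threshold (default 3).
#' @param pseudocount added to CPM before log2 (default 1).
#' @return list of class `mds_outlier_report`: `coordinates` (samples x 2),
#'   `centroid_dist` (named), `flagged` (character), `exempt` (groups of size
#'   1), `threshold`, and `rule` (parameter echo).
#' @export
mds_outliers <- function(counts, groups, n_flag_max = 2, k = 3, pseudocount = 1) {
  counts <- check_counts(counts)
  n <- ncol(counts)
  if (n < 3L) stop("need at least 3 samples for MDS screening", call. = FALSE)
  if (length(groups) != n) stop("'groups' must have one label per sample", call. = FALSE)
  if (n_flag_max < 0) stop("n_flag_max must be >= 0", call. = FALSE)
  lg <- log2(cpm(counts) + pseudocount)
  d <- 1 - stats::cor(lg)
  d[d < 0] <- 0  # guard tiny negatives from floating point
  ## degenerate geometries (e.g. identical samples) legitimately yield fewer
  ## than 2 positive eigenvalues; the embedding is padded below
  coords <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = min(2L, n - 1L)))
  if (ncol(coords) < 2L) {       # degenerate geometry (e.g. identical samples)
    coords <- cbind(coords, matrix(0, n, 2L - ncol(coords)))
  }
  rownames(coords) <- colnames(counts)
  groups <- as.character(groups)
  sizes <- table(groups)
  exempt <- names(sizes)[sizes < 2L]
  cd <- rep(NA_real_, n)
  names(cd) <- colnames(counts)
  for (g in names(sizes)[sizes >= 2L]) {
    idx <- which(groups == g)
    ctr <- colMeans(coords[idx, , drop = FALSE])
    cd[idx] <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2L, ctr)^2))
  }
  eligible <- !is.na(cd)
  thr <- if (any(eligible)) {
    stats::median(cd[eligible]) + k * stats::mad(cd[eligible])
  } else Inf
  cand <- names(cd)[eligible & cd > thr]
  cand <- cand[order(cd[cand], decreasing = TRUE)]
  flagged <- utils::head(cand, n_flag_max)
  out <- list(
    coordinates = coords,
    centroid_dist = cd,
    flagged = flagged,
    exempt = exempt,
    threshold = thr,
    rule = list(metric = "1 - Pearson r of log2(CPM + pseudocount)",
                k = k, n_flag_max = n_flag_max, pseudocount = pseudocount)
  )
  class(out) <- "mds_outlier_report"
  out
}

#' @export
print.mds_outlier_report <- function(x, ...) {
  cat("MDS outlier screen over", nrow(x$coordinates), "samples",
      sprintf("(threshold %.4g)\n", x$threshold))
  if (length(x$flagged)) {
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("  no samples flagged\n")
  }
  if (length(x$exempt)) {
    cat("  exempt singleton groups:", paste(x$exempt, collapse = ", "), "\n")
  }
  invisible(x)
}
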