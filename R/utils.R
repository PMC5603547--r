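## Internal helpers shared across stages.

## Round half away from zero at `digits` decimals. base::round() rounds half to
## even, which does not reproduce conventional 1-decimal summary tables.
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Validate a counts matrix: numeric, non-negative, integral values, unique
## dimnames. Returns the matrix with dimnames filled in if missing.
check_counts <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop(what, " must be non-negative and free of NA", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids", call. = FALSE)
  counts
}

## Group factor from labels. A supplied factor keeps its level order (the
## first level is the reference); character labels get first-appearance order.
as_two_groups <- function(groups, n) {
  if (length(groups) != n) stop("'groups' must have one label per sample", call. = FALSE)
  if (is.factor(groups)) droplevels(groups) else {
    factor(groups, levels = unique(as.character(groups)))
  }
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
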