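## Per-sample equalization factors for the DE stage, normalized to
## geometric mean 1. Median-of-ratios is used when a reference gene set
## exists (robust to a few dominant genes); otherwise plain library sizes.
equalize_size_factors <- function(counts) {
  sf <- if (any(rowSums(counts > 0) == ncol(counts))) {
    median_of_ratios(counts)$size_factors
  } else {
    lib <- colSums(counts)
    if (any(lib <= 0)) stop("zero library size", call. = FALSE)
    lib
  }
  sf / geometric_mean(sf)
}

#' Method-of-moments common dispersion estimate
#'
#' Estimates a single negative-binomial dispersion shared by all genes.
#' Counts are first brought to a common scale by dividing each sample by
#' its median-of-ratios size factor (normalized to geometric mean 1; plain
#' library sizes are used if no reference gene is positive everywhere).
#' For each gene the within-group mean `m` and variance
#' `v` (averaged over groups) give a moment estimate
#' `phi_g = max(0, (v - m) / m^2)`; the common value is the 20%-trimmed mean
#' of `phi_g` over genes with positive mean. The estimator is deterministic
#' and deliberately simple: it supplies the nuisance parameter of
#' [nb_exact_test()], not a per-gene shrinkage fit.
#'
#' @param counts count matrix, genes x samples.
#' @param groups group label per sample; every group must have >= 2 samples.
#' @param trim tail fraction trimmed from each side of the gene-wise
#'   estimates (default 0.2).
#' @return list of class `dispersion_estimate` with `phi` and `method`.
#' @export
estimate_common_dispersion <- function(counts, groups, trim = 0.2) {
  counts <- check_counts(counts)
  f <- as_two_groups(groups, ncol(counts))  # works for >= 2 groups too
  if (any(table(f) < 2L)) {
    stop("every group needs at least 2 samples to estimate a variance", call. = FALSE)
  }
  z <- sweep(counts, 2L, equalize_size_factors(counts), "/")
  lv <- levels(f)
  m_g <- sapply(lv, function(g) rowMeans(z[, f == g, drop = FALSE]))
  v_g <- sapply(lv, function(g) apply(z[, f == g, drop = FALSE], 1L, stats::var))
  m <- rowMeans(as.matrix(m_g))
  v <- rowMeans(as.matrix(v_g))
  ok <- m > 0
  phi_g <- pmax(0, (v[ok] - m[ok]) / m[ok]^2)
  out <- list(phi = mean(phi_g, trim = trim), method = "moments-trimmed",
              n_genes = sum(ok))
  class(out) <- "dispersion_estimate"
  out
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("Common NB dispersion phi = %.4f (%s, %d genes)\n",
              x$phi, x$method, x$n_genes))
  invisible(x)
}

## Conditional exact NB p-value for one gene.
## yA, yB: group-summed pseudo-counts (integers); nA, nB: group sizes.
## Under H0 the group sums are NB with means proportional to group size and
## dispersion phi / n_group; conditioning on t = yA + yB, the two-sided
## p-value sums the probabilities of all partitions of t no more likely than
## the observed one, normalized by the total.
exact_nb_pvalue <- function(yA, yB, nA, nB, phi, window_limit = 10000L) {
  t <- yA + yB
  if (t == 0) return(1)
  pA <- nA / (nA + nB)
  muA <- t * pA
  if (phi <= 1e-12) {
    ## Poisson limit: the conditional law of yA is exactly binomial(t, pA)
    if (t <= window_limit) {
      a <- 0:t
      lp <- stats::dbinom(a, t, pA, log = TRUE)
    } else {
      sd <- sqrt(t * pA * (1 - pA))
      a <- max(0, floor(muA - 50 * sd)):min(t, ceiling(muA + 50 * sd))
      a <- unique(sort(c(a, yA)))
      lp <- stats::dbinom(a, t, pA, log = TRUE)
    }
  } else {
    sizeA <- nA / phi
    sizeB <- nB / phi
    muB <- t - muA
    if (t <= window_limit) {
      a <- 0:t
    } else {
      sd <- sqrt(muA * (1 + muA * phi / nA))
      a <- max(0, floor(muA - 50 * sd)):min(t, ceiling(muA + 50 * sd))
      a <- unique(sort(c(a, yA)))
    }
    lp <- stats::dnbinom(a, size = sizeA, mu = muA, log = TRUE) +
      stats::dnbinom(t - a, size = sizeB, mu = muB, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p_obs <- p[match(yA, a)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]) / sum(p))
}

#' Negative-binomial exact test for two-group differential expression
#'
#' Tests each gene for a difference between two groups with a conditional
#' exact test. Samples are first equalized by dividing each column by its
#' median-of-ratios size factor (normalized to geometric mean 1) and
#' rounding ("pseudo-counts"), so all libraries sit on a common scale
#' without letting a few dominant genes distort the totals; per-group
#' pseudo-count sums are then compared conditional on their total, with
#' group sums modelled as negative binomial (mean proportional to group
#' size, dispersion `phi / n_group`). The two-sided p-value aggregates all
#' partitions of the total at most as probable as the observed one. With
#' `phi = 0` this reduces to the exact binomial (minimum-likelihood
#' two-sided) test.
#'
#' The reported effect is `log2fc = log2((yB/nB + c) / (yA/nA + c))`, the
#' second group over the first, where `c = prior_count` damps fold changes
#' of weakly expressed genes.
#'
#' @param counts count matrix, genes x samples.
#' @param groups two group labels, one per sample; the reference
#'   (denominator) group is the first factor level, or the first label to
#'   appear when `groups` is a character vector.
#' @param phi common NB dispersion (>= 0), e.g. from
#'   [estimate_common_dispersion()].
#' @param prior_count pseudocount `c` in the fold-change formula
#'   (default 0.125).
#' @return data frame with columns `gene_id`, `log2fc`, `pvalue`.
#' @examples
#' cts <- matrix(rpois(60, 50), 10, 6,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' nb_exact_test(cts, rep(c("CTRL", "E2"), each = 3), phi = 0.1)
#' @export
nb_exact_test <- function(counts, groups, phi, prior_count = 0.125) {
  counts <- check_counts(counts)
  f <- as_two_groups(groups, ncol(counts))
  if (nlevels(f) != 2L) stop("exactly two groups required", call. = FALSE)
  if (phi < 0) stop("phi must be >= 0", call. = FALSE)
  pseudo <- round(sweep(counts, 2L, equalize_size_factors(counts), "/"))
  a_idx <- f == levels(f)[1L]
  nA <- sum(a_idx); nB <- sum(!a_idx)
  yA <- rowSums(pseudo[, a_idx, drop = FALSE])
  yB <- rowSums(pseudo[, !a_idx, drop = FALSE])
  pv <- vapply(seq_along(yA), function(i) {
    exact_nb_pvalue(yA[i], yB[i], nA, nB, phi)
  }, numeric(1))
  lfc <- ifelse(yA + yB == 0, 0,
                log2((yB / nB + prior_count) / (yA / nA + prior_count)))
  data.frame(gene_id = rownames(counts), log2fc = lfc, pvalue = pv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (`stats::p.adjust(method =
#' "BH")`) with input validation, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values in `[0, 1]`.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the joint FDR and fold-change rule to exact-test results: a gene
#' is `up` if `qvalue < alpha` and `log2fc > log2(fc_min)`, `down` if
#' `qvalue < alpha` and `log2fc < -log2(fc_min)`, otherwise `ns`. Results
#' are partitioned by transcript biotype and per-biotype up/down counts are
#' attached as a summary.
#'
#' @param results data frame from [nb_exact_test()] (columns `gene_id`,
#'   `log2fc`, `pvalue`); q-values are computed here with [bh_adjust()].
#' @param biotype named character vector mapping gene ids to biotypes
#'   (`"lncRNA"`, `"mRNA"`, ...); genes without a biotype are kept in the
#'   table (biotype `NA`) but excluded from the biotype summary.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_min minimum fold change on the natural scale (default 2).
#' @return data frame of class `de_result` with columns `gene_id`,
#'   `biotype`, `log2fc`, `pvalue`, `qvalue`, `call`, with attributes
#'   `summary` (biotype x call counts), `alpha`, `fc_min` and
#'   `missing_biotype`.
#' @export
call_degs <- function(results, biotype = NULL, alpha = 0.05, fc_min = 2.0) {
  stopifnot(is.data.frame(results),
            all(c("gene_id", "log2fc", "pvalue") %in% names(results)))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (fc_min < 1) stop("fc_min must be >= 1", call. = FALSE)
  q <- bh_adjust(results$pvalue)
  lcut <- log2(fc_min)
  call <- rep("ns", nrow(results))
  call[q < alpha & results$log2fc > lcut] <- "up"
  call[q < alpha & results$log2fc < -lcut] <- "down"
  bt <- if (is.null(biotype)) rep(NA_character_, nrow(results)) else {
    unname(biotype[results$gene_id])
  }
  missing_bt <- results$gene_id[is.na(bt)]
  out <- data.frame(gene_id = results$gene_id, biotype = bt,
                    log2fc = results$log2fc, pvalue = results$pvalue,
                    qvalue = q,
                    call = factor(call, levels = c("up", "down", "ns")),
                    row.names = NULL, stringsAsFactors = FALSE)
  known <- !is.na(out$biotype)
  attr(out, "summary") <- table(biotype = out$biotype[known],
                                call = out$call[known])
  attr(out, "alpha") <- alpha
  attr(out, "fc_min") <- fc_min
  attr(out, "missing_biotype") <- missing_bt
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential expression over %d genes (FDR < %g, fold change > %g)\n",
              nrow(x), attr(x, "alpha"), attr(x, "fc_min")))
  s <- attr(x, "summary")
  if (length(s)) print(s)
  nm <- length(attr(x, "missing_biotype"))
  if (nm) cat("  ", nm, "gene(s) without biotype excluded from the summary\n")
  invisible(x)
}
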