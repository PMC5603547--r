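#' Pearson correlation of two expression profiles
#'
#' Product-moment correlation with validation; returns `NA` when either
#' vector has zero variance (such pairs are excluded from networks and
#' counted).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite values.
#' @return correlation in `[-1, 1]`, or `NA_real_` for degenerate input.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Student-t test of zero correlation: `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' on `n - 2` degrees of freedom. `r = +/-1` maps to `p = 0` by convention;
#' `NA` correlations give `NA`. Vectorized over `r`.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param n number of paired observations (>= 3).
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
corr_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3", call. = FALSE)
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  one <- ok & abs(r) >= 1
  p[one] <- 0
  mid <- ok & !one
  tstat <- r[mid] * sqrt(n - 2) / sqrt(1 - r[mid]^2)
  p[mid] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p
}

#' Build the lncRNA-mRNA co-expression network
#'
#' Computes the Pearson correlation between every lncRNA-mRNA pair of
#' expression profiles, attaches t-based p-values, adjusts them jointly with
#' Benjamini-Hochberg over all tested pairs, and keeps the pairs passing
#' both the correlation and the FDR threshold. The result is a bipartite
#' network (lncRNA and mRNA node sets, correlation-weighted edges) with node
#' degrees.
#'
#' By default correlations are computed on `log2(value + pseudocount)`;
#' `log2 = FALSE` uses the values as supplied. With `signed =
#' "positive"` only correlations `r >= r_threshold` form edges (co-expressed
#' pairs); `"absolute"` also admits strong negative correlations.
#'
#' @param expr normalized expression matrix (genes x samples), e.g.
#'   `median_of_ratios(counts)$normalized`, with at least 3 samples.
#' @param lnc_ids,mrna_ids row names of `expr` forming the two node
#'   candidate sets (typically the differentially expressed lncRNAs and
#'   mRNAs); must be disjoint.
#' @param r_threshold minimum correlation for an edge (default 0.99).
#' @param q_threshold FDR threshold (default 0.05).
#' @param signed `"positive"` (default) or `"absolute"`.
#' @param log2 log-transform expression before correlating (default `TRUE`).
#' @param pseudocount added before the log (default 1).
#' @return list of class `coexpression_network`: `edges` (data frame
#'   `lnc_id`, `mrna_id`, `r`, `pvalue`, `qvalue`), `nodes` (data frame
#'   `id`, `biotype`, `degree` for connected nodes), `n_pairs_tested`,
#'   `n_pairs_degenerate` (zero-variance pairs excluded) and `params`.
#' @export
build_network <- function(expr, lnc_ids, mrna_ids, r_threshold = 0.99,
                          q_threshold = 0.05,
                          signed = c("positive", "absolute"),
                          log2 = TRUE, pseudocount = 1) {
  signed <- match.arg(signed)
  if (!is.matrix(expr) || is.null(rownames(expr))) {
    stop("expr must be a matrix with gene row names", call. = FALSE)
  }
  if (ncol(expr) < 3L) stop("need at least 3 samples to correlate", call. = FALSE)
  lnc_ids <- sort(unique(as.character(lnc_ids)))
  mrna_ids <- sort(unique(as.character(mrna_ids)))
  if (length(intersect(lnc_ids, mrna_ids))) {
    stop("lnc_ids and mrna_ids must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(lnc_ids, mrna_ids), rownames(expr))
  if (length(missing)) {
    stop("ids absent from expr: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!length(lnc_ids) || !length(mrna_ids)) {
    stop("no lncRNA-mRNA pairs to test", call. = FALSE)
  }
  x <- expr[c(lnc_ids, mrna_ids), , drop = FALSE]
  if (log2) x <- base::log2(x + pseudocount)
  xl <- t(x[lnc_ids, , drop = FALSE])
  xm <- t(x[mrna_ids, , drop = FALSE])
  suppressWarnings(R <- stats::cor(xl, xm))  # NA for zero-variance profiles
  n <- ncol(expr)
  edges <- data.frame(
    lnc_id = rep(lnc_ids, times = length(mrna_ids)),
    mrna_id = rep(mrna_ids, each = length(lnc_ids)),
    r = as.vector(R),
    stringsAsFactors = FALSE
  )
  degenerate <- sum(is.na(edges$r))
  edges <- edges[!is.na(edges$r), , drop = FALSE]
  if (!nrow(edges)) stop("all pairs degenerate; nothing to test", call. = FALSE)
  edges$pvalue <- corr_pvalue(edges$r, n)
  edges$qvalue <- bh_adjust(edges$pvalue)
  n_tested <- nrow(edges)
  pass_r <- if (signed == "positive") edges$r >= r_threshold else abs(edges$r) >= r_threshold
  edges <- edges[pass_r & edges$qvalue < q_threshold, , drop = FALSE]
  edges <- edges[order(edges$lnc_id, edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- c(table(edges$lnc_id), table(edges$mrna_id))
  nodes <- data.frame(
    id = as.character(names(deg) %||% character(0)),
    biotype = rep(c("lncRNA", "mRNA"),
                  c(length(unique(edges$lnc_id)), length(unique(edges$mrna_id)))),
    degree = as.integer(deg),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  out <- list(
    edges = edges, nodes = nodes,
    n_pairs_tested = n_tested,
    n_pairs_degenerate = degenerate,
    n_samples = n,
    params = list(r_threshold = r_threshold, q_threshold = q_threshold,
                  signed = signed, log2 = log2, pseudocount = pseudocount)
  )
  class(out) <- "coexpression_network"
  out
}

#' @export
print.coexpression_network <- function(x, ...) {
  nl <- sum(x$nodes$biotype == "lncRNA")
  nm <- sum(x$nodes$biotype == "mRNA")
  cat(sprintf(paste0("lncRNA-mRNA co-expression network: %d edges between ",
                     "%d lncRNAs and %d mRNAs\n"), nrow(x$edges), nl, nm))
  cat(sprintf("  %d pairs tested over %d samples (r >= %g, FDR < %g, %s)\n",
              x$n_pairs_tested, x$n_samples, x$params$r_threshold,
              x$params$q_threshold, x$params$signed))
  if (x$n_pairs_degenerate) {
    cat("  ", x$n_pairs_degenerate, "zero-variance pair(s) excluded\n")
  }
  invisible(x)
}

#' @export
summary.coexpression_network <- function(object, ...) {
  d <- object$nodes$degree
  cat("Degree distribution over", nrow(object$nodes), "connected nodes\n")
  if (length(d)) print(summary(d))
  invisible(object)
}

#' Select hub nodes by degree
#'
#' Ranks the connected nodes of a co-expression network by degree
#' (descending, ties broken lexicographically by id) and returns either the
#' top `k` nodes (`rule = "top_k"`) or the top `ceiling(fraction * n)`
#' (`rule = "top_fraction"`).
#'
#' @param network a `coexpression_network`.
#' @param rule `"top_k"` (default) or `"top_fraction"`.
#' @param k number of hubs for `top_k` (default 20).
#' @param fraction node fraction for `top_fraction` (default 0.05).
#' @return list of class `hub_set`: `hubs` (data frame `id`, `biotype`,
#'   `degree` in rank order), `rule`, `k_effective` and `composition`
#'   (biotype counts among hubs).
#' @export
select_hubs <- function(network, rule = c("top_k", "top_fraction"), k = 20,
                        fraction = 0.05) {
  rule <- match.arg(rule)
  stopifnot(inherits(network, "coexpression_network"))
  nodes <- network$nodes
  if (!nrow(nodes)) stop("empty network", call. = FALSE)
  if (rule == "top_k") {
    if (k < 1) stop("k must be >= 1", call. = FALSE)
    k_eff <- min(as.integer(k), nrow(nodes))
  } else {
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
    k_eff <- min(ceiling(fraction * nrow(nodes)), nrow(nodes))
  }
  ord <- order(-nodes$degree, nodes$id)
  hubs <- nodes[ord[seq_len(k_eff)], , drop = FALSE]
  rownames(hubs) <- NULL
  out <- list(hubs = hubs, rule = rule, k_effective = k_eff,
              composition = table(hubs$biotype))
  class(out) <- "hub_set"
  out
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("Top %d hub nodes by degree (%s)\n", x$k_effective, x$rule))
  print(utils::head(x$hubs, 25))
  cat("  composition:", paste(sprintf("%s=%d", names(x$composition),
                                      as.integer(x$composition)), collapse = ", "), "\n")
  invisible(x)
}
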