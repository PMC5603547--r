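#' Rich factor
#'
#' Observed pathway overlap divided by its expectation under the
#' hypergeometric null: `k * N / (K * n)` for `k` query genes in a pathway
#' of `K` genes, a query of size `n` and a universe of size `N` ("gene
#' count divided by the expected gene count").
#'
#' @param k overlap count.
#' @param K pathway size in the universe (> 0).
#' @param n query size (> 0).
#' @param N universe size (> 0).
#' @return non-negative ratio; 1 means exactly the expected overlap.
#' @export
rich_factor <- function(k, K, n, N) {
  if (any(K <= 0) || any(n <= 0) || any(N <= 0)) {
    stop("K, n and N must be positive", call. = FALSE)
  }
  k * N / (K * n)
}

#' Hypergeometric pathway over-representation
#'
#' Tests each gene set for over-representation of a query (e.g. the
#' differentially expressed mRNAs) against a gene universe, with the
#' upper-tail hypergeometric probability inclusive of the observed overlap:
#' `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`. P-values are BH-adjusted
#' across the tested pathways and each pathway gets a rich factor.
#'
#' Query genes outside the universe are dropped (and counted); pathways
#' with no gene in the universe are skipped.
#'
#' @param query character vector of gene ids of interest.
#' @param pathways named list of character vectors (pathway id -> gene ids),
#'   e.g. from [read_gmt()].
#' @param universe character vector of background gene ids (e.g. all
#'   expressed genes).
#' @param alpha FDR threshold recorded for downstream use (default 0.05).
#' @return data frame of class `enrichment_result`, sorted by p-value, with
#'   columns `pathway_id`, `N`, `K`, `n`, `k`, `pvalue`, `qvalue`,
#'   `rich_factor`; attributes `n_query_dropped`, `skipped_pathways`,
#'   `alpha`.
#' @export
hypergeom_enrich <- function(query, pathways, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(pathways)) stop("no pathways supplied", call. = FALSE)
  if (is.null(names(pathways)) || anyDuplicated(names(pathways))) {
    stop("pathways must be a uniquely named list", call. = FALSE)
  }
  query <- unique(as.character(query))
  n_dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  K <- vapply(pathways, function(g) length(intersect(g, universe)), integer(1))
  skipped <- names(pathways)[K == 0L]
  keep <- K > 0L
  k <- vapply(pathways[keep], function(g) length(intersect(g, query)), integer(1))
  K <- K[keep]
  p <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  out <- data.frame(
    pathway_id = names(pathways)[keep],
    N = N, K = K, n = n, k = k,
    pvalue = p,
    qvalue = bh_adjust(p),
    rich_factor = if (n > 0) rich_factor(k, K, n, N) else 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$pvalue, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- n_dropped
  attr(out, "skipped_pathways") <- skipped
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("Hypergeometric enrichment: %d pathways tested, %d at FDR < %g\n",
              nrow(x), sum(x$qvalue < alpha), alpha))
  print.data.frame(utils::head(x, 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more pathways\n")
  invisible(x)
}

#' lncRNA-pathway projection network
#'
#' Projects a lncRNA-mRNA co-expression network onto pathways: a lncRNA is
#' linked to a pathway when at least `min_support` of its co-expressed mRNA
#' neighbours belong to the pathway's gene set. With `require_enriched =
#' TRUE` (default) only pathways significant in `enrichment` (`qvalue <
#' alpha`) are eligible. Each edge records its supporting mRNAs, and a
#' per-pathway summary counts the regulatory lncRNAs, sorted descending.
#'
#' @param coexp a `coexpression_network` from [build_network()].
#' @param enrichment an `enrichment_result` from [hypergeom_enrich()]
#'   computed on the matching DE mRNA set (may be `NULL` when
#'   `require_enriched = FALSE`).
#' @param pathways named list of pathway gene sets (same annotation used for
#'   the enrichment).
#' @param alpha FDR cutoff defining "enriched" (default the `alpha` recorded
#'   in `enrichment`, else 0.05).
#' @param require_enriched restrict to enriched pathways (default `TRUE`).
#' @param min_support minimum number of supporting mRNAs per edge
#'   (default 1).
#' @return list of class `lnc_pathway_network`: `edges` (data frame
#'   `lnc_id`, `pathway_id`, `n_support`, `supporting_mrnas`
#'   (semicolon-separated)), `pathway_summary` (data frame `pathway_id`,
#'   `n_lncrnas`, descending), `n_lncrnas`, `n_pathways`, `params`.
#' @export
build_lnc_pathway_network <- function(coexp, enrichment = NULL, pathways,
                                      alpha = NULL, require_enriched = TRUE,
                                      min_support = 1) {
  stopifnot(inherits(coexp, "coexpression_network"))
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)
  if (require_enriched) {
    if (is.null(enrichment)) {
      stop("require_enriched = TRUE needs an enrichment result", call. = FALSE)
    }
    alpha <- alpha %||% attr(enrichment, "alpha") %||% 0.05
    eligible <- enrichment$pathway_id[enrichment$qvalue < alpha]
  } else {
    eligible <- names(pathways)
  }
  pathways <- pathways[intersect(names(pathways), eligible)]
  if (!nrow(coexp$edges)) {
    warning("empty co-expression network; projection is empty")
    neighbours <- list()
  } else {
    neighbours <- split(coexp$edges$mrna_id, coexp$edges$lnc_id)
  }
  rows <- list()
  for (lnc in names(neighbours)) {
    nb <- unique(neighbours[[lnc]])
    for (pw in names(pathways)) {
      supp <- sort(intersect(nb, pathways[[pw]]))
      if (length(supp) >= min_support) {
        rows[[length(rows) + 1L]] <- data.frame(
          lnc_id = lnc, pathway_id = pw, n_support = length(supp),
          supporting_mrnas = paste(supp, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(lnc_id = character(0), pathway_id = character(0),
               n_support = integer(0), supporting_mrnas = character(0),
               stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$lnc_id, edges$pathway_id), , drop = FALSE]
  rownames(edges) <- NULL
  cnt <- table(edges$pathway_id)
  pathway_summary <- data.frame(
    pathway_id = as.character(names(cnt) %||% character(0)),
    n_lncrnas = as.integer(cnt),
    stringsAsFactors = FALSE)
  pathway_summary <- pathway_summary[order(-pathway_summary$n_lncrnas,
                                           pathway_summary$pathway_id), , drop = FALSE]
  rownames(pathway_summary) <- NULL
  out <- list(
    edges = edges,
    pathway_summary = pathway_summary,
    n_lncrnas = length(unique(edges$lnc_id)),
    n_pathways = length(unique(edges$pathway_id)),
    params = list(require_enriched = require_enriched,
                  min_support = min_support, alpha = alpha)
  )
  class(out) <- "lnc_pathway_network"
  out
}

#' @export
print.lnc_pathway_network <- function(x, ...) {
  cat(sprintf("lncRNA-pathway network: %d lncRNAs linked to %d pathways (%d edges)\n",
              x$n_lncrnas, x$n_pathways, nrow(x$edges)))
  if (nrow(x$pathway_summary)) {
    print(utils::head(x$pathway_summary, 10))
    if (nrow(x$pathway_summary) > 10) {
      cat("  ...", nrow(x$pathway_summary) - 10, "more pathways\n")
    }
  }
  invisible(x)
}
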