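#' Pipeline configuration
#'
#' Collects the per-stage parameters of [run_pipeline()]: the simulation
#' config (or external inputs), thresholds for filtering, outlier
#' screening, differential expression, network construction, hub selection
#' and enrichment, and the output directory.
#'
#' @param sim a [sim_config()] describing the synthetic experiment; ignored
#'   when `counts` is supplied.
#' @param counts,samples,transcripts,pathways external inputs (count
#'   matrix, sample sheet with `sample`/`group`/`time` columns, transcript
#'   table, pathway list); all four must be given together.
#' @param min_cpm,min_samples expression filter (CPM threshold; samples
#'   required at that level, default the smallest group-by-time cell size).
#' @param mds_k,max_outliers MDS outlier rule (MAD multiplier, flag cap).
#' @param alpha,fc_min DE thresholds (FDR and fold change).
#' @param network_time time point whose DE sets and samples feed the
#'   network (default 24).
#' @param pool_samples correlate over all retained samples instead of only
#'   the `network_time` samples (default `FALSE`).
#' @param r_threshold,q_threshold,signed network thresholds, see
#'   [build_network()].
#' @param hub_k hubs reported from the network (default 20).
#' @param enrich_alpha FDR threshold defining enriched pathways.
#' @param min_support minimum supporting mRNAs per lncRNA-pathway edge.
#' @param out_dir directory for stage outputs; `NULL` (default) skips
#'   writing.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), counts = NULL, samples = NULL,
                            transcripts = NULL, pathways = NULL,
                            min_cpm = 1, min_samples = NULL,
                            mds_k = 3, max_outliers = 2,
                            alpha = 0.05, fc_min = 2.0,
                            network_time = 24, pool_samples = FALSE,
                            r_threshold = 0.99, q_threshold = 0.05,
                            signed = "positive", hub_k = 20,
                            enrich_alpha = 0.05, min_support = 1,
                            out_dir = NULL) {
  external <- !is.null(counts)
  if (external && (is.null(samples) || is.null(transcripts) || is.null(pathways))) {
    stop("external input needs counts, samples, transcripts and pathways",
         call. = FALSE)
  }
  stopifnot(min_cpm >= 0, mds_k >= 0, max_outliers >= 0,
            alpha > 0, alpha <= 1, fc_min >= 1,
            r_threshold >= -1, r_threshold <= 1,
            q_threshold > 0, q_threshold <= 1,
            hub_k >= 1, enrich_alpha > 0, enrich_alpha <= 1, min_support >= 1)
  cfg <- list(sim = sim, counts = counts, samples = samples,
              transcripts = transcripts, pathways = pathways,
              min_cpm = min_cpm, min_samples = min_samples,
              mds_k = mds_k, max_outliers = max_outliers,
              alpha = alpha, fc_min = fc_min,
              network_time = network_time, pool_samples = pool_samples,
              r_threshold = r_threshold, q_threshold = q_threshold,
              signed = signed, hub_k = hub_k,
              enrich_alpha = enrich_alpha, min_support = min_support,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

## Scalar parameter echo for provenance headers / the manifest.
flat_params <- function(config) {
  keep <- c("min_cpm", "min_samples", "mds_k", "max_outliers", "alpha",
            "fc_min", "network_time", "pool_samples", "r_threshold",
            "q_threshold", "signed", "hub_k", "enrich_alpha", "min_support")
  config[keep]
}

#' Run the full analysis pipeline
#'
#' Executes the stage order: simulate (or ingest) counts, CPM filter, MDS
#' outlier removal, per-time-point negative-binomial exact-test
#' differential expression with biotype calls, lncRNA-mRNA co-expression
#' network over the DE sets at `network_time`, hub selection,
#' hypergeometric pathway enrichment of the DE mRNAs against the expressed
#' background, and the lncRNA-pathway projection. All stage outputs are
#' optionally written under `config$out_dir` (TSV with provenance headers,
#' SIF/GraphML networks, GMT annotation, JSON manifest); rerunning with the
#' same config reproduces byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: stage outputs (`sim`,
#'   `filtered_counts`, `outliers`, `normalized`, `de` (per time point),
#'   `network`, `hubs`, `enrichment`, `projection`) plus a `manifest` of
#'   per-stage record counts, the seed and the parameter echo.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  external <- !is.null(config$counts)
  if (external) {
    sim <- NULL
    counts <- check_counts(config$counts)
    samples <- as.data.frame(config$samples)
    transcripts <- as.data.frame(config$transcripts)
    pathways <- config$pathways
    seed <- NA_integer_
  } else {
    sim <- simulate_experiment(config$sim)
    counts <- sim$counts
    samples <- sim$samples
    transcripts <- sim$transcripts
    pathways <- sim$pathways
    seed <- config$sim$seed
  }
  stopifnot(all(c("sample", "group", "time") %in% names(samples)),
            identical(sort(samples$sample), sort(colnames(counts))))
  samples <- samples[match(colnames(counts), samples$sample), ]
  cell <- interaction(samples$group, samples$time, drop = TRUE)
  min_samples <- config$min_samples %||% min(table(cell))

  ## expression filter, then outlier screen on the filtered matrix
  filtered <- filter_expressed(counts, min_cpm = config$min_cpm,
                               min_samples = min_samples)
  outliers <- mds_outliers(filtered, groups = as.character(cell),
                           n_flag_max = config$max_outliers, k = config$mds_k)
  keep <- setdiff(colnames(filtered), outliers$flagged)
  filtered <- filtered[, keep, drop = FALSE]
  samples <- samples[samples$sample %in% keep, ]

  ## biotype from the transcript classifier (falls back to supplied column
  ## when lengths/ORFs are absent)
  biotype <- if (all(c("length", "longest_orf_aa") %in% names(transcripts))) {
    cls <- classify_transcripts(transcripts)
    stats::setNames(cls$biotype, cls$id)
  } else {
    stats::setNames(transcripts$biotype, transcripts$id)
  }

  ## per-time-point two-group DE
  de <- list()
  for (tp in sort(unique(samples$time))) {
    idx <- samples$time == tp
    cts <- filtered[, samples$sample[idx], drop = FALSE]
    grp <- samples$group[idx]
    disp <- estimate_common_dispersion(cts, grp)
    res <- nb_exact_test(cts, grp, phi = disp$phi)
    de[[as.character(tp)]] <- call_degs(res, biotype = biotype,
                                        alpha = config$alpha,
                                        fc_min = config$fc_min)
  }

  ## co-expression network over the DE sets at network_time
  tp_key <- as.character(config$network_time)
  if (!tp_key %in% names(de)) {
    stop("network_time ", tp_key, " has no DE contrast", call. = FALSE)
  }
  det <- de[[tp_key]]
  de_lnc <- det$gene_id[det$call != "ns" & det$biotype %in% "lncRNA"]
  de_mrna <- det$gene_id[det$call != "ns" & det$biotype %in% "mRNA"]
  net_samples <- if (config$pool_samples) samples$sample else {
    samples$sample[samples$time == config$network_time]
  }
  norm <- median_of_ratios(filtered[, net_samples, drop = FALSE])
  network <- if (length(de_lnc) && length(de_mrna)) {
    build_network(norm$normalized, de_lnc, de_mrna,
                  r_threshold = config$r_threshold,
                  q_threshold = config$q_threshold, signed = config$signed)
  } else {
    warning("no DE lncRNA-mRNA pairs at the network time point; empty network")
    NULL
  }
  hubs <- if (!is.null(network) && nrow(network$nodes)) {
    select_hubs(network, k = config$hub_k)
  } else NULL

  ## enrichment of DE mRNAs against the expressed mRNA background
  universe <- rownames(filtered)[biotype[rownames(filtered)] %in% "mRNA"]
  enrichment <- if (length(pathways) && length(universe)) {
    hypergeom_enrich(de_mrna, pathways, universe, alpha = config$enrich_alpha)
  } else NULL
  projection <- if (!is.null(network) && nrow(network$edges) &&
                    !is.null(enrichment)) {
    build_lnc_pathway_network(network, enrichment, pathways,
                              alpha = config$enrich_alpha,
                              min_support = config$min_support)
  } else NULL

  manifest <- list(
    version = as.character(utils::packageVersion("lncnet")),
    seed = seed,
    params = flat_params(config),
    stages = list(
      genes_input = nrow(counts),
      genes_expressed = nrow(filtered),
      samples_retained = ncol(filtered),
      outliers_flagged = length(outliers$flagged),
      de_counts = lapply(de, function(d) sum(d$call != "ns")),
      network_edges = if (is.null(network)) 0L else nrow(network$edges),
      network_lncrnas = if (is.null(network)) 0L else
        sum(network$nodes$biotype == "lncRNA"),
      network_mrnas = if (is.null(network)) 0L else
        sum(network$nodes$biotype == "mRNA"),
      pathways_tested = if (is.null(enrichment)) 0L else nrow(enrichment),
      pathways_enriched = if (is.null(enrichment)) 0L else
        sum(enrichment$qvalue < config$enrich_alpha),
      projection_lncrnas = if (is.null(projection)) 0L else projection$n_lncrnas,
      projection_pathways = if (is.null(projection)) 0L else projection$n_pathways
    )
  )
  out <- list(sim = sim, filtered_counts = filtered, outliers = outliers,
              normalized = norm, de = de, network = network, hubs = hubs,
              enrichment = enrichment, projection = projection,
              biotype = biotype, manifest = manifest, config = config)
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

## Write every stage table under out_dir; deterministic given the config.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- result$manifest$seed
  params <- result$manifest$params
  p <- function(f) file.path(out_dir, f)
  write_counts(result$filtered_counts, p("counts_filtered.tsv"),
               seed = seed, params = params)
  for (tp in names(result$de)) {
    write_tsv(as.data.frame(result$de[[tp]]), p(sprintf("de_%sh.tsv", tp)),
              seed = seed, params = params)
  }
  if (!is.null(result$network)) {
    write_tsv(result$network$edges, p("network_edges.tsv"),
              seed = seed, params = params)
    write_tsv(result$network$nodes, p("network_nodes.tsv"),
              seed = seed, params = params)
    export_sif(result$network, p("network.sif"))
    export_graphml(result$network, p("network.graphml"))
  }
  if (!is.null(result$hubs)) {
    write_tsv(result$hubs$hubs, p("hubs.tsv"), seed = seed, params = params)
  }
  if (!is.null(result$enrichment)) {
    write_tsv(as.data.frame(result$enrichment), p("enrichment.tsv"),
              seed = seed, params = params)
  }
  if (!is.null(result$projection)) {
    write_tsv(result$projection$edges, p("lnc_pathway_edges.tsv"),
              seed = seed, params = params)
    write_tsv(result$projection$pathway_summary, p("pathway_lncrna_counts.tsv"),
              seed = seed, params = params)
    export_sif(result$projection, p("lnc_pathway.sif"))
  }
  if (length(result$sim$pathways %||% list())) {
    write_gmt(result$sim$pathways, p("pathways.gmt"))
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$manifest$stages
  cat("lncnet pipeline result\n")
  cat(sprintf("  %d/%d genes expressed, %d samples retained (%d outliers removed)\n",
              s$genes_expressed, s$genes_input, s$samples_retained,
              s$outliers_flagged))
  for (tp in names(x$de)) {
    cat(sprintf("  DE at %s h: %d called\n", tp, sum(x$de[[tp]]$call != "ns")))
  }
  cat(sprintf("  network: %d edges (%d lncRNAs, %d mRNAs); %d/%d pathways enriched\n",
              s$network_edges, s$network_lncrnas, s$network_mrnas,
              s$pathways_enriched, s$pathways_tested))
  cat(sprintf("  projection: %d lncRNAs x %d pathways\n",
              s$projection_lncrnas, s$projection_pathways))
  invisible(x)
}
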