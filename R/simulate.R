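#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic count generator.
#' The defaults emulate a two-treatment (vehicle control vs estradiol), two
#' time point (24 h, 72 h) muscle RNA-seq design with four replicates per
#' cell, negative-binomial counts, a minority of genes differentially
#' expressed at 24 h with planted |log2FC| >= 1, latent-factor co-expression
#' modules tying lncRNAs to mRNAs, and pathway annotations in which a subset
#' of pathways is constructed to be enriched among the planted DE mRNAs.
#'
#' @param n_mrna,n_lncrna numbers of mRNA and lncRNA transcripts.
#' @param n_samples_per_group replicates per treatment-by-time cell
#'   (default 4).
#' @param groups treatment labels; the second is the treated group.
#' @param times time points in hours.
#' @param base_mean_log_mu,base_mean_log_sigma log-normal parameters of the
#'   per-gene baseline mean `mu_g`.
#' @param dispersion NB dispersion `phi >= 0` (`phi = 0` gives Poisson
#'   counts).
#' @param frac_de fraction of genes differentially expressed at `de_time`.
#' @param de_log2fc_min,de_log2fc_max planted |log2FC| range (uniform draw);
#'   the default minimum 1 matches a 2-fold call threshold.
#' @param de_time time point at which DE effects are planted (default 24;
#'   the other time point stays null, emulating a transient response).
#' @param n_modules number of co-expression modules.
#' @param module_size_lnc,module_size_mrna lncRNAs and mRNAs per module
#'   (module gene sets are disjoint and non-DE).
#' @param module_strength latent-factor scale `lambda >= 0`; each module
#'   multiplies its genes' means by `exp(lambda * f_j)` with a shared
#'   per-sample standard-normal factor `f_j`.
#' @param n_pathways,pathway_size number and size of annotated gene sets
#'   (over mRNAs).
#' @param n_enriched_pathways how many pathways are constructed to be
#'   enriched in DE mRNAs.
#' @param frac_pathway_de_overlap fraction of each enriched pathway drawn
#'   from planted DE mRNAs.
#' @param lib_size_factor_range range of the uniform per-sample library
#'   size factors `s_j` (non-trivial normalization by default).
#' @param seed integer RNG seed governing all draws.
#' @return validated list of class `sim_config`.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_mrna = 2000, n_lncrna = 400, n_samples_per_group = 4,
                       groups = c("CTRL", "E2"), times = c(24, 72),
                       base_mean_log_mu = log(100), base_mean_log_sigma = 1,
                       dispersion = 0.1, frac_de = 0.1,
                       de_log2fc_min = 1, de_log2fc_max = 3, de_time = 24,
                       n_modules = 3, module_size_lnc = 10,
                       module_size_mrna = 20, module_strength = 3,
                       n_pathways = 20, n_enriched_pathways = 5,
                       pathway_size = 50, frac_pathway_de_overlap = 0.5,
                       lib_size_factor_range = c(0.7, 1.3), seed = 1) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_samples_per_group = as.integer(n_samples_per_group),
              groups = as.character(groups), times = as.numeric(times),
              base_mean_log_mu = base_mean_log_mu,
              base_mean_log_sigma = base_mean_log_sigma,
              dispersion = dispersion, frac_de = frac_de,
              de_log2fc_min = de_log2fc_min, de_log2fc_max = de_log2fc_max,
              de_time = de_time,
              n_modules = as.integer(n_modules),
              module_size_lnc = as.integer(module_size_lnc),
              module_size_mrna = as.integer(module_size_mrna),
              module_strength = module_strength,
              n_pathways = as.integer(n_pathways),
              n_enriched_pathways = as.integer(n_enriched_pathways),
              pathway_size = as.integer(pathway_size),
              frac_pathway_de_overlap = frac_pathway_de_overlap,
              lib_size_factor_range = as.numeric(lib_size_factor_range),
              seed = as.integer(seed))
  if (cfg$n_mrna < 1 || cfg$n_lncrna < 1) stop("need positive gene counts", call. = FALSE)
  if (cfg$n_samples_per_group < 1) stop("need >= 1 sample per group", call. = FALSE)
  if (length(cfg$groups) != 2L) stop("exactly two treatment groups", call. = FALSE)
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop("frac_de must be in [0, 1]", call. = FALSE)
  if (cfg$de_log2fc_min < 0 || cfg$de_log2fc_max < cfg$de_log2fc_min) {
    stop("need 0 <= de_log2fc_min <= de_log2fc_max", call. = FALSE)
  }
  if (cfg$module_strength < 0) stop("module_strength must be >= 0", call. = FALSE)
  if (cfg$n_modules < 0 || cfg$module_size_lnc < 0 || cfg$module_size_mrna < 0) {
    stop("module counts must be >= 0", call. = FALSE)
  }
  if (cfg$n_modules * cfg$module_size_lnc > cfg$n_lncrna ||
      cfg$n_modules * cfg$module_size_mrna > cfg$n_mrna) {
    stop("module sizes exceed available genes", call. = FALSE)
  }
  if (cfg$n_enriched_pathways > cfg$n_pathways) {
    stop("n_enriched_pathways exceeds n_pathways", call. = FALSE)
  }
  if (cfg$pathway_size > cfg$n_mrna) stop("pathway_size exceeds n_mrna", call. = FALSE)
  if (cfg$frac_pathway_de_overlap < 0 || cfg$frac_pathway_de_overlap > 1) {
    stop("frac_pathway_de_overlap must be in [0, 1]", call. = FALSE)
  }
  if (length(cfg$lib_size_factor_range) != 2L ||
      any(cfg$lib_size_factor_range <= 0) ||
      diff(cfg$lib_size_factor_range) < 0) {
    stop("lib_size_factor_range must be positive and increasing", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_mrna, "mRNAs +", x$n_lncrna, "lncRNAs,",
      length(x$groups) * length(x$times), "cells x", x$n_samples_per_group,
      "replicates\n")
  cat(sprintf("  NB dispersion %.3g, %.0f%% DE at %g h (|log2FC| in [%g, %g])\n",
              x$dispersion, 100 * x$frac_de, x$de_time,
              x$de_log2fc_min, x$de_log2fc_max))
  cat(sprintf("  %d modules (%d lnc + %d mRNA each, strength %.2g); %d pathways (%d enriched)\n",
              x$n_modules, x$module_size_lnc, x$module_size_mrna,
              x$module_strength, x$n_pathways, x$n_enriched_pathways))
  cat("  seed", x$seed, "\n")
  invisible(x)
}

#' Simulate a two-group, two-time RNA-seq experiment with planted truth
#'
#' Draws a gene-by-sample count matrix from the model
#' `count_gj ~ NB(mean = s_j * mu_g * 2^(x_j * beta_g) * exp(lambda *
#' f_{m(g),j}), dispersion = phi)`, where `s_j` is a uniform library size
#' factor, `mu_g` a log-normal baseline, `x_j` the treated-at-`de_time`
#' indicator, `beta_g` the planted log2 fold change (0 for non-DE genes),
#' and `f_{m,j}` a per-sample standard-normal latent factor shared by the
#' genes of module `m` (zero for unassigned genes). Alongside the counts it
#' emits the sample sheet, a transcript table with lengths and ORF lengths
#' consistent with each biotype, pathway annotations over the mRNAs (a
#' subset constructed to be enriched among the planted DE mRNAs), and the
#' full ground truth for recovery testing.
#'
#' DE genes, module members (disjoint from DE genes and from each other)
#' and pathway contents are resampled from the configured seed, so the same
#' config reproduces the identical experiment bit for bit.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_experiment` with elements
#' \describe{
#'   \item{counts}{integer matrix, genes x samples, with dimnames.}
#'   \item{samples}{data frame `sample`, `group`, `time`, `replicate`.}
#'   \item{transcripts}{data frame `id`, `biotype`, `length`,
#'     `longest_orf_aa`.}
#'   \item{pathways}{named list of mRNA id vectors.}
#'   \item{truth}{list: `de_genes` (data frame `gene_id`, `log2fc`),
#'     `module_assignments` (named vector gene -> module),
#'     `pathway_assignments` (the annotation list), `enriched_pathways`
#'     (character), `size_factors` (`s_j`), `base_means` (`mu_g`).}
#' }
#' @examples
#' sim <- simulate_experiment(sim_config(n_mrna = 50, n_lncrna = 10, seed = 7))
#' dim(sim$counts)
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gene_ids <- c(sprintf("mRNA_%04d", seq_len(config$n_mrna)),
                sprintf("lnc_%04d", seq_len(config$n_lncrna)))
  n_genes <- length(gene_ids)
  is_mrna <- rep(c(TRUE, FALSE), c(config$n_mrna, config$n_lncrna))

  samples <- expand.grid(replicate = seq_len(config$n_samples_per_group),
                         group = config$groups, time = config$times,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("group", "time", "replicate")]
  samples$sample <- sprintf("%s_%gh_R%d", samples$group, samples$time,
                            samples$replicate)
  samples <- samples[, c("sample", "group", "time", "replicate")]
  n_samples <- nrow(samples)

  ## planted DE genes (both biotypes), then disjoint modules among non-DE genes
  n_de <- round(config$frac_de * n_genes)
  de_idx <- sort(sample.int(n_genes, n_de))
  beta <- numeric(n_genes)
  if (n_de > 0) {
    mag <- stats::runif(n_de, config$de_log2fc_min, config$de_log2fc_max)
    beta[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  module <- rep(NA_integer_, n_genes)
  free_lnc <- setdiff(which(!is_mrna), de_idx)
  free_mrna <- setdiff(which(is_mrna), de_idx)
  if (config$n_modules > 0) {
    need_l <- config$n_modules * config$module_size_lnc
    need_m <- config$n_modules * config$module_size_mrna
    if (length(free_lnc) < need_l || length(free_mrna) < need_m) {
      stop("not enough non-DE genes to fill the modules", call. = FALSE)
    }
    pick_l <- sample(free_lnc, need_l)
    pick_m <- sample(free_mrna, need_m)
    module[pick_l] <- rep(seq_len(config$n_modules), each = config$module_size_lnc)
    module[pick_m] <- rep(seq_len(config$n_modules), each = config$module_size_mrna)
  }

  mu <- stats::rlnorm(n_genes, config$base_mean_log_mu, config$base_mean_log_sigma)
  s <- stats::runif(n_samples, config$lib_size_factor_range[1],
                    config$lib_size_factor_range[2])
  x_treated <- as.numeric(samples$group == config$groups[2] &
                            samples$time == config$de_time)
  f <- if (config$n_modules > 0) {
    matrix(stats::rnorm(config$n_modules * n_samples),
           config$n_modules, n_samples)
  } else matrix(0, 0, n_samples)

  mean_mat <- outer(mu, s) * 2^(beta %o% x_treated)
  if (config$n_modules > 0) {
    assigned <- which(!is.na(module))
    mean_mat[assigned, ] <- mean_mat[assigned, , drop = FALSE] *
      exp(config$module_strength * f[module[assigned], , drop = FALSE])
  }
  counts <- if (config$dispersion <= 1e-12) {
    matrix(stats::rpois(n_genes * n_samples, mean_mat), n_genes, n_samples)
  } else {
    matrix(stats::rnbinom(n_genes * n_samples, mu = mean_mat,
                          size = 1 / config$dispersion), n_genes, n_samples)
  }
  dimnames(counts) <- list(gene_ids, samples$sample)

  ## transcript table: lengths and ORFs consistent with each biotype
  orf <- ifelse(is_mrna,
                sample(100:600, n_genes, replace = TRUE),
                sample(0:99, n_genes, replace = TRUE))
  len_min <- pmax(ifelse(is_mrna, 300L, 200L), 3L * orf + 3L)
  tr_len <- len_min + sample(0:2500, n_genes, replace = TRUE)
  transcripts <- data.frame(id = gene_ids,
                            biotype = ifelse(is_mrna, "mRNA", "lncRNA"),
                            length = tr_len, longest_orf_aa = orf,
                            stringsAsFactors = FALSE)

  ## pathway annotation over mRNAs; the first n_enriched_pathways sets are
  ## seeded with planted DE mRNAs
  mrna_ids <- gene_ids[is_mrna]
  de_mrna <- intersect(gene_ids[de_idx], mrna_ids)
  non_de_mrna <- setdiff(mrna_ids, de_mrna)
  pathways <- list()
  if (config$n_pathways > 0) {
    for (i in seq_len(config$n_pathways)) {
      if (i <= config$n_enriched_pathways && length(de_mrna)) {
        n_hit <- min(round(config$frac_pathway_de_overlap * config$pathway_size),
                     length(de_mrna))
        n_rest <- min(config$pathway_size - n_hit, length(non_de_mrna))
        genes <- c(sample(de_mrna, n_hit), sample(non_de_mrna, n_rest))
      } else {
        genes <- sample(mrna_ids, config$pathway_size)
      }
      pathways[[sprintf("path_%02d", i)]] <- sort(genes)
    }
  }

  truth <- list(
    de_genes = data.frame(gene_id = gene_ids[de_idx],
                          log2fc = beta[de_idx], stringsAsFactors = FALSE),
    module_assignments = stats::setNames(module[!is.na(module)],
                                         gene_ids[!is.na(module)]),
    pathway_assignments = pathways,
    enriched_pathways = if (length(de_mrna)) {
      names(pathways)[seq_len(min(config$n_enriched_pathways, length(pathways)))]
    } else character(0),
    size_factors = stats::setNames(s, samples$sample),
    base_means = stats::setNames(mu, gene_ids)
  )

  out <- list(counts = counts, samples = samples, transcripts = transcripts,
              pathways = pathways, truth = truth, config = config)
  class(out) <- "sim_experiment"
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Simulated experiment:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat(" ", nrow(x$truth$de_genes), "planted DE genes,",
      length(unique(x$truth$module_assignments)), "modules,",
      length(x$pathways), "pathways (", length(x$truth$enriched_pathways),
      "enriched )\n")
  invisible(x)
}
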