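test_that("identical seeds give bit-identical experiments", {
  cfg <- sim_config(n_mrna = 80, n_lncrna = 30, n_modules = 2,
                    module_size_lnc = 3, module_size_mrna = 6,
                    pathway_size = 20, seed = 7)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pathways, s2$pathways)
  s3 <- simulate_experiment(sim_config(n_mrna = 80, n_lncrna = 30,
                                       n_modules = 2, module_size_lnc = 3,
                                       module_size_mrna = 6,
                                       pathway_size = 20, seed = 8))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("null configuration yields Poisson-like counts centred on zero log-ratio", {
  cfg <- sim_config(n_mrna = 1500, n_lncrna = 500, frac_de = 0,
                    module_strength = 0, n_modules = 0, dispersion = 0,
                    times = 24, n_pathways = 0, n_enriched_pathways = 0,
                    seed = 9)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == floor(sim$counts)))
  expect_true(all(colSums(sim$counts) > 0))
  g <- sim$samples$group
  ## compare on CPM so the per-sample library factors cancel
  x <- cpm(sim$counts)
  ratio <- log2((rowMeans(x[, g == "E2"]) + 0.5) /
                  (rowMeans(x[, g == "CTRL"]) + 0.5))
  expect_lt(abs(median(ratio)), 0.05)
  expect_equal(nrow(sim$truth$de_genes), 0)
})

test_that("positive dispersion produces overdispersed counts", {
  cfg <- sim_config(n_mrna = 1000, n_lncrna = 200, frac_de = 0,
                    n_modules = 0, dispersion = 0.3, times = 24,
                    n_pathways = 0, n_enriched_pathways = 0, seed = 10)
  sim <- simulate_experiment(cfg)
  v <- apply(sim$counts, 1, var)
  m <- rowMeans(sim$counts)
  expect_gt(mean(v > m), 0.9)
})

test_that("within-module correlation exceeds between-module correlation", {
  cfg <- sim_config(n_mrna = 100, n_lncrna = 40, n_samples_per_group = 2,
                    times = c(24, 72), n_modules = 2, module_size_lnc = 5,
                    module_size_mrna = 8, module_strength = 1.5,
                    frac_de = 0, n_pathways = 0, n_enriched_pathways = 0,
                    seed = 11)
  sim <- simulate_experiment(cfg)  # 8 samples
  mod <- sim$truth$module_assignments
  lg <- log2(sim$counts + 1)
  lnc <- grep("^lnc", names(mod), value = TRUE)
  mr <- grep("^mRNA", names(mod), value = TRUE)
  rmat <- cor(t(lg[lnc, ]), t(lg[mr, ]))
  same <- outer(mod[lnc], mod[mr], "==")
  expect_gt(mean(rmat[same]), mean(rmat[!same]))
})

test_that("planted structure is internally consistent", {
  cfg <- sim_config(n_mrna = 200, n_lncrna = 80, seed = 12)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$de_genes$gene_id %in% rownames(sim$counts)))
  expect_true(all(abs(sim$truth$de_genes$log2fc) >= cfg$de_log2fc_min))
  ## modules are disjoint from each other and from DE genes
  mod <- sim$truth$module_assignments
  expect_false(anyDuplicated(names(mod)) > 0)
  expect_length(intersect(names(mod), sim$truth$de_genes$gene_id), 0)
  ## pathway genes are mRNAs; enriched pathways overlap planted DE mRNAs
  all_pw <- unique(unlist(sim$pathways))
  expect_true(all(startsWith(all_pw, "mRNA")))
  de_mrna <- grep("^mRNA", sim$truth$de_genes$gene_id, value = TRUE)
  for (pw in sim$truth$enriched_pathways) {
    expect_gte(length(intersect(sim$pathways[[pw]], de_mrna)),
               0.4 * cfg$frac_pathway_de_overlap * cfg$pathway_size)
  }
  ## sample sheet matches the count columns
  expect_identical(sim$samples$sample, colnames(sim$counts))
  expect_equal(nrow(sim$samples),
               cfg$n_samples_per_group * length(cfg$groups) * length(cfg$times))
})

test_that("sim_config rejects invalid parameter combinations", {
  expect_error(sim_config(n_mrna = 0), "positive gene counts")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(frac_de = 1.5), "frac_de")
  expect_error(sim_config(n_modules = 10, module_size_lnc = 100,
                          n_lncrna = 50), "exceed")
  expect_error(sim_config(n_pathways = 2, n_enriched_pathways = 3),
               "n_enriched_pathways")
  expect_error(sim_config(lib_size_factor_range = c(-1, 1)), "positive")
})

test_that("DE effects are planted only at the configured time point", {
  cfg <- sim_config(n_mrna = 800, n_lncrna = 200, dispersion = 0.05,
                    frac_de = 0.2, de_log2fc_min = 2, de_log2fc_max = 2,
                    n_modules = 0, n_pathways = 0, n_enriched_pathways = 0,
                    seed = 13)
  sim <- simulate_experiment(cfg)
  s <- sim$samples
  de <- sim$truth$de_genes
  for (tp in c(24, 72)) {
    e2 <- rowMeans(sim$counts[de$gene_id, s$sample[s$time == tp & s$group == "E2"]])
    ct <- rowMeans(sim$counts[de$gene_id, s$sample[s$time == tp & s$group == "CTRL"]])
    obs <- log2((e2 + 0.5) / (ct + 0.5))
    if (tp == 24) {
      expect_gt(cor(obs, de$log2fc), 0.9)
    } else {
      expect_lt(mean(abs(obs)), 0.5)
    }
  }
})
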