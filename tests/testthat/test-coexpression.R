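test_that("pearson_r matches the covariance definition and handles edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2, 4, 5, 9)
  expect_equal(pearson_r(x, y), bf_pearson(x, y), tolerance = 1e-12)
  expect_true(is.na(pearson_r(x, rep(1, 4))))
  expect_error(pearson_r(x, 1:3), "mismatch")
  expect_error(pearson_r(1:2, 1:2), "3 paired")
})

test_that("corr_pvalue follows the t-distribution tail", {
  expect_equal(corr_pvalue(0, 10), 1)
  expect_equal(corr_pvalue(1, 10), 0)
  expect_lt(corr_pvalue(0.99, 6), 0.001)
  ## monotone decreasing in |r| at fixed n
  rs <- seq(0, 0.95, by = 0.05)
  ps <- corr_pvalue(rs, 8)
  expect_true(all(diff(ps) < 0))
  ## equals the textbook formula
  r <- 0.8; n <- 12
  expect_equal(corr_pvalue(r, n),
               2 * pt(r * sqrt(n - 2) / sqrt(1 - r^2), n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(corr_pvalue(0.5, 2), "n >= 3")
})

## small labelled expression matrix: 2 lnc + 3 mrna over n samples
toy_expr <- function(n = 10, seed = 31) {
  set.seed(seed)
  shared <- rnorm(n)
  expr <- rbind(
    lnc_a = shared + rnorm(n, sd = 0.01),
    lnc_b = rnorm(n),
    m_1 = shared + rnorm(n, sd = 0.01),
    m_2 = rnorm(n),
    m_3 = rnorm(n))
  colnames(expr) <- sprintf("s%02d", seq_len(n))
  expr
}

test_that("build_network keeps near-duplicate profiles and drops noise", {
  expr <- toy_expr()
  net <- build_network(expr, c("lnc_a", "lnc_b"), c("m_1", "m_2", "m_3"),
                       log2 = FALSE)
  expect_true(any(net$edges$lnc_id == "lnc_a" & net$edges$mrna_id == "m_1"))
  expect_false(any(net$edges$lnc_id == "lnc_b"))
  expect_equal(net$n_pairs_tested, 6)
})

test_that("network edges equal a brute-force recount of passing pairs", {
  set.seed(32)
  expr <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(c(sprintf("lnc_%02d", 1:8),
                                   sprintf("m_%02d", 1:12)),
                                 sprintf("s%02d", 1:12)))
  lnc <- sprintf("lnc_%02d", 1:8)
  mr <- sprintf("m_%02d", 1:12)
  ## permissive thresholds so a non-trivial subset passes
  net <- build_network(expr, lnc, mr, r_threshold = 0.2, q_threshold = 0.8,
                       log2 = FALSE)
  pairs <- expand.grid(l = lnc, m = mr, stringsAsFactors = FALSE)
  r <- mapply(function(l, m) pearson_r(expr[l, ], expr[m, ]), pairs$l, pairs$m)
  p <- corr_pvalue(r, 12)
  q <- bf_bh(p)
  want <- pairs[r >= 0.2 & q < 0.8, ]
  got <- net$edges[, c("lnc_id", "mrna_id")]
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$lnc_id, got$mrna_id),
                  paste(want$l, want$m))
  ## bipartite handshake
  expect_equal(sum(net$nodes$degree[net$nodes$biotype == "lncRNA"]),
               nrow(net$edges))
  expect_equal(sum(net$nodes$degree[net$nodes$biotype == "mRNA"]),
               nrow(net$edges))
})

test_that("build_network is invariant to gene and sample ordering", {
  set.seed(33)
  expr <- toy_expr(12, seed = 33)
  lnc <- c("lnc_a", "lnc_b"); mr <- c("m_1", "m_2", "m_3")
  net1 <- build_network(expr, lnc, mr, r_threshold = 0.3, q_threshold = 0.9,
                        log2 = FALSE)
  perm_g <- sample(nrow(expr)); perm_s <- sample(ncol(expr))
  net2 <- build_network(expr[perm_g, perm_s], rev(lnc), sample(mr),
                        r_threshold = 0.3, q_threshold = 0.9, log2 = FALSE)
  expect_equal(net1$edges, net2$edges)
  expect_equal(net1$nodes, net2$nodes)
})

test_that("build_network rejects invalid candidate sets", {
  expr <- toy_expr()
  expect_error(build_network(expr, "lnc_a", "absent"), "absent")
  expect_error(build_network(expr, "lnc_a", "lnc_a"), "disjoint")
  expect_error(build_network(expr[, 1:2], "lnc_a", "m_1"), "3 samples")
})

test_that("module recall rises with module strength on a seeded grid", {
  recall <- sapply(c(0.5, 3, 6), function(strength) {
    sim <- simulate_experiment(sim_config(
      n_mrna = 150, n_lncrna = 60, n_modules = 2, module_size_lnc = 5,
      module_size_mrna = 8, module_strength = strength, frac_de = 0,
      n_pathways = 0, n_enriched_pathways = 0, seed = 77))
    norm <- median_of_ratios(sim$counts)$normalized
    net <- build_network(norm, grep("^lnc", rownames(norm), value = TRUE),
                         grep("^mRNA", rownames(norm), value = TRUE))
    mod <- sim$truth$module_assignments
    within <- outer(mod[grep("^lnc", names(mod), value = TRUE)],
                    mod[grep("^mRNA", names(mod), value = TRUE)], "==")
    found <- paste(net$edges$lnc_id, net$edges$mrna_id)
    truth <- paste(rep(rownames(within), ncol(within)),
                   rep(colnames(within), each = nrow(within)))[within]
    mean(truth %in% found)
  })
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], recall[1])
})

test_that("select_hubs ranks by degree with lexicographic ties", {
  fake <- structure(list(
    edges = data.frame(),
    nodes = data.frame(id = c("e", "d", "c", "b", "a"),
                       biotype = c("lncRNA", "mRNA", "lncRNA", "mRNA", "lncRNA"),
                       degree = c(4L, 3L, 2L, 2L, 1L),
                       stringsAsFactors = FALSE)),
    class = "coexpression_network")
  top2 <- select_hubs(fake, k = 2)
  expect_equal(top2$hubs$id, c("e", "d"))

  tied <- fake
  tied$nodes$degree <- rep(2L, 5)
  expect_equal(select_hubs(tied, k = 2)$hubs$id, c("a", "b"))

  ## top_fraction uses a ceiling: 5% of 365 nodes -> 19
  big <- fake
  big$nodes <- data.frame(id = sprintf("n%03d", 1:365),
                          biotype = "lncRNA", degree = 365:1,
                          stringsAsFactors = FALSE)
  expect_equal(select_hubs(big, rule = "top_fraction",
                           fraction = 0.05)$k_effective, 19)
  expect_error(select_hubs(fake, k = 0), "k must be")
  expect_error(select_hubs(fake, rule = "top_fraction", fraction = 0), "fraction")
})
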