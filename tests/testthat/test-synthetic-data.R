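test_that("generators are bit-reproducible under a fixed seed", {
  ps <- peak_set(rep("chr1", 5), (0:4) * 2000, (1:5) * 2000,
                 id = sprintf("p%d", 1:5))
  a <- generate_accessibility_matrix(50, ps, baseline_rate = 0.2, seed = 42)
  b <- generate_accessibility_matrix(50, ps, baseline_rate = 0.2, seed = 42)
  expect_identical(as.matrix(a$matrix$entries), as.matrix(b$matrix$entries))
  e1 <- generate_expression_table(200, seed = 7)
  e2 <- generate_expression_table(200, seed = 7)
  expect_identical(e1$expression, e2$expression)
  l1 <- generate_binding_landscape(c(chr1 = 1e7), 20, 25, 8, seed = 3)
  l2 <- generate_binding_landscape(c(chr1 = 1e7), 20, 25, 8, seed = 3)
  expect_identical(as.data.frame(l1$stat1), as.data.frame(l2$stat1))
  f1 <- generate_feature_matrix(c(Poised = 10), noise_sd = 0.3, seed = 5)
  f2 <- generate_feature_matrix(c(Poised = 10), noise_sd = 0.3, seed = 5)
  expect_identical(f1$features, f2$features)
  # generators do not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_expression_table(50, seed = 9))
  expect_identical(runif(1), r1)
})

test_that("unplanted peaks are independent and column means match the rate", {
  n_peaks <- 40
  am <- null_matrix(2000, n_peaks, rate = 0.1, seed = 21)
  set.seed(22)
  pr <- replicate(100, sample(n_peaks, 2))
  rs <- vapply(seq_len(100), function(k) {
    pairwise_correlation(am$entries, pr[1, k], pr[2, k])
  }, 1)
  expect_lt(mean(abs(rs), na.rm = TRUE), 0.05)
  cm <- Matrix::colMeans(am$entries)
  expect_true(all(abs(cm - 0.1) < 0.02))
})

test_that("planted-pair correlation grows monotonically with effect strength", {
  ps <- peak_set(rep("chr1", 2), c(0, 2000), c(2000, 4000),
                 id = c("s", "t"))
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mean_r <- vapply(grid, function(eff) {
    rs <- vapply(1:20, function(seed) {
      pl <- data.frame(site_id = "s", tile_id = "t", effect = eff)
      sim <- generate_accessibility_matrix(
        800, ps, pl, baseline_rate = 0.1,
        fragment_count_distribution = list(meanlog = log(5000), sdlog = 0),
        groups = data.frame(cell_type = "ESC", condition = "0h"),
        seed = seed)
      pairwise_correlation(sim$matrix$entries, "s", "t")
    }, 1)
    mean(rs)
  }, 1)
  expect_true(all(diff(mean_r) > 0))
  expect_lt(abs(mean_r[1]), 0.02)
})

test_that("a strong planted link exceeds the null threshold in >= 95% of seeds", {
  # Monte-Carlo oracle over seeds: effect 0.9, baseline 0.1, 2,700 cells,
  # against the analytic null 99th percentile for binary columns
  thr <- qnorm(0.99) / sqrt(2700 - 1)
  ps <- peak_set(rep("chr1", 2), c(0, 2000), c(2000, 4000), id = c("s", "t"))
  hits <- vapply(1:100, function(seed) {
    pl <- data.frame(site_id = "s", tile_id = "t", effect = 0.9)
    sim <- generate_accessibility_matrix(
      2700, ps, pl, baseline_rate = 0.1,
      fragment_count_distribution = list(meanlog = log(5000), sdlog = 0),
      groups = data.frame(cell_type = "ESC", condition = "0h"), seed = seed)
    pairwise_correlation(sim$matrix$entries, "s", "t") > thr
  }, TRUE)
  expect_gte(sum(hits), 95)
})

test_that("degenerate accessibility rates and bad links are rejected", {
  ps <- peak_set("chr1", 0, 2000, id = "p")
  expect_error(generate_accessibility_matrix(10, ps, baseline_rate = 0),
               "baseline_rate")
  expect_error(generate_accessibility_matrix(10, ps, baseline_rate = 1),
               "baseline_rate")
  expect_error(generate_accessibility_matrix(
    10, ps, planted_links = data.frame(site_id = "p", tile_id = "nope",
                                       effect = 0.5),
    baseline_rate = 0.1), "unknown peak")
})

test_that("expression generator produces a recoverable mixture and ISG truth", {
  gen <- generate_expression_table(
    10000, active_params = c(mean = 5, sd = 1, weight = 0.5),
    repressed_params = c(mean = 1, sd = 1, weight = 0.5),
    isg_fraction = 0, noise_sd = 0, seed = 31)
  fit <- fit_two_gaussians(log10(gen$expression[["0h"]]))
  expect_lt(abs(fit$mu_repressed - 1), 0.1)
  expect_lt(abs(fit$mu_active - 5), 0.1)
  expect_equal(sum(gen$truth$isg), 0)
  # induction_fold = 1: treated equals untreated up to the noise model
  gen1 <- generate_expression_table(500, isg_fraction = 0.2,
                                    induction_fold = 1, noise_sd = 0,
                                    seed = 32)
  expect_equal(gen1$expression[["1h"]], gen1$expression[["0h"]])
  # ISGs are induced by the stated fold at treated conditions
  gen8 <- generate_expression_table(500, isg_fraction = 0.2,
                                    induction_fold = 8, noise_sd = 0,
                                    seed = 33)
  isg <- gen8$truth$isg
  ratio <- gen8$expression[["6h"]] / gen8$expression[["0h"]]
  expect_equal(unname(ratio[isg]), rep(8, sum(isg)), tolerance = 1e-9)
  expect_equal(unname(ratio[!isg]), rep(1, sum(!isg)), tolerance = 1e-9)
  expect_error(generate_expression_table(100, isg_fraction = 1.2),
               "isg_fraction")
  # named genes and per-ISG induction folds
  genv <- generate_expression_table(
    4, gene_names = c("a", "b", "c", "d"), isg_genes = c("a", "c"),
    induction_fold = c(a = 10, c = 2), noise_sd = 0, seed = 34)
  ratio <- genv$expression[["6h"]] / genv$expression[["0h"]]
  expect_equal(unname(ratio[match(c("a", "b", "c", "d"),
                                  genv$expression$gene)]),
               c(10, 1, 2, 1), tolerance = 1e-9)
})

test_that("binding landscape honours requested overlap structure", {
  sizes <- c(chr1 = 8e8, chr2 = 8e8)
  land <- generate_binding_landscape(sizes, 208, 276, 92, n_tss = 150,
                                     seed = 13)
  st <- classify_stat_sites(land$stat1, land$stat2)
  expect_equal(unname(attr(st, "counts")["STAT1/2"]), 92)
  # n_overlap = 0: no shared sites
  land0 <- generate_binding_landscape(c(chr1 = 1e7), 15, 20, 0, seed = 14)
  st0 <- classify_stat_sites(land0$stat1, land0$stat2)
  expect_equal(unname(attr(st0, "counts")["STAT1/2"]), 0)
  # full overlap: no singles
  landf <- generate_binding_landscape(c(chr1 = 1e7), 12, 12, 12, seed = 15)
  stf <- classify_stat_sites(landf$stat1, landf$stat2)
  expect_equal(unname(attr(stf, "counts")[c("STAT1", "STAT2")]), c(0, 0))
  expect_error(generate_binding_landscape(c(chr1 = 1e7), 10, 10, 11),
               "n_overlap")
  expect_error(generate_binding_landscape(c(chr1 = 1e4), 500, 500, 100),
               "insufficient chromosome space")
})

test_that("feature generator reproduces archetypes and validates inputs", {
  n <- setNames(rep(10, 5), state_vocabulary())
  fm0 <- generate_feature_matrix(n, noise_sd = 0, seed = 1)
  st <- cluster_states(fm0$features, k_scan = 2:6, n_init = 5, seed = 2)
  expect_equal(mclust::adjustedRandIndex(fm0$truth$state,
                                         st$assignment$state), 1)
  expect_error(generate_feature_matrix(n, noise_sd = -1), "noise_sd")
  bad <- chromatin_archetypes()[, 1:5]
  expect_error(generate_feature_matrix(n, archetype_means = bad),
               "missing feature")
})
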