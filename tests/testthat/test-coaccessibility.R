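test_that("balanced cell selection matches depth distributions across groups", {
  # groups of exactly the requested size pass through unchanged
  ps <- peak_set("chr1", 0, 2000, id = "p")
  sim <- generate_accessibility_matrix(
    100, ps, baseline_rate = 0.1,
    groups = data.frame(cell_type = "ESC", condition = c("0h", "6h")),
    seed = 1)
  sel <- select_balanced_cells(sim$matrix, 100)
  expect_identical(sel$cell_meta$barcode, sim$matrix$cell_meta$barcode)
  # undersized group errors with the group name
  expect_error(select_balanced_cells(sim$matrix, 101), "ESC\\|0h")
  # a depth-shifted group moves toward the pooled distribution
  set.seed(5)
  n <- 800
  meta <- data.frame(
    barcode = sprintf("c%04d", 1:(2 * n)),
    cell_type = "ESC",
    condition = rep(c("0h", "6h"), each = n),
    fragment_count = c(rlnorm(n, log(3000), 0.4), rlnorm(n, log(9000), 0.4)))
  m <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(2 * n, 1))
  colnames(m) <- "p"
  am <- accessibility_matrix(m, meta, ps)
  sel2 <- select_balanced_cells(am, 300)
  med <- tapply(sel2$cell_meta$fragment_count, sel2$cell_meta$condition,
                median)
  pre <- tapply(meta$fragment_count, meta$condition, median)
  expect_lt(abs(diff(log(med))), abs(diff(log(pre))))
})

test_that("candidate tiles cover the window on a fixed grid", {
  sizes <- c(chr1 = 1e8)
  # mid-chromosome, grid-aligned site: 1 Mb / 2 kb tiles minus the self tile
  site <- peak_set("chr1", 50000000 - 200, 50000000 + 200, id = "s")
  tl <- candidate_tiles(site, sizes)
  expect_equal(nrow(tl), 499)
  expect_false(any(tl$start <= 5e7 & tl$end > 5e7))
  # 100 kb from the chromosome start: left side clipped
  site2 <- peak_set("chr1", 100000 - 200, 100000 + 200, id = "s")
  tl2 <- candidate_tiles(site2, sizes)
  expect_equal(nrow(tl2), (100000 + 500000) / 2000 - 1)
  # window = tile leaves no candidates
  site3 <- peak_set("chr1", 20000 - 200, 20000 + 200, id = "s")
  expect_equal(nrow(candidate_tiles(site3, sizes, window = 2000)), 0)
  expect_error(candidate_tiles(site, c(chr1 = 1e6)), "beyond chromosome")
  expect_error(candidate_tiles(peak_set("chrZ", 0, 100, id = "s"), sizes),
               "absent")
})

test_that("pairwise correlation equals the dense Pearson oracle", {
  # hand example: phi coefficient of two binary vectors
  m <- Matrix::sparseMatrix(i = c(1, 2, 5, 1, 5), j = c(1, 1, 1, 2, 2),
                            x = 1, dims = c(6, 2))
  expect_equal(pairwise_correlation(m, 1, 2), sqrt(2) / 2,
               tolerance = 1e-7)
  expect_equal(pairwise_correlation(m, 1, 1), 1)
  # zero-variance column yields NA
  m2 <- cbind(m, Matrix::sparseMatrix(i = 1:6, j = rep(1, 6), x = 1,
                                      dims = c(6, 1)))
  expect_true(is.na(pairwise_correlation(m2, 1, 3)))
  # exact agreement with stats::cor on random 50x50 binary matrices
  for (seed in 1:3) {
    set.seed(seed)
    r <- Matrix::Matrix(matrix(rbinom(2500, 1, 0.2), 50, 50), sparse = TRUE)
    got <- pairwise_correlation(r, 1, 2:50)
    want <- dense_pearson(r, 1, 2:50)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # permuting cell order leaves correlations unchanged
  set.seed(4)
  perm <- sample(50)
  r <- Matrix::Matrix(matrix(rbinom(2500, 1, 0.2), 50, 50), sparse = TRUE)
  expect_equal(pairwise_correlation(r[perm, ], 1, 2:50),
               pairwise_correlation(r, 1, 2:50), tolerance = 1e-12)
})

test_that("shuffled null threshold matches the analytic large-n value", {
  am <- null_matrix(2700, 60, rate = 0.1, seed = 77)
  pairs <- expand.grid(site_id = sprintf("pk%03d", 1:3),
                       tile_id = sprintf("pk%03d", 4:60),
                       stringsAsFactors = FALSE)
  nm <- shuffle_null_threshold(am, pairs, n_shuffles = 10, seed = 78)
  analytic <- qnorm(0.99) / sqrt(2700 - 1)
  expect_lt(abs(nm$threshold - analytic) / analytic, 0.15)
  # doubling the shuffles moves the threshold by less than the MC spread
  nm2 <- shuffle_null_threshold(am, pairs, n_shuffles = 20, seed = 78)
  se <- sd(nm$shuffled_r_values) / sqrt(length(nm$shuffled_r_values)) * 10
  expect_lt(abs(nm2$threshold - nm$threshold), max(se, 0.01))
  expect_warning(shuffle_null_threshold(am, pairs[1:5, ], n_shuffles = 1),
                 "unstable")
})

test_that("the r threshold alone flags about 1% of structure-free pairs", {
  am <- null_matrix(2000, 110, rate = 0.1, seed = 90)
  pairs <- expand.grid(site_id = sprintf("pk%03d", 1:10),
                       tile_id = sprintf("pk%03d", 11:110),
                       stringsAsFactors = FALSE)
  nm <- shuffle_null_threshold(am, pairs, n_shuffles = 20, seed = 91)
  lt <- link_table(am, pairs)
  frac <- mean(lt$r > nm$threshold, na.rm = TRUE)
  n_pairs <- sum(!is.na(lt$r))
  ci <- 2 * sqrt(0.01 * 0.99 / n_pairs)
  # allow the Monte-Carlo wobble of the threshold itself on top of the CI
  expect_lt(abs(frac - 0.01), ci + 0.01)
  # QC independence: link r and percent-accessible are uncorrelated on null
  expect_lt(abs(cor(lt$r, lt$pct_accessible, use = "complete.obs")), 0.1)
})

test_that("correlation p-values follow the t approximation", {
  expect_equal(correlation_pvalue(0, 100), 1)
  expect_equal(correlation_pvalue(0.5, 27), 0.0079, tolerance = 1e-2)
  expect_equal(correlation_pvalue(1, 50), 0)
  expect_equal(correlation_pvalue(-1, 50), 0)
  expect_true(is.na(correlation_pvalue(NA, 50)))
  rs <- seq(0, 0.9, by = 0.1)
  ps <- correlation_pvalue(rs, 30)
  expect_true(all(diff(ps) < 0))
  # cross-check against cor.test on a concrete sample
  set.seed(6)
  x <- rbinom(40, 1, 0.4); y <- rbinom(40, 1, 0.4)
  r <- suppressWarnings(cor(x, y))
  expect_equal(correlation_pvalue(r, 40),
               cor.test(x, y)$p.value, tolerance = 1e-10)
})

test_that("percent accessible follows the stated definition", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3, 1, 2), j = c(1, 1, 1, 2, 2),
                            x = 1, dims = c(6, 2))
  # fractions 1/2 and 1/3 average to 5/12
  expect_equal(percent_accessible(m, 1, 2), 5 / 12)
  expect_equal(percent_accessible(m, 1, 2, mode = "either_open"), 1 / 2)
  ones <- Matrix::Matrix(1, 4, 2, sparse = TRUE)
  expect_equal(percent_accessible(ones, 1, 2), 1)
  zero <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(4, 2))
  expect_equal(percent_accessible(zero, 1, 2), 0)
})

test_that("link calling combines the r threshold and the p-value gate", {
  null <- structure(list(threshold = 0.07), class = "null_model")
  lt <- data.frame(site_a = "s", site_b = c("t1", "t2", "t3", "t4"),
                   r = c(0.5, 0.06, 0.5, NA),
                   p = c(1e-6, 1e-6, 0.02, NA))
  called <- call_links(lt, null, alpha = 0.01)
  expect_equal(called$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(call_links(lt, null, alpha = 1.5), "alpha")
})

test_that("link deltas classify gained, lost, stable and absent pairs", {
  ref <- data.frame(site_a = "s", site_b = c("t1", "t2", "t3", "t4"),
                    r = c(0.5, 0.01, 0.4, 0.0),
                    significant = c(TRUE, FALSE, TRUE, FALSE))
  trt <- data.frame(site_a = "s", site_b = c("t2", "t1", "t4", "t3"),
                    r = c(0.5, 0.45, 0.01, 0.39),
                    significant = c(TRUE, TRUE, FALSE, TRUE))
  d <- diff_links(ref, trt)
  expect_equal(d$status[match(c("t1", "t2", "t3", "t4"), d$site_b)],
               c("stable", "gained", "stable", "absent"))
  ref2 <- ref[ref$site_b != "t4", ]
  expect_error(diff_links(ref2, trt), "universes differ")
  # lost: significant only in the reference
  trt2 <- trt; trt2$significant <- FALSE
  d2 <- diff_links(ref, trt2)
  expect_equal(sort(unique(d2$status[d2$site_b %in% c("t1", "t3")])), "lost")
})

test_that("planted links are recovered with high recall and calibrated FPR", {
  ps <- peak_set(rep("chr1", 50), (0:49) * 2000, (1:50) * 2000,
                 id = c(sprintf("s%02d", 1:5), sprintf("t%02d", 1:45)))
  pairs <- expand.grid(site_id = sprintf("s%02d", 1:5),
                       tile_id = sprintf("t%02d", 1:45),
                       stringsAsFactors = FALSE)
  planted <- data.frame(site_id = sprintf("s%02d", 1:5),
                        tile_id = sprintf("t%02d", 1:5),
                        effect = 0.9)
  planted_key <- paste(planted$site_id, planted$tile_id)
  res <- vapply(1:20, function(seed) {
    sim <- generate_accessibility_matrix(
      2700, ps, planted, baseline_rate = 0.1,
      fragment_count_distribution = list(meanlog = log(5000), sdlog = 0),
      groups = data.frame(cell_type = "ESC", condition = "0h"), seed = seed)
    nm <- shuffle_null_threshold(sim$matrix, pairs, n_shuffles = 3,
                                 seed = seed + 1000)
    called <- call_links(link_table(sim$matrix, pairs), nm, alpha = 0.01)
    key <- paste(called$site_a, called$site_b)
    is_planted <- key %in% planted_key
    c(recall = mean(called$significant[is_planted]),
      fpr = mean(called$significant[!is_planted]))
  }, c(recall = 1, fpr = 1))
  expect_gte(mean(res["recall", ]), 0.95)
  # false positives stay at the level the raw alpha implies
  expect_lte(mean(res["fpr", ]), 0.015)
})
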