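test_that("BED round-trip is the identity and keeps half-open coordinates", {
  ps <- peak_set(c("chr1", "chr1", "chr2"), c(0, 5000, 100),
                 c(2000, 5400, 900), id = c("a", "b", "c"),
                 strand = c("+", "-", "."), label = "trip")
  path <- tempfile(fileext = ".bed")
  write_bed(ps, path)
  back <- read_bed(path, label = "trip")
  expect_equal(as.data.frame(back), as.data.frame(ps))
  # interval (chr1, 0, 2000) spans 2000 bases under the half-open convention
  expect_equal(back$end[1] - back$start[1], 2000)
})

test_that("malformed BED lines are rejected with a line number", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t100\t100"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t100"), path)
  expect_error(read_bed(path), "line 1")
  expect_error(peak_set("chr1", 100, 100), "start")
})

test_that("accessibility mtx round-trips, binarizes, and validates sidecars", {
  ps <- peak_set(rep("chr1", 3), c(0, 2000, 4000), c(2000, 4000, 6000),
                 id = c("p1", "p2", "p3"))
  m <- Matrix::sparseMatrix(i = c(5, 2), j = c(2, 3), x = c(3, 7),
                            dims = c(6, 3))
  meta <- data.frame(barcode = sprintf("bc%d", 1:6), cell_type = "ESC",
                     condition = "0h", fragment_count = 1000 + 1:6)
  am <- accessibility_matrix(m, meta, ps)
  # value 3 at (cell 5, peak 2) binarized to 1
  expect_equal(am$entries[5, 2], 1)
  expect_equal(am$entries[2, 3], 1)
  dir <- tempfile()
  write_accessibility_mtx(am, dir)
  back <- read_accessibility_mtx(file.path(dir, "matrix.mtx"),
                                 file.path(dir, "barcodes.tsv"),
                                 file.path(dir, "peaks.bed"),
                                 file.path(dir, "cell_meta.tsv"))
  expect_equal(as.matrix(back$entries), as.matrix(am$entries),
               ignore_attr = TRUE)
  expect_equal(back$cell_meta$barcode, meta$barcode)
  # empty triplet -> all-zero matrix of the declared shape
  empty <- accessibility_matrix(Matrix::sparseMatrix(i = integer(),
                                                     j = integer(),
                                                     x = numeric(),
                                                     dims = c(4, 3)),
                                meta[1:4, ], ps)
  expect_equal(sum(empty$entries), 0)
  expect_equal(dim(empty$entries), c(4L, 3L))
  # barcode count mismatch is an error
  writeLines(sprintf("bc%d", 1:4), file.path(dir, "barcodes.tsv"))
  expect_error(read_accessibility_mtx(file.path(dir, "matrix.mtx"),
                                      file.path(dir, "barcodes.tsv"),
                                      file.path(dir, "peaks.bed"),
                                      file.path(dir, "cell_meta.tsv")),
               "barcode count")
})

test_that("overlap_sets matches the brute-force oracle and edge semantics", {
  a1 <- peak_set("chr1", 100, 300, id = "x")
  b1 <- peak_set("chr1", 250, 400, id = "y")
  expect_equal(nrow(overlap_sets(a1, b1)), 1)
  # half-open abutment does not overlap
  b2 <- peak_set("chr1", 200, 300, id = "y")
  expect_equal(nrow(overlap_sets(peak_set("chr1", 100, 200, id = "x"), b2)), 0)
  for (seed in 1:3) {
    a <- random_peaks(50, "a", seed)
    b <- random_peaks(50, "b", seed + 100)
    got <- overlap_sets(a, b)
    want <- brute_overlap_pairs(a, b)
    key <- function(d) sort(paste(d$id_a, d$id_b))
    expect_equal(key(got), key(want))
  }
})

test_that("union_sets obeys inclusion-exclusion and merges shared loci", {
  # disjoint sets
  a <- peak_set(c("chr1", "chr1"), c(0, 5000), c(400, 5400),
                id = c("a1", "a2"))
  b <- peak_set("chr2", 100, 500, id = "b1")
  u <- union_sets(a, b)
  expect_equal(nrow(u), 3)
  expect_equal(sort(unique(u$membership)), c("a_only", "b_only"))
  # identical sets collapse to all-shared
  u2 <- union_sets(a, peak_set(a$chrom, a$start, a$end, id = c("c1", "c2")))
  expect_equal(nrow(u2), 2)
  expect_true(all(u2$membership == "shared"))
  # shared loci span both contributors
  a3 <- peak_set("chr1", 100, 300, id = "a")
  b3 <- peak_set("chr1", 250, 450, id = "b")
  u3 <- union_sets(a3, b3)
  expect_equal(u3$start, 100)
  expect_equal(u3$end, 450)
  expect_equal(u3$members, "a,b")
  # inclusion-exclusion on random inputs: every input interval appears in
  # exactly one union locus, and |union| = |a| + |b| - absorbed intervals
  for (seed in 4:6) {
    ra <- random_peaks(40, "a", seed)
    rb <- random_peaks(40, "b", seed + 50)
    ru <- union_sets(ra, rb)
    members <- unlist(strsplit(ru$members, ","))
    expect_setequal(members, c(ra$id, rb$id))
    expect_equal(length(members), length(unique(members)))
    absorbed <- sum(lengths(strsplit(ru$members, ",")) - 1)
    expect_equal(nrow(ru), nrow(ra) + nrow(rb) - absorbed)
  }
})

test_that("promoter windows are strand-aware and half-open", {
  tss <- data.frame(chrom = "chr1", start = 10000, end = 15000,
                    gene = "g1", strand = "+")
  # site centered exactly on the TSS
  expect_true(promoter_flag(peak_set("chr1", 9900, 10100, id = "s"), tss))
  # site ending exactly at TSS - 1000 misses the window (half-open)
  expect_false(promoter_flag(peak_set("chr1", 8500, 9000, id = "s"), tss))
  expect_true(promoter_flag(peak_set("chr1", 8500, 9001, id = "s"), tss))
  # minus strand: TSS = end - 1
  tssm <- data.frame(chrom = "chr1", start = 10000, end = 15000,
                     gene = "g1", strand = "-")
  expect_true(promoter_flag(peak_set("chr1", 14990, 15010, id = "s"), tssm))
  expect_false(promoter_flag(peak_set("chr1", 9100, 9500, id = "s"), tssm))
  # unknown chromosome warns and yields non-promoter
  expect_warning(fl <- promoter_flag(peak_set("chrX", 0, 100, id = "s"), tss),
                 "absent")
  expect_false(fl)
  # random layout equals the brute-force window test
  set.seed(9)
  n <- 200
  sites <- peak_set(rep("chr1", n), st <- sample(5e5, n), st + 200,
                    id = sprintf("s%03d", 1:n))
  tssr <- data.frame(chrom = "chr1", start = sample(5e5, 20),
                     end = 0, gene = sprintf("g%02d", 1:20), strand = "+")
  tssr$end <- tssr$start + 1000
  got <- promoter_flag(sites, tssr)
  want <- vapply(seq_len(n), function(i) {
    any(sites$start[i] < tssr$start + 1000 & sites$end[i] > tssr$start - 1000)
  }, TRUE)
  expect_equal(got, want)
})

test_that("nearest_tss picks the closest TSS with deterministic ties", {
  tss <- data.frame(chrom = "chr1", start = c(20000, 30000),
                    end = c(25000, 35000), gene = c("far", "near"),
                    strand = "+")
  res <- nearest_tss(peak_set("chr1", 24900, 25100, id = "s"), tss)
  expect_equal(res$gene, "far")
  expect_equal(res$distance, 5000)
  # equidistant TSS: lexicographically smaller gene wins
  tie <- data.frame(chrom = "chr1", start = c(1000, 3000),
                    end = c(2000, 4000), gene = c("zeta", "alpha"),
                    strand = "+")
  res2 <- nearest_tss(peak_set("chr1", 1900, 2100, id = "s"), tie)
  expect_equal(res2$gene, "alpha")
  # chromosome without genes yields NA sentinel
  res3 <- nearest_tss(peak_set("chrY", 0, 100, id = "s"), tss)
  expect_true(is.na(res3$gene))
  # random layout equals exhaustive scan
  set.seed(11)
  sites <- peak_set(rep("chr1", 50), st <- sample(1e5, 50), st + 100,
                    id = sprintf("s%02d", 1:50))
  tssr <- data.frame(chrom = "chr1", start = sample(1e5, 15), end = 0,
                     gene = sprintf("g%02d", 1:15), strand = "+")
  tssr$end <- tssr$start + 500
  got <- nearest_tss(sites, tssr)
  ctr <- floor((sites$start + sites$end) / 2)
  for (i in seq_len(50)) {
    d <- abs(ctr[i] - tssr$start)
    expect_equal(got$distance[i], min(d))
  }
})

test_that("venn_counts and sets_from_venn are mutually inverse", {
  s <- sets_from_venn(3, 2, 1, 4, 0, 5, 7)
  v <- venn_counts(s$a, s$b, s$c)
  expect_equal(v$only_a, 3)
  expect_equal(v$bc_only, 5)
  expect_equal(v$abc, 7)
  expect_equal(v$union, 3 + 2 + 1 + 4 + 0 + 5 + 7)
  expect_equal(v$total_a, 3 + 4 + 0 + 7)
})
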