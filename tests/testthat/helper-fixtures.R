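# Shared fixtures and independent brute-force oracles.

# Quadratic all-pairs interval overlap oracle (0-based half-open).
brute_overlap_pairs <- function(a, b, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    shared <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (shared >= min_overlap) {
      out[[length(out) + 1L]] <- data.frame(id_a = a$id[i], id_b = b$id[j])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id_a = character(), id_b = character()))
  }
  do.call(rbind, out)
}

# Dense Pearson correlation oracle via stats::cor on plain matrices.
dense_pearson <- function(m, i, js) {
  m <- as.matrix(m)
  vapply(js, function(j) suppressWarnings(stats::cor(m[, i], m[, j])), 1)
}

random_peaks <- function(n, label, seed, chrom = c("chr1", "chr2"),
                         max_pos = 1e5, width = c(50, 500)) {
  set.seed(seed)
  start <- sample(max_pos, n)
  peak_set(sample(chrom, n, replace = TRUE), start,
           start + sample(width[1]:width[2], n, replace = TRUE),
           id = sprintf("%s_%03d", label, seq_len(n)), label = label)
}

# Uniform-depth Bernoulli accessibility matrix (structure-free null).
null_matrix <- function(n_cells, n_peaks, rate = 0.1, seed = 1) {
  ps <- peak_set(rep("chr1", n_peaks), (0:(n_peaks - 1)) * 2000,
                 (1:n_peaks) * 2000,
                 id = sprintf("pk%03d", seq_len(n_peaks)))
  generate_accessibility_matrix(
    n_cells, ps, baseline_rate = rate,
    fragment_count_distribution = list(meanlog = log(5000), sdlog = 0),
    groups = data.frame(cell_type = "ESC", condition = "0h"),
    seed = seed)$matrix
}

# Small gene annotation used across regulation tests.
toy_tss_table <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(10000, 50000, 90000, 20000),
    end = c(20000, 60000, 100000, 30000),
    gene = c("isgA", "isgB", "geneC", "isgD"),
    strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE)
}
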