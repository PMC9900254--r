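#!/usr/bin/env Rscript
# Stage 1 — simulate the study's data structure.
#
# Generates every input the downstream stages read: STAT1/STAT2 peak sets
# with a controlled overlap, a TSS annotation, a binary single-cell
# accessibility matrix (two conditions, planted co-accessible links to ISG
# loci), a bimodal expression table with mechanism-dependent ISG induction,
# and per-site chromatin feature matrices for two cell types. All files are
# plain text under results/analysis/data/.

suppressMessages(library(ifnchrom))

seed <- 1L
data_dir <- "results/analysis/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

chrom_sizes <- c(chr1 = 3e7, chr2 = 3e7)

## binding landscape: 60 STAT1 and 70 STAT2 peaks, 25 shared loci
land <- generate_binding_landscape(chrom_sizes, n_stat1 = 60, n_stat2 = 70,
                                   n_overlap = 25, n_tss = 80, seed = seed)
write_bed(land$stat1, file.path(data_dir, "stat1_peaks.bed"))
write_bed(land$stat2, file.path(data_dir, "stat2_peaks.bed"))
write.table(land$tss_table, file.path(data_dir, "genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(chrom = names(chrom_sizes), size = chrom_sizes),
            file.path(data_dir, "chrom_sizes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## site universe and candidate 2-kb tiles in 1-Mb windows
sites <- classify_stat_sites(land$stat1, land$stat2, cell_type = "ESC")
stat12 <- sites_as_peaks(sites, "STAT1/2", label = "stat12")
layout <- candidate_pair_layout(stat12, chrom_sizes, window = 1e6,
                                tile = 2000)
cat(sprintf("site universe: %d loci (%d STAT1/2), %d candidate tiles\n",
            nrow(sites), nrow(stat12), nrow(layout$tiles)))

## ISG list: promoter-bound genes (TSS near a STAT1/2 locus) plus distal
## genes whose bodies are covered by candidate tiles
gene_bodies <- peak_set(land$tss_table$chrom, land$tss_table$start,
                        land$tss_table$end, id = land$tss_table$gene,
                        label = "genes")
tile_hits <- overlap_sets(layout$tiles, gene_bodies)
near <- land$truth$overlap_near_tss
linkable <- setdiff(unique(tile_hits$id_b), near)
set.seed(seed)
extras <- sample(linkable, min(9, length(linkable)))
isg_genes <- sort(c(near, extras))
writeLines(isg_genes, file.path(data_dir, "isg_genes.txt"))

## planted links: gained (6 h only) for 6 distal ISGs, lost (0 h only) for 3
roles <- data.frame(gene = extras,
                    status = rep(c("gained", "lost"), c(6, 3))[seq_along(extras)])
planted <- do.call(rbind, lapply(seq_len(nrow(roles)), function(k) {
  tl <- tile_hits$id_a[tile_hits$id_b == roles$gene[k]]
  cand <- layout$pairs[layout$pairs$tile_id %in% tl, , drop = FALSE]
  cand <- cand[sample(nrow(cand), 1L), ]
  data.frame(site_id = cand$site_id, tile_id = cand$tile_id, effect = 0.9,
             condition = if (roles$status[k] == "gained") "6h" else "0h",
             gene = roles$gene[k])
}))
write.table(planted, file.path(data_dir, "planted_links.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("planted %d gained and %d lost links at ISG loci\n",
            sum(planted$condition == "6h"), sum(planted$condition == "0h")))

## accessibility matrix: 3,000 cells per condition, baseline rate 0.1
peaks_all <- peak_set(c(stat12$chrom, layout$tiles$chrom),
                      c(stat12$start, layout$tiles$start),
                      c(stat12$end, layout$tiles$end),
                      id = c(stat12$id, layout$tiles$id),
                      label = "matrix_peaks")
sim <- generate_accessibility_matrix(
  3000, peaks_all, planted[, 1:4], baseline_rate = 0.1,
  fragment_count_distribution = list(meanlog = log(5000), sdlog = 0.3),
  groups = data.frame(cell_type = "ESC", condition = c("0h", "6h")),
  seed = seed + 1L)
write_accessibility_mtx(sim$matrix, file.path(data_dir, "scatac"))
cat(sprintf("accessibility matrix: %d cells x %d peaks, density %.3f\n",
            nrow(sim$matrix$entries), ncol(sim$matrix$entries),
            Matrix::nnzero(sim$matrix$entries) /
              prod(dim(sim$matrix$entries))))

## expression: bimodal baseline; ISG induction depends on the mechanism
## (promoter-bound > gained distal link > lost)
folds <- setNames(rep(10, length(isg_genes)), isg_genes)
folds[roles$gene[roles$status == "gained"]] <- 6
folds[roles$gene[roles$status == "lost"]] <- 3
expr <- generate_expression_table(
  nrow(land$tss_table), gene_names = land$tss_table$gene,
  isg_genes = isg_genes, induction_fold = folds, seed = seed + 2L)
write.table(expr$expression, file.path(data_dir, "expression_tpm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## chromatin features at a 200-site universe for two cell types; MEFs have
## more active enhancers, ESCs more poised/repressed sites
n_esc <- setNames(c(50, 25, 20, 55, 50), state_vocabulary())
n_mef <- setNames(c(55, 60, 30, 25, 30), state_vocabulary())
fm_esc <- generate_feature_matrix(n_esc, noise_sd = 0.8, seed = seed + 3L)
fm_mef <- generate_feature_matrix(n_mef, noise_sd = 0.8, seed = seed + 4L)
# one shared site universe: reuse the ESC site ids in permuted order
set.seed(seed + 5L)
fm_mef$truth$site <- rownames(fm_mef$features) <-
  sample(rownames(fm_esc$features))
for (ct in c("esc", "mef")) {
  fm <- get(paste0("fm_", ct))
  write.table(data.frame(site = rownames(fm$features), fm$features),
              file.path(data_dir, sprintf("features_%s.tsv", ct)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fm$truth, file.path(data_dir, sprintf("states_truth_%s.tsv", ct)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

## STAT1/2 binding signal at 1 h: loads positively on ATAC and H3K27ac,
## negatively on H3K27me3 (synthetic ground truth for stage 5)
set.seed(seed + 6L)
mk_binding <- function(fm) {
  f <- fm$features
  b <- exp(0.6 * log(f[, "ATAC"] + 0.01) + 0.6 * log(f[, "H3K27ac"] + 0.01) -
             0.4 * log(f[, "H3K27me3"] + 0.01) + rnorm(nrow(f), 0, 0.3))
  data.frame(site = rownames(f),
             stat1_1h = b * exp(rnorm(nrow(f), 0, 0.1)),
             stat2_1h = b * exp(rnorm(nrow(f), 0, 0.1)))
}
write.table(mk_binding(fm_esc), file.path(data_dir, "binding_esc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mk_binding(fm_mef), file.path(data_dir, "binding_mef.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("stage 1 done: inputs written to", data_dir, "\n")
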