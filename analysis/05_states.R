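#!/usr/bin/env Rscript
# Stage 5 — chromatin states at STAT1/2 sites.
#
# Clusters the per-site chromatin feature matrices (six histone marks +
# ATAC) into five named states with a silhouette scan over k, tabulates
# state transitions between the two cell types over the shared site
# universe, and correlates untreated chromatin features with subsequent
# STAT1/2 binding.

suppressMessages(library(ifnchrom))

data_dir <- "results/analysis/data"
out_dir <- "results/analysis"

read_features <- function(ct) {
  f <- read.delim(file.path(data_dir, sprintf("features_%s.tsv", ct)))
  m <- as.matrix(f[, -1])
  rownames(m) <- f$site
  m
}

assignments <- list()
for (ct in c("esc", "mef")) {
  feats <- read_features(ct)
  st <- cluster_states(feats, k = 5, k_scan = 2:10, n_init = 20,
                       seed = 1 + match(ct, c("esc", "mef")))
  best_k <- st$silhouette$k[which.max(st$silhouette$mean_silhouette)]
  cat(sprintf("[%s] clustered %d sites; silhouette favors k = %d\n",
              ct, nrow(feats), best_k))
  print(table(st$assignment$state))
  truth <- read.delim(file.path(data_dir,
                                sprintf("states_truth_%s.tsv", ct)))
  ari <- mclust::adjustedRandIndex(
    truth$state[match(st$assignment$site, truth$site)],
    st$assignment$state)
  cat(sprintf("[%s] agreement with generating states: ARI %.3f\n", ct, ari))
  write.table(st$assignment,
              file.path(out_dir, sprintf("states_%s.tsv", ct)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(st$silhouette,
              file.path(out_dir, sprintf("silhouette_%s.tsv", ct)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  assignments[[ct]] <- st$assignment
}

## state transitions between cell types over the shared site universe
tt <- state_transition_table(assignments$esc, assignments$mef)
cat("state transitions (rows ESC, columns MEF):\n")
print(tt)
write.table(as.data.frame.matrix(tt),
            file.path(out_dir, "state_transitions.tsv"),
            sep = "\t", quote = FALSE, row.names = TRUE)

## preexisting chromatin features vs subsequent STAT1/2 binding
for (ct in c("esc", "mef")) {
  feats <- read_features(ct)
  bind <- read.delim(file.path(data_dir, sprintf("binding_%s.tsv", ct)))
  fb <- feature_binding_correlation(
    feats,
    setNames(bind$stat1_1h, bind$site),
    setNames(bind$stat2_1h, bind$site))
  cat(sprintf("[%s] feature-binding correlations:\n", ct))
  print(transform(fb, R = round(R, 2), p = signif(p, 2)))
  write.table(fb, file.path(out_dir, sprintf("feature_binding_%s.tsv", ct)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("stage 5 done\n")
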