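#' The five chromatin-state names
#' @return Character vector of the canonical state vocabulary.
#' @export
state_vocabulary <- function() {
  c("Active Promoter", "Active Enhancer", "Bivalent", "Poised", "Repressed")
}

#' Cluster chromatin features at binding sites into states
#'
#' Standardizes each feature column (z-score), runs k-means with `n_init`
#' restarts keeping the best inertia, and reports the mean silhouette
#' coefficient for every cluster number in `k_scan` as a sanity check on the
#' choice of `k`. With `annotate = TRUE` (and `k = 5`) clusters are named via
#' [annotate_states()].
#'
#' @param features Sites x features numeric matrix (site ids as row names);
#'   columns must include the seven features used by [annotate_states()]
#'   when annotation is requested.
#' @param k Number of clusters (default 5, the number of biologically
#'   distinct states at these sites).
#' @param k_scan Cluster numbers for the silhouette scan (default 2:20).
#' @param n_init Random restarts per k-means run (default 25).
#' @param standardize Z-score columns before clustering (default TRUE).
#' @param annotate Name clusters by their centroid profiles (default TRUE
#'   when `k == 5`).
#' @param seed Integer seed.
#' @return A `state_assignment` list: `assignment` (`data.frame` site,
#'   cluster, state), `centers` (k x features, standardized space),
#'   `silhouette` (`data.frame` k, mean_silhouette), `state_names`
#'   (cluster -> state), `tot_withinss`.
#' @export
cluster_states <- function(features, k = 5L, k_scan = 2:20, n_init = 25L,
                           standardize = TRUE, annotate = (k == 5L),
                           seed = 1L) {
  if (k > nrow(features)) stop("k exceeds the number of sites")
  x <- as.matrix(features)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) sds[sds == 0] <- 1  # constant feature: center only
    x <- scale(x, center = TRUE, scale = sds)
  }
  with_seed(seed, {
    n_distinct <- nrow(unique(x))
    if (k > n_distinct) stop("k exceeds the number of distinct profiles")
    k_scan <- k_scan[k_scan >= 2 & k_scan < nrow(x) & k_scan <= n_distinct]
    dx <- stats::dist(x)
    sil <- vapply(k_scan, function(kk) {
      km <- stats::kmeans(x, centers = kk, nstart = n_init, iter.max = 100)
      mean(cluster::silhouette(km$cluster, dx)[, "sil_width"])
    }, 1)
    km <- stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100)
    state_names <- NULL
    state <- rep(NA_character_, nrow(x))
    if (annotate) {
      state_names <- annotate_states(km$centers)
      state <- unname(state_names[km$cluster])
    }
    out <- list(
      assignment = data.frame(site = rownames(x), cluster = km$cluster,
                              state = state, stringsAsFactors = FALSE),
      centers = km$centers,
      silhouette = data.frame(k = k_scan, mean_silhouette = sil),
      state_names = state_names,
      tot_withinss = km$tot.withinss)
    class(out) <- c("state_assignment", "list")
    out
  })
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("state_assignment: %d sites in %d clusters\n",
              nrow(x$assignment), nrow(x$centers)))
  if (!is.null(x$state_names)) print(table(x$assignment$state))
  best <- x$silhouette$k[which.max(x$silhouette$mean_silhouette)]
  cat(sprintf("silhouette scan over k = %d..%d; best mean silhouette at k = %d\n",
              min(x$silhouette$k), max(x$silhouette$k), best))
  invisible(x)
}

# Rule scores of each state for one standardized centroid. Higher = better
# match; built from the mark combinations that define each state.
state_rule_scores <- function(z) {
  act <- c("H3K4me1", "H3K4me3", "H3K9ac", "H3K27ac")
  v <- c(min(z["H3K4me3"], max(z["H3K9ac"], z["H3K27ac"])),
         min(z["H3K4me1"], z["H3K27ac"]),
         min(z["H3K4me3"], z["H3K27me3"]),
         z["H3K4me1"] -
           max(z["H3K4me3"], z["H3K9ac"], z["H3K27ac"], z["H3K9me3"],
               z["H3K27me3"]),
         max(z["H3K9me3"], z["H3K27me3"]) - max(z[act]))
  stats::setNames(as.numeric(v), state_vocabulary())
}

#' Name five k-means centroids with the canonical chromatin states
#'
#' Rule-based annotation on standardized centroid values: Bivalent needs both
#' H3K4me3 and H3K27me3 elevated; Active Promoter needs H3K4me3 with
#' H3K9ac/H3K27ac; Active Enhancer needs H3K4me1 with H3K27ac; Poised is
#' H3K4me1 alone; Repressed is H3K9me3 or H3K27me3 without active marks.
#' Each rule yields a score per centroid and the one-to-one naming is the
#' permutation maximizing the total score; invariant to cluster index order.
#'
#' @param centroids k x features matrix of cluster centers in standardized
#'   (z-score) space; k must be 5.
#' @return Named character vector: cluster index -> state name.
#' @export
annotate_states <- function(centroids) {
  if (nrow(centroids) != 5L) stop("annotation rules are defined for k = 5")
  req <- c("H3K4me1", "H3K4me3", "H3K9ac", "H3K27ac", "H3K9me3", "H3K27me3")
  miss <- setdiff(req, colnames(centroids))
  if (length(miss) > 0L) {
    stop("centroids missing feature(s): ", paste(miss, collapse = ", "))
  }
  states <- state_vocabulary()
  scores <- t(apply(centroids, 1, function(z) state_rule_scores(z)[states]))
  colnames(scores) <- states
  perms <- permutations_of(5L)
  totals <- apply(perms, 1, function(p) sum(scores[cbind(1:5, p)]))
  best <- which(totals == max(totals))
  if (length(best) > 1L) {
    stop("ambiguous state annotation; centroid scores:\n",
         paste(utils::capture.output(print(round(scores, 3))), collapse = "\n"))
  }
  nm <- states[perms[best, ]]
  stats::setNames(nm, rownames(centroids) %||% as.character(1:5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..n (n small), one per row.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow = nrow(sub)))
  }))
}

#' Chromatin-state transition table between two cell types
#'
#' Cross-tabulates the state of each site in condition/cell type A against
#' its state in B, optionally restricted to a site subset (e.g. the
#' cell-type-specific binding sites). Marginals equal the per-cell-type
#' state histograms by construction.
#'
#' @param states_a,states_b `data.frame`s with columns `site`, `state` over
#'   the same site universe.
#' @param site_subset Optional character vector of site ids.
#' @return 5 x 5 contingency table (rows = A states, columns = B states).
#' @export
state_transition_table <- function(states_a, states_b, site_subset = NULL) {
  if (!setequal(states_a$site, states_b$site)) {
    stop("site universes differ between the two assignments")
  }
  if (!is.null(site_subset)) {
    states_a <- states_a[states_a$site %in% site_subset, , drop = FALSE]
    states_b <- states_b[states_b$site %in% site_subset, , drop = FALSE]
  }
  ord <- match(states_a$site, states_b$site)
  lv <- state_vocabulary()
  table(factor(states_a$state, levels = lv),
        factor(states_b$state[ord], levels = lv))
}

#' Correlate preexisting chromatin features with subsequent STAT1/2 binding
#'
#' The binding signal per site is the average of the STAT1 and STAT2 signals
#' after 1 h of treatment; each untreated (0 h) chromatin feature is
#' correlated (Pearson) against it, on log2-transformed enrichments.
#'
#' @param features_0h Sites x features matrix of untreated enrichments.
#' @param stat1_signal_1h,stat2_signal_1h Named numeric vectors of binding
#'   signal per site at 1 h.
#' @param site_subset Optional site ids to restrict to (e.g. combined
#'   cell-type-specific sites).
#' @param log_transform Correlate `log2(value + pseudocount)` (default TRUE).
#' @param pseudocount Added before log2 (default 0.01).
#' @return `data.frame`: `feature`, `R`, `p`, `n`. Zero-variance features
#'   give `NA`.
#' @export
feature_binding_correlation <- function(features_0h, stat1_signal_1h,
                                        stat2_signal_1h, site_subset = NULL,
                                        log_transform = TRUE,
                                        pseudocount = 0.01) {
  sites <- rownames(features_0h)
  if (is.null(sites)) stop("features_0h needs site ids as row names")
  if (!is.null(site_subset)) sites <- intersect(sites, site_subset)
  f <- features_0h[sites, , drop = FALSE]
  binding <- (stat1_signal_1h[sites] + stat2_signal_1h[sites]) / 2
  if (anyNA(binding)) stop("binding signal missing for some sites")
  tf <- function(v) if (log_transform) log2(v + pseudocount) else v
  yb <- tf(binding)
  rows <- lapply(colnames(f), function(feat) {
    xv <- tf(f[, feat])
    if (stats::sd(xv) == 0 || stats::sd(yb) == 0) {
      return(data.frame(feature = feat, R = NA_real_, p = NA_real_,
                        n = length(xv)))
    }
    ct <- stats::cor.test(xv, yb)
    data.frame(feature = feat, R = unname(ct$estimate), p = ct$p.value,
               n = length(xv), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
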