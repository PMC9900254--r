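# All generators funnel randomness through with_seed(): the caller's RNG
# state is saved and restored, so identical seeds give bit-identical outputs
# and no global state leaks between stages.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a binary single-cell accessibility matrix with planted
#' co-accessible pairs
#'
#' Cells are organised into (cell type, condition) groups. Each cell gets a
#' log-normal fragment count whose relative depth scales its per-peak open
#' probability; entries are independent Bernoulli draws given depth. A
#' planted link (site, tile, effect strength) adds a shared latent per-cell
#' "activity" Bernoulli with success probability
#' `effect * baseline_rate` that is OR-ed into both members, so the expected
#' phi correlation of the pair increases monotonically with effect strength
#' while unplanted pairs stay conditionally independent.
#'
#' @param n_cells_per_group Cells per (cell type, condition) group (>= 2).
#' @param peak_layout [peak_set()] giving the matrix columns (sites + tiles).
#' @param planted_links `data.frame` with columns `site_id`, `tile_id`,
#'   `effect` in `[0, 1]` and optional `condition` (NA or absent = planted in
#'   every condition).
#' @param baseline_rate Per-peak open probability at average depth, in (0,1).
#' @param fragment_count_distribution List with `meanlog`, `sdlog` of the
#'   per-cell fragment count log-normal. `sdlog = 0` gives uniform depth.
#' @param groups `data.frame` with columns `cell_type`, `condition`; one row
#'   per group.
#' @param seed Integer seed.
#' @return List with `matrix` (an [accessibility_matrix()]) and `truth`
#'   (planted links and group labels).
#' @export
generate_accessibility_matrix <- function(n_cells_per_group,
                                          peak_layout,
                                          planted_links = NULL,
                                          baseline_rate = 0.1,
                                          fragment_count_distribution =
                                            list(meanlog = log(5000), sdlog = 0.5),
                                          groups = data.frame(
                                            cell_type = "ESC",
                                            condition = c("0h", "6h")),
                                          seed = 1L) {
  if (baseline_rate <= 0 || baseline_rate >= 1) {
    stop("baseline_rate must lie strictly between 0 and 1 ",
         "(degenerate rates give zero-variance columns)")
  }
  if (n_cells_per_group < 2L) stop("n_cells_per_group must be >= 2")
  if (anyDuplicated(peak_layout$id)) stop("peak ids must be unique")
  if (!is.null(planted_links) && nrow(planted_links) > 0L) {
    if (is.null(planted_links$condition)) planted_links$condition <- NA_character_
    unknown <- setdiff(c(planted_links$site_id, planted_links$tile_id),
                       peak_layout$id)
    if (length(unknown) > 0L) {
      stop("planted link references unknown peak id(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    if (any(planted_links$effect < 0 | planted_links$effect > 1)) {
      stop("effect strengths must lie in [0, 1]")
    }
  }
  n_groups <- nrow(groups)
  n_cells <- n_cells_per_group * n_groups
  n_peaks <- nrow(peak_layout)
  with_seed(seed, {
    frag <- stats::rlnorm(n_cells,
                          meanlog = fragment_count_distribution$meanlog,
                          sdlog = fragment_count_distribution$sdlog)
    depth_mult <- frag / exp(fragment_count_distribution$meanlog +
                               fragment_count_distribution$sdlog^2 / 2)
    p_cell <- pmin(pmax(baseline_rate * depth_mult, 1e-6), 1 - 1e-6)
    ii <- vector("list", n_peaks)
    for (j in seq_len(n_peaks)) {
      ii[[j]] <- which(stats::runif(n_cells) < p_cell)
    }
    cond_of_cell <- rep(groups$condition, each = n_cells_per_group)
    type_of_cell <- rep(groups$cell_type, each = n_cells_per_group)
    if (!is.null(planted_links) && nrow(planted_links) > 0L) {
      for (k in seq_len(nrow(planted_links))) {
        cells <- if (is.na(planted_links$condition[k])) seq_len(n_cells) else
          which(cond_of_cell == planted_links$condition[k])
        q <- planted_links$effect[k] * baseline_rate
        active <- cells[stats::runif(length(cells)) < q]
        ja <- match(planted_links$site_id[k], peak_layout$id)
        jb <- match(planted_links$tile_id[k], peak_layout$id)
        ii[[ja]] <- union(ii[[ja]], active)
        ii[[jb]] <- union(ii[[jb]], active)
      }
    }
    i_idx <- unlist(ii)
    j_idx <- rep.int(seq_len(n_peaks), lengths(ii))
    entries <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1,
                                    dims = c(n_cells, n_peaks))
    meta <- data.frame(
      barcode = sprintf("cell_%06d", seq_len(n_cells)),
      cell_type = type_of_cell,
      condition = cond_of_cell,
      fragment_count = round(frag),
      stringsAsFactors = FALSE)
    truth <- list(
      planted_links = planted_links,
      group_labels = stats::setNames(paste(meta$cell_type, meta$condition),
                                     meta$barcode))
    list(matrix = accessibility_matrix(entries, meta, peak_layout),
         truth = truth)
  })
}

#' Simulate a bimodal expression table with interferon-stimulated genes
#'
#' Baseline (0 h) log10 expression is drawn from a two-component Gaussian
#' mixture of repressed and active genes. A fraction of genes is labelled ISG
#' and multiplied by `induction_fold` at treated conditions. Per-condition
#' log-normal measurement noise is added throughout, so `induction_fold = 1`
#' leaves treated and untreated columns identical up to that noise.
#'
#' @param n_genes Number of genes.
#' @param active_params,repressed_params Numeric vectors
#'   `c(mean, sd, weight)` of the two log10-TPM components; weights must sum
#'   to 1 and sds must be positive.
#' @param isg_fraction Fraction of genes labelled ISG, in `[0, 1]`. ISGs are
#'   preferentially drawn from the active component, mirroring interferon
#'   response genes being inducible rather than stably silenced. Ignored
#'   when `isg_genes` is given.
#' @param induction_fold Fold induction of ISGs at treated conditions;
#'   either a scalar or a named vector giving a per-ISG fold.
#' @param conditions Character vector; the first entry is untreated.
#' @param noise_sd Per-condition measurement noise sd in log10 units.
#' @param gene_names Optional gene ids (length `n_genes`); autogenerated
#'   when `NULL`.
#' @param isg_genes Optional explicit ISG gene ids (overrides
#'   `isg_fraction`).
#' @param seed Integer seed.
#' @return List with `expression` (`data.frame`: gene, one TPM column per
#'   condition) and `truth` (`gene_class` map with levels active / repressed
#'   / ISG flag).
#' @export
generate_expression_table <- function(n_genes,
                                      active_params = c(mean = 1.5, sd = 0.6, weight = 0.55),
                                      repressed_params = c(mean = -1.2, sd = 0.6, weight = 0.45),
                                      isg_fraction = 0.05,
                                      induction_fold = 8,
                                      conditions = c("0h", "1h", "6h"),
                                      noise_sd = 0.05,
                                      gene_names = NULL,
                                      isg_genes = NULL,
                                      seed = 1L) {
  if (isg_fraction < 0 || isg_fraction > 1) {
    stop("isg_fraction must lie in [0, 1]")
  }
  w <- active_params[["weight"]] + repressed_params[["weight"]]
  if (abs(w - 1) > 1e-8) stop("component weights must sum to 1")
  if (active_params[["sd"]] <= 0 || repressed_params[["sd"]] <= 0) {
    stop("component sds must be positive")
  }
  with_seed(seed, {
    comp <- stats::rbinom(n_genes, 1L, active_params[["weight"]])  # 1 = active
    mu <- ifelse(comp == 1L, active_params[["mean"]], repressed_params[["mean"]])
    sd <- ifelse(comp == 1L, active_params[["sd"]], repressed_params[["sd"]])
    base_log <- stats::rnorm(n_genes, mu, sd)
    genes <- if (is.null(gene_names)) sprintf("gene_%05d", seq_len(n_genes))
      else as.character(gene_names)
    if (length(genes) != n_genes) stop("gene_names must have length n_genes")
    if (is.null(isg_genes)) {
      n_isg <- round(isg_fraction * n_genes)
      active_ix <- which(comp == 1L)
      pool <- if (length(active_ix) >= n_isg) active_ix else seq_len(n_genes)
      isg <- rep(FALSE, n_genes)
      if (n_isg > 0L) isg[sample(pool, n_isg)] <- TRUE
    } else {
      isg <- genes %in% isg_genes
    }
    fold <- rep(1, n_genes)
    if (length(induction_fold) == 1L) {
      fold[isg] <- induction_fold
    } else {
      fold[isg] <- ifelse(genes[isg] %in% names(induction_fold),
                          induction_fold[genes[isg]], 1)
    }
    expr <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (ci in seq_along(conditions)) {
      lg <- base_log
      if (ci > 1L) lg <- lg + log10(fold)
      lg <- lg + stats::rnorm(n_genes, 0, noise_sd)
      expr[[conditions[ci]]] <- 10^lg
    }
    truth <- data.frame(gene = genes,
                        class = ifelse(comp == 1L, "active", "repressed"),
                        isg = isg, stringsAsFactors = FALSE)
    list(expression = expr, truth = truth)
  })
}

#' Simulate STAT1 / STAT2 binding landscapes with controlled overlap
#'
#' Lays out disjoint peak slots along the given chromosomes and fills them so
#' that exactly `n_overlap` STAT1 peaks reciprocally overlap a STAT2 peak
#' while all remaining peaks are disjoint from the other set. TSS positions
#' are drawn so that `tss_at_overlap_fraction` of the overlap loci fall
#' within +/-1 kb of a TSS (promoter-bound STAT1/2 sites).
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param n_stat1,n_stat2 Number of STAT1 / STAT2 peaks.
#' @param n_overlap Number of reciprocally overlapping pairs
#'   (`<= min(n_stat1, n_stat2)`).
#' @param n_tss Number of annotated genes/TSS.
#' @param peak_width Peak width in bp.
#' @param tss_at_overlap_fraction Fraction of overlap loci placed within
#'   +/-1 kb of a TSS.
#' @param seed Integer seed.
#' @return List with `stat1`, `stat2` ([peak_set()]s), `tss_table`
#'   (`chrom`, `start`, `end`, `gene`, `strand`) and `truth` (slot roles).
#' @export
generate_binding_landscape <- function(chrom_sizes,
                                       n_stat1, n_stat2, n_overlap,
                                       n_tss = 100L,
                                       peak_width = 400L,
                                       tss_at_overlap_fraction = 0.5,
                                       seed = 1L) {
  if (n_overlap > min(n_stat1, n_stat2)) {
    stop("n_overlap must not exceed min(n_stat1, n_stat2)")
  }
  n_slots <- n_stat1 + n_stat2 - n_overlap + n_tss
  slot_pitch <- 6000L + peak_width  # keeps slots > ±1 kb apart
  capacity <- sum(pmax(floor((chrom_sizes - 2000) / slot_pitch), 0))
  if (capacity < n_slots) {
    stop(sprintf("insufficient chromosome space: need %d slots, have %d",
                 n_slots, capacity))
  }
  with_seed(seed, {
    slots <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
      k <- floor((chrom_sizes[[ch]] - 2000) / slot_pitch)
      if (k <= 0) return(NULL)
      data.frame(chrom = ch,
                 pos = 2000 + slot_pitch * (seq_len(k) - 1L),
                 stringsAsFactors = FALSE)
    }))
    slots <- slots[sample(nrow(slots), n_slots), , drop = FALSE]
    role <- rep(c("overlap", "stat1_only", "stat2_only", "tss_free"),
                c(n_overlap, n_stat1 - n_overlap, n_stat2 - n_overlap, n_tss))
    # jitter within the slot so coordinates are not lattice-like
    jit <- function(n) round(stats::runif(n, 0, 500))
    slots$pos <- slots$pos + jit(nrow(slots))
    ov <- slots[role == "overlap", , drop = FALSE]
    s1o <- slots[role == "stat1_only", , drop = FALSE]
    s2o <- slots[role == "stat2_only", , drop = FALSE]
    free <- slots[role == "tss_free", , drop = FALSE]
    half <- floor(peak_width / 2)
    # overlap pairs: STAT2 peak shifted by half a width so the two peaks
    # share peak_width/2 bases
    stat1 <- peak_set(
      c(ov$chrom, s1o$chrom),
      c(ov$pos, s1o$pos),
      c(ov$pos, s1o$pos) + peak_width,
      id = sprintf("stat1_%04d", seq_len(n_stat1)), label = "STAT1")
    stat2 <- peak_set(
      c(ov$chrom, s2o$chrom),
      c(ov$pos + half, s2o$pos),
      c(ov$pos + half, s2o$pos) + peak_width,
      id = sprintf("stat2_%04d", seq_len(n_stat2)), label = "STAT2")
    # TSS near a fraction of the overlap loci, the rest in free slots
    n_near <- round(tss_at_overlap_fraction * n_overlap)
    n_near <- min(n_near, n_tss, n_overlap)
    near_ix <- if (n_near > 0) sample(n_overlap, n_near) else integer(0)
    tss_chrom <- c(ov$chrom[near_ix], free$chrom)[seq_len(n_tss)]
    tss_pos <- c(ov$pos[near_ix] + half +
                   round(stats::runif(n_near, -800, 800)),
                 free$pos)[seq_len(n_tss)]
    strand <- sample(c("+", "-"), n_tss, replace = TRUE)
    gene_len <- round(stats::runif(n_tss, 5000, 20000))
    tss_table <- data.frame(
      chrom = tss_chrom,
      start = ifelse(strand == "+", tss_pos, pmax(tss_pos - gene_len, 0)),
      end = ifelse(strand == "+", tss_pos + gene_len, tss_pos + 1),
      gene = sprintf("gene_%04d", seq_len(n_tss)),
      strand = strand, stringsAsFactors = FALSE)
    truth <- list(n_overlap = n_overlap,
                  overlap_near_tss = sprintf("gene_%04d", seq_len(n_near)))
    list(stat1 = stat1, stat2 = stat2, tss_table = tss_table, truth = truth)
  })
}

#' Default chromatin-state archetype profiles
#'
#' Mean enrichment (over input control) of the seven chromatin features for
#' the five canonical states: Active Promoter (H3K4me3 + H3K9ac + H3K27ac,
#' open), Active Enhancer (H3K4me1 + H3K27ac), Bivalent (H3K4me3 together
#' with H3K27me3), Poised (H3K4me1 alone) and Repressed (H3K9me3 / H3K27me3).
#'
#' @return Numeric matrix, states x features.
#' @export
chromatin_archetypes <- function() {
  feats <- c("H3K4me1", "H3K4me3", "H3K9ac", "H3K27ac",
             "H3K9me3", "H3K27me3", "ATAC")
  m <- rbind(
    "Active Promoter" = c(1.0, 8.0, 6.0, 6.0, 0.5, 0.5, 8.0),
    "Active Enhancer" = c(6.0, 1.0, 2.0, 6.0, 0.5, 0.5, 5.0),
    "Bivalent"        = c(1.0, 6.0, 1.0, 1.0, 0.5, 6.0, 2.0),
    "Poised"          = c(6.0, 1.0, 0.5, 0.5, 0.5, 0.5, 1.0),
    "Repressed"       = c(0.5, 0.5, 0.5, 0.5, 6.0, 3.0, 0.5))
  colnames(m) <- feats
  m
}

#' Simulate a per-site chromatin feature matrix from state archetypes
#'
#' Each site's feature vector is its state archetype mean plus i.i.d.
#' Gaussian noise; the generating state is recorded as truth.
#'
#' @param n_sites_per_state Named integer vector (state -> site count);
#'   names must match rows of `archetype_means`.
#' @param archetype_means States x features matrix; defaults to
#'   [chromatin_archetypes()]. Must cover the seven features H3K4me1,
#'   H3K4me3, H3K9ac, H3K27ac, H3K9me3, H3K27me3, ATAC.
#' @param noise_sd Non-negative noise standard deviation (enrichment units).
#' @param seed Integer seed.
#' @return List with `features` (sites x features matrix, site ids as row
#'   names) and `truth` (`data.frame` site, state).
#' @export
generate_feature_matrix <- function(n_sites_per_state,
                                    archetype_means = chromatin_archetypes(),
                                    noise_sd = 0.5,
                                    seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  req <- c("H3K4me1", "H3K4me3", "H3K9ac", "H3K27ac",
           "H3K9me3", "H3K27me3", "ATAC")
  miss <- setdiff(req, colnames(archetype_means))
  if (length(miss) > 0L) {
    stop("archetypes missing feature(s): ", paste(miss, collapse = ", "))
  }
  unknown <- setdiff(names(n_sites_per_state), rownames(archetype_means))
  if (length(unknown) > 0L) {
    stop("no archetype for state(s): ", paste(unknown, collapse = ", "))
  }
  with_seed(seed, {
    states <- rep(names(n_sites_per_state), n_sites_per_state)
    n <- length(states)
    base <- archetype_means[states, , drop = FALSE]
    noise <- matrix(stats::rnorm(n * ncol(base), 0, noise_sd),
                    nrow = n)
    features <- pmax(base + noise, 0)
    rownames(features) <- sprintf("site_%04d", seq_len(n))
    truth <- data.frame(site = rownames(features), state = states,
                        stringsAsFactors = FALSE)
    list(features = features, truth = truth)
  })
}
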