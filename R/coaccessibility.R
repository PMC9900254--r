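#' Select depth-balanced cells per group
#'
#' Subsets the matrix to exactly `n_per_group` cells per (cell type,
#' condition) group, chosen so the per-group fragment-count distributions
#' match the pooled distribution: pooled quantiles at probabilities
#' `(i - 0.5) / n` are computed once and each group contributes its nearest
#' available cell (greedy two-pointer over sorted depths). Deterministic.
#'
#' @param am An [accessibility_matrix()].
#' @param n_per_group Cells to keep per group (default 2700, the per-group
#'   cell number used for the co-accessibility analysis).
#' @return The subsetted [accessibility_matrix()].
#' @export
select_balanced_cells <- function(am, n_per_group = 2700L) {
  meta <- am$cell_meta
  grp <- paste(meta$cell_type, meta$condition, sep = "|")
  sizes <- table(grp)
  small <- names(sizes)[sizes < n_per_group]
  if (length(small) > 0L) {
    stop(sprintf("group '%s' has only %d cells (< %d required)",
                 small[1], sizes[[small[1]]], n_per_group))
  }
  targets <- stats::quantile(meta$fragment_count,
                             probs = (seq_len(n_per_group) - 0.5) / n_per_group,
                             names = FALSE, type = 7)
  keep <- integer(0)
  for (g in names(sizes)) {
    ix <- which(grp == g)
    ord <- ix[order(meta$fragment_count[ix])]
    depths <- meta$fragment_count[ord]
    m <- length(ord)
    sel <- integer(n_per_group)
    j <- 1L
    for (i in seq_len(n_per_group)) {
      limit <- m - (n_per_group - i)  # leave enough cells for later targets
      while (j < limit &&
             abs(depths[j + 1L] - targets[i]) <= abs(depths[j] - targets[i])) {
        j <- j + 1L
      }
      sel[i] <- ord[j]
      j <- j + 1L
    }
    keep <- c(keep, sel)
  }
  keep <- sort(keep)
  accessibility_matrix(am$entries[keep, , drop = FALSE],
                       meta[keep, , drop = FALSE],
                       am$peak_coords)
}

#' Candidate 2-kb tiles around a binding site
#'
#' Tiles lie on a genome-anchored grid of `tile` bp (so tiles are shared
#' between nearby sites) and must fall fully inside the window
#' `[center - window/2, center + window/2)`, clipped at the chromosome ends.
#' The tile containing the site center is excluded from the candidates.
#'
#' @param site One-row [peak_set()] (or data.frame with `chrom`, `start`,
#'   `end`).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param window Window width in bp (default 1 Mb).
#' @param tile Tile width in bp (default 2 kb).
#' @return A [peak_set()] of candidate tiles with ids
#'   `tile_<chrom>_<start>`.
#' @export
candidate_tiles <- function(site, chrom_sizes, window = 1e6, tile = 2000) {
  if (window < tile) stop("window must be at least one tile wide")
  ch <- site$chrom[1]
  if (!ch %in% names(chrom_sizes)) {
    stop("chromosome '", ch, "' absent from chrom_sizes")
  }
  size <- chrom_sizes[[ch]]
  center <- floor((site$start[1] + site$end[1]) / 2)
  if (center < 0 || center >= size) stop("site beyond chromosome bounds")
  win_start <- max(0, center - window / 2)
  win_end <- min(size, center + window / 2)
  first <- ceiling(win_start / tile)
  last <- floor(win_end / tile) - 1
  if (last < first) return(peak_set(character(), label = "tiles"))
  idx <- seq(first, last)
  self <- floor(center / tile)
  idx <- idx[idx != self]
  if (length(idx) == 0L) return(peak_set(character(), label = "tiles"))
  starts <- idx * tile
  peak_set(rep(ch, length(idx)), starts, starts + tile,
           id = sprintf("tile_%s_%d", ch, starts), label = "tiles")
}

#' Site-tile candidate pair layout for a set of binding sites
#'
#' Runs [candidate_tiles()] for every site and pools the results.
#'
#' @param sites [peak_set()] of binding sites.
#' @inheritParams candidate_tiles
#' @return List with `tiles` (deduplicated [peak_set()] of all candidate
#'   tiles) and `pairs` (`data.frame`: `site_id`, `tile_id`).
#' @export
candidate_pair_layout <- function(sites, chrom_sizes, window = 1e6,
                                  tile = 2000) {
  per_site <- lapply(seq_len(nrow(sites)), function(i) {
    tl <- candidate_tiles(sites[i, , drop = FALSE], chrom_sizes,
                          window = window, tile = tile)
    if (nrow(tl) == 0L) return(NULL)
    list(tiles = tl,
         pairs = data.frame(site_id = sites$id[i], tile_id = tl$id,
                            stringsAsFactors = FALSE))
  })
  per_site <- per_site[!vapply(per_site, is.null, TRUE)]
  if (length(per_site) == 0L) {
    return(list(tiles = peak_set(character(), label = "tiles"),
                pairs = data.frame(site_id = character(),
                                   tile_id = character())))
  }
  all_tiles <- do.call(rbind, lapply(per_site, function(x) {
    as.data.frame(x$tiles)[, c("chrom", "start", "end", "id")]
  }))
  all_tiles <- all_tiles[!duplicated(all_tiles$id), , drop = FALSE]
  tiles <- peak_set(all_tiles$chrom, all_tiles$start, all_tiles$end,
                    id = all_tiles$id, label = "tiles")
  pairs <- do.call(rbind, lapply(per_site, `[[`, "pairs"))
  list(tiles = tiles, pairs = pairs)
}

#' Pearson correlation between one site column and many tile columns
#'
#' Per-cell Pearson correlation (no aggregation of single cells) between
#' binary accessibility columns, which equals the phi coefficient. Columns
#' with zero variance yield `NA`.
#'
#' @param entries Binary sparse matrix (cells x peaks), or an
#'   [accessibility_matrix()].
#' @param site_col Column id or index of the site.
#' @param tile_cols Column ids or indices of the tiles.
#' @return Numeric vector of correlations, one per tile column.
#' @export
pairwise_correlation <- function(entries, site_col, tile_cols) {
  if (inherits(entries, "accessibility_matrix")) entries <- entries$entries
  n <- nrow(entries)
  if (n < 3L) stop("need at least 3 cells")
  x <- entries[, site_col]
  y <- entries[, tile_cols, drop = FALSE]
  sx <- sum(x)
  sy <- Matrix::colSums(y)
  sxy <- as.vector(Matrix::crossprod(y, x))
  # binary columns: sum(x^2) = sum(x)
  num <- n * sxy - sx * sy
  den2 <- (n * sx - sx^2) * (n * sy - sy^2)
  r <- ifelse(den2 > 0, num / sqrt(den2), NA_real_)
  unname(r)
}

#' Shuffled-matrix null model for co-accessibility
#'
#' Destroys all structure while preserving total density: the accessibility
#' entries are permuted jointly over the full cells x peaks matrix (each
#' shuffle places the nonzero entries uniformly at random). Correlations are
#' recomputed on the same site-tile pair layout as the real analysis, pooled
#' over shuffles, and the threshold is the empirical `percentile` quantile of
#' the pooled null correlations. The study's own matrices gave r = 0.07 at
#' the 99th percentile.
#'
#' @param am [accessibility_matrix()] (already subset to the condition under
#'   analysis).
#' @param pairs `data.frame` with `site_id`, `tile_id` — the real candidate
#'   pair layout.
#' @param n_shuffles Number of matrix shuffles pooled (default 10).
#' @param percentile Null quantile used as the r threshold (default 0.99).
#' @param seed Integer seed.
#' @return A `null_model` list: `threshold`, `shuffled_r_values`,
#'   `n_shuffles`, `percentile`, `seed`.
#' @export
shuffle_null_threshold <- function(am, pairs, n_shuffles = 10L,
                                   percentile = 0.99, seed = 1L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  entries <- if (inherits(am, "accessibility_matrix")) am$entries else am
  n <- nrow(entries); p <- ncol(entries)
  nnz <- Matrix::nnzero(entries)
  cols <- colnames(entries)
  site_ix <- match(pairs$site_id, cols)
  tile_ix <- match(pairs$tile_id, cols)
  if (anyNA(site_ix) || anyNA(tile_ix)) {
    stop("pair layout references columns absent from the matrix")
  }
  with_seed(seed, {
    pooled <- vector("list", n_shuffles)
    for (s in seq_len(n_shuffles)) {
      pos <- sample.int(n * p, nnz)  # uniform placement of all open entries
      i <- ((pos - 1L) %% n) + 1L
      j <- ((pos - 1L) %/% n) + 1L
      shuf <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, p))
      r_null <- numeric(nrow(pairs))
      for (sc in unique(site_ix)) {
        sel <- which(site_ix == sc)
        r_null[sel] <- pairwise_correlation(shuf, sc, tile_ix[sel])
      }
      pooled[[s]] <- r_null[!is.na(r_null)]
    }
    pooled <- unlist(pooled)
    if (length(pooled) < 500L) {
      warning("only ", length(pooled),
              " pooled null correlations; percentile estimate is unstable")
    }
    structure(list(
      threshold = unname(stats::quantile(pooled, percentile, type = 7)),
      shuffled_r_values = pooled,
      n_shuffles = n_shuffles,
      percentile = percentile,
      seed = seed), class = c("null_model", "list"))
  })
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "co-accessibility null model: %d pooled correlations from %d shuffle(s)\n%sth percentile r threshold = %.4f\n",
    length(x$shuffled_r_values), x$n_shuffles, 100 * x$percentile,
    x$threshold))
  invisible(x)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Student-t approximation: `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom (the approximation used downstream of ArchR-style
#' co-accessibility calls). `|r| = 1` gives p = 0 by convention.
#'
#' @param r Correlation value(s); `NA` propagates.
#' @param n_cells Number of cells (> 2).
#' @return Two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n_cells) {
  if (n_cells <= 2L) stop("need more than 2 cells")
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  exact1 <- ok & abs(r) >= 1
  p[exact1] <- 0
  mid <- ok & !exact1
  tval <- r[mid] * sqrt((n_cells - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tval), df = n_cells - 2)
  p
}

#' Percent accessible cells for a site pair
#'
#' QC covariate of a link: by default the average of the two per-site
#' accessible-cell fractions (`mode = "mean_of_fractions"`); the alternative
#' reading — the fraction of cells with either member open — is available as
#' `mode = "either_open"`.
#'
#' @param entries Binary matrix or [accessibility_matrix()].
#' @param site_col,tile_col Column ids or indices.
#' @param mode `"mean_of_fractions"` (default) or `"either_open"`.
#' @return Proportion in `[0, 1]`.
#' @export
percent_accessible <- function(entries, site_col, tile_col,
                               mode = c("mean_of_fractions", "either_open")) {
  mode <- match.arg(mode)
  if (inherits(entries, "accessibility_matrix")) entries <- entries$entries
  x <- entries[, site_col]
  y <- entries[, tile_col]
  if (mode == "mean_of_fractions") {
    (mean(x) + mean(y)) / 2
  } else {
    mean((x + y) > 0)
  }
}

#' Correlation, p-value and percent-accessible for a pair layout
#'
#' Computes the per-cell co-accessibility statistics for every site-tile
#' pair, optionally restricted to the cells of one (cell type, condition)
#' group.
#'
#' @param am [accessibility_matrix()].
#' @param pairs `data.frame` with `site_id`, `tile_id`.
#' @param condition,cell_type Optional cell filters.
#' @param pct_mode Passed to [percent_accessible()].
#' @return `data.frame`: `site_a`, `site_b`, `r`, `p`, `pct_accessible`,
#'   `condition`, `n_cells`.
#' @export
link_table <- function(am, pairs, condition = NULL, cell_type = NULL,
                       pct_mode = "mean_of_fractions") {
  keep <- rep(TRUE, nrow(am$cell_meta))
  if (!is.null(condition)) keep <- keep & am$cell_meta$condition %in% condition
  if (!is.null(cell_type)) keep <- keep & am$cell_meta$cell_type %in% cell_type
  entries <- am$entries[keep, , drop = FALSE]
  n <- nrow(entries)
  cols <- colnames(entries)
  site_ix <- match(pairs$site_id, cols)
  tile_ix <- match(pairs$tile_id, cols)
  if (anyNA(site_ix) || anyNA(tile_ix)) {
    stop("pair layout references columns absent from the matrix")
  }
  r <- numeric(nrow(pairs))
  for (sc in unique(site_ix)) {
    sel <- which(site_ix == sc)
    r[sel] <- pairwise_correlation(entries, sc, tile_ix[sel])
  }
  frac <- Matrix::colMeans(entries)
  pct <- if (pct_mode == "mean_of_fractions") {
    (frac[site_ix] + frac[tile_ix]) / 2
  } else {
    vapply(seq_len(nrow(pairs)), function(k) {
      percent_accessible(entries, site_ix[k], tile_ix[k], mode = "either_open")
    }, 1)
  }
  data.frame(site_a = pairs$site_id, site_b = pairs$tile_id,
             r = r, p = correlation_pvalue(r, n),
             pct_accessible = unname(pct),
             condition = if (is.null(condition)) NA_character_ else
               paste(condition, collapse = "+"),
             n_cells = n, stringsAsFactors = FALSE)
}

#' Call significant co-accessible links
#'
#' A pair is a significant co-accessible link iff its correlation exceeds
#' the null-model r threshold (strictly, one-sided positive — negative
#' correlations are never "co-accessible") and its p-value is below `alpha`.
#' All candidate pairs are retained with their significance flag.
#'
#' @param lt Link table from [link_table()].
#' @param null A `null_model` from [shuffle_null_threshold()].
#' @param alpha Raw p-value significance level (default 0.01, not
#'   multiplicity-adjusted).
#' @return `lt` with a logical `significant` column; threshold and alpha in
#'   attributes.
#' @export
call_links <- function(lt, null, alpha = 0.01) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  sig <- !is.na(lt$r) & lt$r > null$threshold & !is.na(lt$p) & lt$p < alpha
  lt$significant <- sig
  attr(lt, "r_threshold") <- null$threshold
  attr(lt, "alpha") <- alpha
  lt
}

#' Gained / lost / stable link status between two conditions
#'
#' Compares significance flags of the same pair universe in a reference and
#' a treated condition: `gained` = significant only in treated, `lost` =
#' significant only in reference, `stable` = both, `absent` = neither.
#'
#' @param links_reference,links_treated Outputs of [call_links()] over the
#'   identical pair universe.
#' @return `data.frame`: `site_a`, `site_b`, `status`, `r_reference`,
#'   `r_treated`.
#' @export
diff_links <- function(links_reference, links_treated) {
  key_r <- paste(links_reference$site_a, links_reference$site_b)
  key_t <- paste(links_treated$site_a, links_treated$site_b)
  if (length(key_r) != length(key_t) || !setequal(key_r, key_t)) {
    stop("link universes differ between conditions")
  }
  ord <- match(key_r, key_t)
  sig_r <- links_reference$significant
  sig_t <- links_treated$significant[ord]
  status <- ifelse(sig_t & !sig_r, "gained",
                   ifelse(sig_r & !sig_t, "lost",
                          ifelse(sig_r & sig_t, "stable", "absent")))
  data.frame(site_a = links_reference$site_a,
             site_b = links_reference$site_b,
             status = status,
             r_reference = links_reference$r,
             r_treated = links_treated$r[ord],
             stringsAsFactors = FALSE)
}
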