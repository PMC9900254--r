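#' Assign each ISG a STAT1/2-dependent regulation mechanism
#'
#' Three non-exclusive flags are derived per interferon-stimulated gene:
#' \itemize{
#'   \item `promoter_STAT12` — a STAT1/2 site overlaps the gene's promoter
#'     window (TSS +/- `flank`);
#'   \item `gained_distal_link` — a gained co-accessible link connects a
#'     distal STAT1/2 site to the gene (tile anchor within the promoter
#'     window or gene body extended by `proximal_margin`);
#'   \item `lost_distal_link` — likewise for lost links.
#' }
#' The single category resolves by priority promoter > gained > lost >
#' other: promoter binding dominates independently of additional distal
#' links.
#'
#' @param isg_genes Character vector of ISG gene ids.
#' @param stat_sites A `stat_site_table` from [classify_stat_sites()].
#' @param deltas Link deltas from [diff_links()].
#' @param tss_table Gene table (`chrom`, `start`, `end`, `gene`, `strand`).
#' @param tile_coords [peak_set()] resolving the tile ids in `deltas`.
#' @param flank Promoter half-width in bp (default 1000).
#' @param proximal_margin Extension of the gene body for link attribution
#'   (default 5000).
#' @param cell_type Label carried through to the output.
#' @return `data.frame` per ISG: flags, `category`
#'   (promoter/gained/lost/other), `unassignable` (gene absent from the
#'   annotation).
#' @export
assign_mechanism <- function(isg_genes, stat_sites, deltas, tss_table,
                             tile_coords, flank = 1000L,
                             proximal_margin = 5000L,
                             cell_type = NA_character_) {
  isg_genes <- unique(isg_genes)
  stat12 <- sites_as_peaks(stat_sites, "STAT1/2", label = "stat12")
  out <- data.frame(gene = isg_genes,
                    promoter_STAT12 = FALSE,
                    gained_distal_link = FALSE,
                    lost_distal_link = FALSE,
                    category = NA_character_,
                    unassignable = FALSE,
                    cell_type = cell_type,
                    stringsAsFactors = FALSE)
  gene_ix <- match(isg_genes, tss_table$gene)
  out$unassignable <- is.na(gene_ix)
  changed <- deltas[deltas$status %in% c("gained", "lost"), , drop = FALSE]
  tile_rows <- match(changed$site_b, tile_coords$id)
  if (nrow(changed) > 0L && anyNA(tile_rows)) {
    stop("delta tile id(s) absent from tile_coords")
  }
  tss <- tss_positions(tss_table)
  for (i in seq_len(nrow(out))) {
    gi <- gene_ix[i]
    if (is.na(gi)) next
    g_chrom <- tss_table$chrom[gi]
    prom_lo <- max(tss[gi] - flank, 0)
    prom_hi <- tss[gi] + flank
    body_lo <- max(tss_table$start[gi] - proximal_margin, 0)
    body_hi <- tss_table$end[gi] + proximal_margin
    ov <- function(lo, hi, s, e) s < hi & e > lo  # half-open overlap
    # promoter-bound STAT1/2
    in_prom <- stat12$chrom == g_chrom &
      ov(prom_lo, prom_hi, stat12$start, stat12$end)
    out$promoter_STAT12[i] <- any(in_prom)
    if (nrow(changed) > 0L) {
      t_chrom <- tile_coords$chrom[tile_rows]
      t_start <- tile_coords$start[tile_rows]
      t_end <- tile_coords$end[tile_rows]
      anchors <- t_chrom == g_chrom &
        (ov(prom_lo, prom_hi, t_start, t_end) |
           ov(body_lo, body_hi, t_start, t_end))
      # the linked STAT1/2 site must be distal: not in this gene's promoter
      site_rows <- match(changed$site_a, stat_sites$id)
      distal <- !(stat_sites$chrom[site_rows] == g_chrom &
                    ov(prom_lo, prom_hi, stat_sites$start[site_rows],
                       stat_sites$end[site_rows]))
      hit <- anchors & distal
      out$gained_distal_link[i] <- any(hit & changed$status == "gained")
      out$lost_distal_link[i] <- any(hit & changed$status == "lost")
    }
  }
  out$category <- ifelse(out$unassignable, NA_character_,
                  ifelse(out$promoter_STAT12, "promoter",
                  ifelse(out$gained_distal_link, "gained",
                  ifelse(out$lost_distal_link, "lost", "other"))))
  out
}

#' Type the distal partner of a link: ISG promoter or enhancer
#'
#' A distal STAT1/2-bound partner counts as `"ISG-promoter"` iff it overlaps
#' the promoter window (TSS +/- `flank`) of any ISG; all other partners —
#' exonic, intronic or intergenic, including non-ISG promoters — are typed
#' `"enhancer"`.
#'
#' @param site_ids Ids of partner sites (rows of `stat_sites`).
#' @param stat_sites A `stat_site_table`.
#' @param isg_genes Character vector of ISG ids.
#' @param tss_table Gene table as in [assign_mechanism()].
#' @param flank Promoter half-width (default 1000).
#' @return Character vector, one type per id.
#' @export
distal_partner_type <- function(site_ids, stat_sites, isg_genes, tss_table,
                                flank = 1000L) {
  rows <- match(site_ids, stat_sites$id)
  if (anyNA(rows)) stop("unknown site id(s)")
  isg_tab <- tss_table[tss_table$gene %in% isg_genes, , drop = FALSE]
  if (nrow(isg_tab) == 0L) return(rep("enhancer", length(site_ids)))
  sites <- peak_set(stat_sites$chrom[rows], stat_sites$start[rows],
                    stat_sites$end[rows],
                    id = sprintf("q_%d", seq_along(rows)), label = "q")
  flag <- promoter_flag(sites, isg_tab, flank = flank)
  # peak_set resorts rows; map flags back to query order
  flag <- flag[match(sprintf("q_%d", seq_along(rows)), sites$id)]
  ifelse(flag, "ISG-promoter", "enhancer")
}

#' Count ISGs supported by more than one regulation mechanism
#'
#' @param assignments Output of [assign_mechanism()].
#' @return List with `n_multi` (ISGs with >= 2 flags), `per_combination`
#'   (table over flag combinations), `n_assigned`.
#' @export
mechanism_overlap <- function(assignments) {
  a <- assignments[!assignments$unassignable, , drop = FALSE]
  flags <- a[, c("promoter_STAT12", "gained_distal_link", "lost_distal_link")]
  nf <- rowSums(flags)
  combo <- apply(flags, 1, function(f) {
    nm <- c("promoter", "gained", "lost")[as.logical(f)]
    if (length(nm) == 0L) "none" else paste(nm, collapse = "+")
  })
  list(n_multi = sum(nf >= 2),
       per_combination = table(combo),
       n_assigned = nrow(a))
}

#' Compare ISG induction between regulation categories
#'
#' Pairwise two-sided Wilcoxon rank-sum tests of expression change between
#' every pair of regulation categories, per time point. Categories with
#' fewer than `min_n` genes are skipped with a notice. The normal
#' approximation with tie correction is used except for very small groups
#' (`n < 10`), where the exact test applies.
#'
#' @param assignments Output of [assign_mechanism()].
#' @param expression_changes `data.frame` with `gene` plus one numeric log
#'   fold change column per time point.
#' @param min_n Minimum genes per compared category (default 3).
#' @return `data.frame`: `time`, `category_a`, `category_b`, `n_a`, `n_b`,
#'   `median_a`, `median_b`, `p`, `stars`, `skipped`.
#' @export
category_expression_test <- function(assignments, expression_changes,
                                     min_n = 3L) {
  time_cols <- setdiff(names(expression_changes), "gene")
  a <- assignments[!assignments$unassignable, , drop = FALSE]
  lfc_row <- match(a$gene, expression_changes$gene)
  cats <- intersect(c("promoter", "gained", "lost", "other"),
                    unique(a$category))
  rows <- list()
  for (tc in time_cols) {
    lfc <- expression_changes[[tc]][lfc_row]
    for (i in seq_along(cats)) for (j in seq_along(cats)) {
      if (j <= i) next
      xa <- lfc[a$category == cats[i] & !is.na(lfc)]
      xb <- lfc[a$category == cats[j] & !is.na(lfc)]
      skipped <- length(xa) < min_n || length(xb) < min_n
      p <- NA_real_
      if (!skipped) {
        exact <- min(length(xa), length(xb)) < 10
        p <- suppressWarnings(
          stats::wilcox.test(xa, xb, alternative = "two.sided",
                             exact = exact, correct = TRUE)$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        time = tc, category_a = cats[i], category_b = cats[j],
        n_a = length(xa), n_b = length(xb),
        median_a = if (length(xa)) stats::median(xa) else NA_real_,
        median_b = if (length(xb)) stats::median(xb) else NA_real_,
        p = p, stars = p_stars(p), skipped = skipped,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Significance star bins: * <0.05, ** <0.01, *** <0.001, **** <0.0001.
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***" else
      if (pp < 1e-2) "**" else if (pp < 0.05) "*" else "ns"
  }, "")
}
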