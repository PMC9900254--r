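#' Classify binding sites into STAT1, STAT2 and STAT1/2
#'
#' STAT1/2 sites — the proxy for ISGF3 binding — are loci where a STAT1 peak
#' and a STAT2 peak overlap; each overlapping pair (or chain) is merged into
#' one spanning locus. Peaks bound by only one factor are classified STAT1 or
#' STAT2. Input peak lists are expected to be the per-cell-type combined
#' lists over treatment time points (combine with [union_sets()] first when
#' needed).
#'
#' @param stat1_peaks,stat2_peaks [peak_set()]s of per-factor peaks.
#' @param min_overlap Minimum shared bases to call a STAT1/2 site.
#' @param cell_type Cell type label attached to the table.
#' @return A `data.frame` (`stat_site_table`): `chrom`, `start`, `end`, `id`,
#'   `class` in {STAT1, STAT2, STAT1/2}, `members`, `cell_type`. Class counts
#'   are in the `"counts"` attribute.
#' @export
classify_stat_sites <- function(stat1_peaks, stat2_peaks, min_overlap = 1L,
                                cell_type = NA_character_) {
  u <- union_sets(stat1_peaks, stat2_peaks, min_overlap = min_overlap,
                  label = "statsite")
  cls <- c(a_only = "STAT1", b_only = "STAT2", shared = "STAT1/2")
  out <- data.frame(chrom = u$chrom, start = u$start, end = u$end,
                    id = u$id, class = unname(cls[u$membership]),
                    members = u$members, cell_type = cell_type,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(
    "STAT1" = sum(out$class == "STAT1"),
    "STAT2" = sum(out$class == "STAT2"),
    "STAT1/2" = sum(out$class == "STAT1/2"))
  class(out) <- c("stat_site_table", "data.frame")
  out
}

#' @export
print.stat_site_table <- function(x, ...) {
  cat(sprintf("stat_site_table (%s): %d sites\n",
              x$cell_type[1], nrow(x)))
  print(attr(x, "counts"))
  invisible(x)
}

#' Extract site classes from a site table as a peak set
#'
#' @param site_table A `stat_site_table` from [classify_stat_sites()].
#' @param classes Site classes to keep.
#' @param label Label of the returned [peak_set()].
#' @return A [peak_set()] of the selected sites.
#' @export
sites_as_peaks <- function(site_table, classes = c("STAT1", "STAT2", "STAT1/2"),
                           label = "sites") {
  keep <- site_table$class %in% classes
  peak_set(site_table$chrom[keep], site_table$start[keep],
           site_table$end[keep], id = site_table$id[keep], label = label)
}

#' Cross-cell-type comparison of binding-site tables
#'
#' For each site class, counts sites common to both cell types and specific
#' to either, by coordinate overlap. Symmetric in its arguments up to
#' swapping the specific labels.
#'
#' @param table_a,table_b `stat_site_table`s from [classify_stat_sites()]
#'   on the same genome.
#' @param min_overlap Minimum shared bases to call two sites the same locus.
#' @return `data.frame` with one row per class: `class`, `n_a`, `n_b`,
#'   `common`, `a_specific`, `b_specific` (common counted in `a` loci).
#' @export
cross_celltype_overlap <- function(table_a, table_b, min_overlap = 1L) {
  classes <- c("STAT1", "STAT2", "STAT1/2")
  rows <- lapply(classes, function(cl) {
    pa <- sites_as_peaks(table_a, cl, label = "a")
    pb <- sites_as_peaks(table_b, cl, label = "b")
    ov <- overlap_sets(pa, pb, min_overlap = min_overlap)
    common_a <- length(unique(ov$id_a))
    common_b <- length(unique(ov$id_b))
    data.frame(class = cl, n_a = nrow(pa), n_b = nrow(pb),
               common = common_a,
               a_specific = nrow(pa) - common_a,
               b_specific = nrow(pb) - common_b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalized chromatin-feature enrichments at binding sites
#'
#' Converts raw read counts in +/-1 kb windows around binding sites into
#' enrichments over a matched control (histone H3 for histone marks, IgG for
#' STAT factors): counts are normalized for library depth and a per-sample
#' fragment-length scalar, a one-read pseudocount is added to both signal and
#' control, the signal rate is divided by the control rate, and replicates of
#' the same feature/condition are averaged.
#'
#' @param site_counts Sites x samples matrix of raw read counts.
#' @param sample_sheet `data.frame` with one row per signal sample: columns
#'   `sample` (column name in `site_counts`), `feature`, `control` (column
#'   name of the matched control sample), `replicate`, `library_size`,
#'   optional `fragment_length` (default 1), and the controls' own
#'   `library_size`/`fragment_length` given on rows where
#'   `sample == control` (feature `"control"`).
#' @param control_counts Sites x control-samples matrix of raw control
#'   counts.
#' @param control_sheet `data.frame` with columns `sample`, `library_size`,
#'   optional `fragment_length` for the control samples.
#' @param pseudocount Reads added to signal and control counts (default 1).
#' @return Sites x features matrix of replicate-averaged enrichments
#'   (`chromatin feature matrix`).
#' @export
quantify_chromatin_features <- function(site_counts, sample_sheet,
                                        control_counts, control_sheet,
                                        pseudocount = 1) {
  if (any(site_counts < 0) || any(control_counts < 0)) {
    stop("read counts must be non-negative")
  }
  if (is.null(sample_sheet$fragment_length)) sample_sheet$fragment_length <- 1
  if (is.null(control_sheet$fragment_length)) control_sheet$fragment_length <- 1
  if (any(control_sheet$library_size <= 0)) {
    stop("control library sizes must be positive")
  }
  if (any(sample_sheet$library_size <= 0)) {
    stop("library sizes must be positive")
  }
  miss <- setdiff(sample_sheet$control, control_sheet$sample)
  if (length(miss) > 0L) {
    stop("control sample(s) missing: ", paste(miss, collapse = ", "))
  }
  feats <- unique(sample_sheet$feature)
  out <- matrix(NA_real_, nrow = nrow(site_counts), ncol = length(feats),
                dimnames = list(rownames(site_counts), feats))
  for (f in feats) {
    rows <- which(sample_sheet$feature == f)
    enr <- vapply(rows, function(r) {
      s <- sample_sheet[r, ]
      ci <- match(s$control, control_sheet$sample)
      sig_rate <- (site_counts[, s$sample] + pseudocount) /
        (s$library_size * s$fragment_length)
      ctl_rate <- (control_counts[, control_sheet$sample[ci]] + pseudocount) /
        (control_sheet$library_size[ci] * control_sheet$fragment_length[ci])
      sig_rate / ctl_rate
    }, numeric(nrow(site_counts)))
    out[, f] <- rowMeans(matrix(enr, nrow = nrow(site_counts)))
  }
  out
}
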