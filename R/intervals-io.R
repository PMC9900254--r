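#' Construct a peak set
#'
#' A peak set is an ordered table of genomic intervals in BED convention:
#' 0-based, half-open coordinates (`start` inclusive, `end` exclusive).
#' Intervals are sorted by (chrom, start) and interval ids must be unique
#' within the set.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based start positions.
#' @param end Integer vector of end positions (exclusive); must satisfy
#'   `start < end`.
#' @param id Character vector of unique interval ids. Auto-generated from the
#'   label and coordinates when missing.
#' @param strand Optional strand vector in `{"+", "-", "."}`.
#' @param label Short name for the set (e.g. `"STAT1_ESC"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `id`,
#'   `strand`, carrying the label as the `"label"` attribute.
#' @export
peak_set <- function(chrom, start, end, id = NULL, strand = NULL,
                     label = "peaks") {
  if (length(chrom) == 0L) {
    ps <- data.frame(chrom = character(), start = integer(), end = integer(),
                     id = character(), strand = character(),
                     stringsAsFactors = FALSE)
    attr(ps, "label") <- label
    class(ps) <- c("peak_set", "data.frame")
    return(ps)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!nzchar(chrom))) stop("chromosome names must be non-empty")
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("empty or inverted interval at row %d: start %s >= end %s",
                 bad[1], format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)))
  }
  if (is.null(id)) {
    id <- sprintf("%s_%s_%s_%s", label, chrom,
                  format(start, scientific = FALSE, trim = TRUE),
                  format(end, scientific = FALSE, trim = TRUE))
  }
  id <- as.character(id)
  if (anyDuplicated(id)) stop("interval ids must be unique within a peak set")
  if (is.null(strand)) strand <- rep(".", length(chrom))
  ps <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   id = id, strand = as.character(strand),
                   stringsAsFactors = FALSE)
  ps <- ps[order(ps$chrom, ps$start, ps$end), , drop = FALSE]
  rownames(ps) <- NULL
  attr(ps, "label") <- label
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d intervals on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

# GRanges view of a peak set (1-based closed, as GenomicRanges expects).
# A shared seqlevels vocabulary avoids cross-object seqlevel warnings.
as_granges <- function(ps, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(ps$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(ps$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = ps$start + 1L, end = ps$end),
    id = ps$id
  )
}

#' Read a BED file into a peak set
#'
#' Accepts 3+-column BED (chrom, start, end, [name, score, strand]).
#' Coordinates are kept 0-based half-open. Malformed lines are reported with
#' their line number.
#'
#' @param path Path to a BED file.
#' @param label Label for the resulting set; defaults to the file name.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, label = NULL) {
  if (is.null(label)) label <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(peak_set(character(), label = label))
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", which(nf < 3L)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinate",
                 which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BED line %d: start >= end", bad[1]))
  }
  id <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  if (anyNA(id)) id <- NULL
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, "", 6L) else NULL
  peak_set(chrom, start, end, id = id, strand = strand, label = label)
}

#' Write a peak set to BED
#'
#' @param ps A [peak_set()].
#' @param path Output path. Writes BED6 (name = id, score = 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(ps, path) {
  df <- data.frame(ps$chrom,
                   format(ps$start, scientific = FALSE, trim = TRUE),
                   format(ps$end, scientific = FALSE, trim = TRUE),
                   ps$id, 0L, ps$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an accessibility matrix bundle
#'
#' @param entries A sparse cells x peaks matrix; any nonzero entry is
#'   binarized to 1.
#' @param cell_meta `data.frame` with columns `barcode`, `cell_type`,
#'   `condition`, `fragment_count`; one row per matrix row.
#' @param peak_coords A [peak_set()] with one interval per matrix column.
#' @return An object of class `accessibility_matrix`.
#' @export
accessibility_matrix <- function(entries, cell_meta, peak_coords) {
  # pattern/logical sparse matrices (e.g. MatrixMarket "pattern") lack an
  # x slot; go through dMatrix first
  if (!methods::is(entries, "dMatrix")) {
    entries <- methods::as(entries, "dMatrix")
  }
  entries <- methods::as(entries, "CsparseMatrix")
  entries@x[] <- 1
  entries <- Matrix::drop0(entries)
  req <- c("barcode", "cell_type", "condition", "fragment_count")
  miss <- setdiff(req, names(cell_meta))
  if (length(miss) > 0L) {
    stop("cell_meta missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(entries) != nrow(cell_meta)) {
    stop(sprintf("matrix has %d rows but cell_meta has %d", nrow(entries),
                 nrow(cell_meta)))
  }
  if (ncol(entries) != nrow(peak_coords)) {
    stop(sprintf("matrix has %d columns but peak_coords has %d intervals",
                 ncol(entries), nrow(peak_coords)))
  }
  rownames(entries) <- cell_meta$barcode
  colnames(entries) <- peak_coords$id
  structure(list(entries = entries, cell_meta = cell_meta,
                 peak_coords = peak_coords),
            class = "accessibility_matrix")
}

#' @export
print.accessibility_matrix <- function(x, ...) {
  cat(sprintf(
    "accessibility_matrix: %d cells x %d peaks, density %.4f\n",
    nrow(x$entries), ncol(x$entries),
    Matrix::nnzero(x$entries) / prod(dim(x$entries))))
  grp <- table(x$cell_meta$cell_type, x$cell_meta$condition)
  print(grp)
  invisible(x)
}

#' Read a cells x peaks accessibility matrix from MatrixMarket sidecar files
#'
#' Expects the triplet matrix (cells x peaks), a barcode list, a peak BED and
#' a metadata TSV with columns `barcode`, `cell_type`, `condition`,
#' `fragment_count`. Nonzero entries are binarized.
#'
#' @param matrix_path MatrixMarket coordinate file.
#' @param barcodes_path One barcode per line, in matrix row order.
#' @param peaks_path BED file of peaks, in matrix column order after sorting.
#' @param meta_path Metadata TSV (must cover every barcode).
#' @return An [accessibility_matrix()].
#' @export
read_accessibility_mtx <- function(matrix_path, barcodes_path, peaks_path,
                                   meta_path) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(barcodes) != nrow(m)) {
    stop(sprintf("barcode count (%d) != declared matrix rows (%d)",
                 length(barcodes), nrow(m)))
  }
  peaks <- read_bed(peaks_path, label = "peaks")
  if (nrow(peaks) != ncol(m)) {
    stop(sprintf("peak count (%d) != declared matrix columns (%d)",
                 nrow(peaks), ncol(m)))
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  missing_bc <- setdiff(barcodes, meta$barcode)
  if (length(missing_bc) > 0L) {
    stop("barcode(s) absent from metadata: ",
         paste(utils::head(missing_bc, 3), collapse = ", "))
  }
  meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  accessibility_matrix(m, meta, peaks)
}

#' Write an accessibility matrix bundle to a directory
#'
#' Emits `matrix.mtx`, `barcodes.tsv`, `peaks.bed` and `cell_meta.tsv`,
#' the formats [read_accessibility_mtx()] reads back.
#'
#' @param am An [accessibility_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_accessibility_mtx <- function(am, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(am$entries, file.path(dir, "matrix.mtx"))
  writeLines(am$cell_meta$barcode, file.path(dir, "barcodes.tsv"))
  write_bed(am$peak_coords, file.path(dir, "peaks.bed"))
  utils::write.table(am$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Overlapping interval pairs between two peak sets
#'
#' Returns every (a-id, b-id) pair sharing at least `min_overlap` bases,
#' equivalent to an all-pairs scan.
#'
#' @param a,b [peak_set()] objects.
#' @param min_overlap Minimum shared bases (default 1).
#' @return `data.frame` with columns `id_a`, `id_b`.
#' @export
overlap_sets <- function(a, b, min_overlap = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  }
  lv <- union(a$chrom, b$chrom)
  hits <- GenomicRanges::findOverlaps(as_granges(a, lv), as_granges(b, lv),
                                      minoverlap = min_overlap)
  data.frame(id_a = a$id[S4Vectors::queryHits(hits)],
             id_b = b$id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Union of two peak sets with membership flags
#'
#' Intervals present in both sets (by the overlap criterion) are merged to
#' their spanning interval and flagged `"shared"`; the rest keep their
#' coordinates and are flagged `"a_only"` / `"b_only"`. When more than two
#' intervals chain-overlap, the merged locus spans all of them and carries all
#' contributing ids. Inclusion-exclusion holds:
#' `|union| = |a| + |b| - |shared pairs counted as merged loci|`.
#'
#' @param a,b [peak_set()] objects.
#' @param min_overlap Minimum shared bases for "shared" (default 1).
#' @param label Label of the output set.
#' @return A [peak_set()] with extra columns `membership`
#'   (`a_only`/`b_only`/`shared`) and `members` (comma-joined contributing
#'   ids).
#' @export
union_sets <- function(a, b, min_overlap = 1L, label = "union") {
  na <- nrow(a); nb <- nrow(b)
  if (na + nb == 0L) return(peak_set(character(), label = label))
  all_chrom <- c(a$chrom, b$chrom)
  all_start <- c(a$start, b$start)
  all_end <- c(a$end, b$end)
  all_id <- c(a$id, b$id)
  origin <- rep(c("a", "b"), c(na, nb))
  gr <- GenomicRanges::GRanges(all_chrom,
                               IRanges::IRanges(all_start + 1L, all_end))
  # connected components of the cross-set overlap graph: intervals from
  # opposite sets that overlap are merged into one locus
  hits <- GenomicRanges::findOverlaps(gr, minoverlap = min_overlap,
                                      drop.self = TRUE, drop.redundant = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  cross <- origin[qh] != origin[sh]
  comp <- seq_along(all_id)
  find_root <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (k in which(cross)) {
    ri <- find_root(qh[k]); rj <- find_root(sh[k])
    if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_along(comp), find_root, 1L)
  groups <- split(seq_along(root), root)
  rows <- lapply(groups, function(ix) {
    memb <- unique(origin[ix])
    data.frame(
      chrom = all_chrom[ix[1]],
      start = min(all_start[ix]),
      end = max(all_end[ix]),
      membership = if (length(memb) == 2L) "shared" else
        if (memb == "a") "a_only" else "b_only",
      members = paste(sort(all_id[ix]), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ps <- peak_set(out$chrom, out$start, out$end,
                 id = sprintf("%s_%05d", label, seq_len(nrow(out))),
                 label = label)
  key <- paste(out$chrom, out$start, out$end)
  ord <- match(paste(ps$chrom, ps$start, ps$end), key)
  ps$membership <- out$membership[ord]
  ps$members <- out$members[ord]
  ps
}

# TSS positions (0-based single bp) from a gene table with columns
# chrom, start, end, gene, strand: start for '+', end-1 for '-'.
tss_positions <- function(tss_table) {
  req <- c("chrom", "start", "end", "gene", "strand")
  miss <- setdiff(req, names(tss_table))
  if (length(miss) > 0L) {
    stop("tss table missing column(s): ", paste(miss, collapse = ", "))
  }
  ifelse(tss_table$strand == "-", tss_table$end - 1L, tss_table$start)
}

#' Flag binding sites overlapping a promoter window
#'
#' A site is a promoter site iff it overlaps `[TSS - flank, TSS + flank)`
#' (0-based half-open) of any gene. TSS is the gene start on the plus strand
#' and `end - 1` on the minus strand.
#'
#' @param sites A [peak_set()].
#' @param tss_table `data.frame` with columns `chrom`, `start`, `end`,
#'   `gene`, `strand`.
#' @param flank Half-width of the promoter window in bp (default 1000).
#' @return Logical vector, one flag per site, in site order.
#' @export
promoter_flag <- function(sites, tss_table, flank = 1000L) {
  if (nrow(sites) == 0L) return(logical(0))
  unknown <- setdiff(sites$chrom, tss_table$chrom)
  if (length(unknown) > 0L) {
    warning("chromosome(s) absent from TSS table treated as non-promoter: ",
            paste(unknown, collapse = ", "))
  }
  tss <- tss_positions(tss_table)
  win_start <- pmax(tss - flank, 0)
  win_end <- tss + flank
  keep <- win_start < win_end
  lv <- union(sites$chrom, tss_table$chrom)
  win <- GenomicRanges::GRanges(factor(tss_table$chrom[keep], levels = lv),
                                IRanges::IRanges(win_start[keep] + 1L,
                                                 win_end[keep]))
  IRanges::overlapsAny(as_granges(sites, lv), win)
}

#' Nearest gene by TSS distance
#'
#' For each site, the gene whose TSS is closest to the site center
#' (`floor((start + end)/2)`). Ties go to the lexicographically smaller gene
#' id. Sites on chromosomes with no annotated TSS get `NA` gene and `NA`
#' distance.
#'
#' @param sites A [peak_set()].
#' @param tss_table Gene table as in [promoter_flag()].
#' @return `data.frame` with columns `id`, `gene`, `distance`.
#' @export
nearest_tss <- function(sites, tss_table) {
  tss <- tss_positions(tss_table)
  center <- floor((sites$start + sites$end) / 2)
  out <- data.frame(id = sites$id, gene = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(sites$chrom)) {
    on_ch <- which(tss_table$chrom == ch)
    if (length(on_ch) == 0L) next
    s_ix <- which(sites$chrom == ch)
    # order candidates by (distance, gene id) so the first match is the
    # deterministic tie-break winner
    for (i in s_ix) {
      d <- abs(center[i] - tss[on_ch])
      ord <- order(d, tss_table$gene[on_ch])
      out$gene[i] <- tss_table$gene[on_ch][ord[1]]
      out$distance[i] <- d[ord[1]]
    }
  }
  out
}

#' Three-way Venn region counts
#'
#' Splits three id sets into the seven disjoint Venn regions and reports the
#' union size, as used for the per-cell-type ISG sets.
#'
#' @param a,b,c Character vectors of ids (e.g. ISG names per cell type).
#' @param names Names of the three sets.
#' @return Named list: per-region counts, per-set totals, pairwise
#'   intersection totals and `union`.
#' @export
venn_counts <- function(a, b, c, names = c("a", "b", "c")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  region <- paste0(ifelse(in_a, "1", "0"), ifelse(in_b, "1", "0"),
                   ifelse(in_c, "1", "0"))
  cnt <- function(code) sum(region == code)
  res <- list(
    only_a = cnt("100"), only_b = cnt("010"), only_c = cnt("001"),
    ab_only = cnt("110"), ac_only = cnt("101"), bc_only = cnt("011"),
    abc = cnt("111"),
    total_a = length(a), total_b = length(b), total_c = length(c),
    ab = sum(in_a & in_b), ac = sum(in_a & in_c), bc = sum(in_b & in_c),
    union = length(u))
  attr(res, "set_names") <- names
  res
}

#' Reconstruct three id sets from Venn region counts
#'
#' Inverse of [venn_counts()]: builds three synthetic id sets whose Venn
#' decomposition matches the given disjoint region counts. Used to turn
#' printed Venn-diagram counts back into concrete sets for set arithmetic.
#'
#' @param only_a,only_b,only_c,ab_only,ac_only,bc_only,abc Region sizes.
#' @param prefix Id prefix.
#' @return List of three character vectors `a`, `b`, `c`.
#' @export
sets_from_venn <- function(only_a, only_b, only_c, ab_only, ac_only,
                           bc_only, abc, prefix = "g") {
  sizes <- c(only_a, only_b, only_c, ab_only, ac_only, bc_only, abc)
  if (any(sizes < 0)) stop("region counts must be non-negative")
  total <- sum(sizes)
  ids <- sprintf("%s%05d", prefix, seq_len(total))
  reg <- rep(c("100", "010", "001", "110", "101", "011", "111"), sizes)
  list(a = ids[substr(reg, 1, 1) == "1"],
       b = ids[substr(reg, 2, 2) == "1"],
       c = ids[substr(reg, 3, 3) == "1"])
}
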