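#' Default pipeline configuration
#'
#' Parameters of the all-synthetic demo pipeline. Analysis parameters
#' default to the study settings (1 Mb window, 2 kb tiles, 99th-percentile
#' shuffled null, alpha 0.01, k = 5 states, +/-1 kb promoter windows);
#' problem sizes default to desk scale.
#'
#' @param seed Master seed; per-stage streams are derived from it.
#' @param outdir Output directory.
#' @return Named list of parameters.
#' @export
default_config <- function(seed = 1L, outdir = tempfile("ifnchrom_run_")) {
  list(
    seed = seed,
    outdir = outdir,
    chrom_sizes = c(chr1 = 6e7, chr2 = 6e7),
    n_stat1 = 60L, n_stat2 = 70L, n_overlap = 25L, n_tss = 80L,
    n_cells_per_group = 400L, cells_per_group = 300L,
    baseline_rate = 0.1,
    fragment_meanlog = log(5000), fragment_sdlog = 0.3,
    n_planted_gained = 8L, n_planted_lost = 4L, planted_effect = 0.9,
    window = 1e6, tile = 2000,
    n_shuffles = 5L, null_percentile = 0.99, alpha = 0.01,
    flank = 1000L, proximal_margin = 5000L,
    n_genes = 2000L, isg_fraction = 0.05, induction_fold = 8,
    k_states = 5L, k_scan = 2:8, n_init = 10L,
    sites_per_state = 30L, state_noise_sd = 0.8)
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  if (config$alpha <= 0 || config$alpha > 1) {
    stop("config invalid: alpha must lie in (0, 1]")
  }
  if (config$baseline_rate <= 0 || config$baseline_rate >= 1) {
    stop("config invalid: baseline_rate must lie in (0, 1)")
  }
  if (config$null_percentile <= 0 || config$null_percentile >= 1) {
    stop("config invalid: null_percentile must lie in (0, 1)")
  }
  if (config$cells_per_group > config$n_cells_per_group) {
    stop("config invalid: cells_per_group exceeds simulated cells per group")
  }
  if (config$window < config$tile) {
    stop("config invalid: window smaller than tile")
  }
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic demo pipeline
#'
#' Executes the stages in dependency order — simulate, site classification,
#' co-accessibility, regulation mechanisms, chromatin states — writes every
#' stage output as TSV under `config$outdir`, serializes the configuration,
#' and writes a manifest with an md5 checksum per output. Rerunning with the
#' same configuration and seed reproduces identical checksums.
#'
#' @param config List from [default_config()] (possibly modified).
#' @return Invisible list with the in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ## stage 1: binding landscape and site classification
  land <- generate_binding_landscape(
    config$chrom_sizes, config$n_stat1, config$n_stat2, config$n_overlap,
    n_tss = config$n_tss, seed = seed + 101L)
  sites <- classify_stat_sites(land$stat1, land$stat2, cell_type = "ESC")
  stat12 <- sites_as_peaks(sites, "STAT1/2", label = "stat12")

  ## stage 2: accessibility matrix with planted links
  layout <- candidate_pair_layout(stat12, config$chrom_sizes,
                                  window = config$window, tile = config$tile)
  peaks_all <- peak_set(
    c(stat12$chrom, layout$tiles$chrom),
    c(stat12$start, layout$tiles$start),
    c(stat12$end, layout$tiles$end),
    id = c(stat12$id, layout$tiles$id), label = "matrix_peaks")
  isg_genes <- demo_isg_genes(land, layout, config, seed + 403L)
  planted <- plant_demo_links(layout, land$tss_table, isg_genes, sites,
                              config, seed + 202L)
  sim <- generate_accessibility_matrix(
    config$n_cells_per_group, peaks_all, planted,
    baseline_rate = config$baseline_rate,
    fragment_count_distribution = list(meanlog = config$fragment_meanlog,
                                       sdlog = config$fragment_sdlog),
    groups = data.frame(cell_type = "ESC", condition = c("0h", "6h")),
    seed = seed + 203L)

  ## stage 3: co-accessibility per condition
  am <- select_balanced_cells(sim$matrix, config$cells_per_group)
  links <- list()
  for (cond in c("0h", "6h")) {
    keep <- am$cell_meta$condition == cond
    am_c <- accessibility_matrix(am$entries[keep, , drop = FALSE],
                                 am$cell_meta[keep, , drop = FALSE],
                                 am$peak_coords)
    null <- shuffle_null_threshold(am_c, layout$pairs,
                                   n_shuffles = config$n_shuffles,
                                   percentile = config$null_percentile,
                                   seed = seed + 301L)
    links[[cond]] <- call_links(link_table(am, layout$pairs, condition = cond),
                                null, alpha = config$alpha)
  }
  deltas <- diff_links(links[["0h"]], links[["6h"]])

  ## stage 4: expression, ISGs, regulation mechanisms
  expr <- generate_expression_table(
    config$n_genes, isg_fraction = config$isg_fraction,
    induction_fold = config$induction_fold, seed = seed + 401L)
  fit <- fit_two_gaussians(log10(expr$expression[["0h"]] + 0.01),
                           seed = seed + 402L)
  classes <- classify_genes(expr$expression, fit$threshold)
  assign <- assign_mechanism(isg_genes, sites, deltas, land$tss_table,
                             layout$tiles, flank = config$flank,
                             proximal_margin = config$proximal_margin,
                             cell_type = "ESC")
  overlap <- mechanism_overlap(assign)

  ## stage 5: chromatin states at the site universe
  nstates <- stats::setNames(rep(config$sites_per_state, 5),
                             state_vocabulary())
  fm <- generate_feature_matrix(nstates, noise_sd = config$state_noise_sd,
                                seed = seed + 501L)
  st <- cluster_states(fm$features, k = config$k_states,
                       k_scan = config$k_scan, n_init = config$n_init,
                       seed = seed + 502L)

  ## outputs + manifest
  outputs <- c(
    write_tsv(as.data.frame(sites), file.path(config$outdir, "stat_sites.tsv")),
    write_tsv(links[["0h"]], file.path(config$outdir, "links_0h.tsv")),
    write_tsv(links[["6h"]], file.path(config$outdir, "links_6h.tsv")),
    write_tsv(deltas, file.path(config$outdir, "link_deltas.tsv")),
    write_tsv(classes, file.path(config$outdir, "gene_classes.tsv")),
    write_tsv(assign, file.path(config$outdir, "isg_mechanisms.tsv")),
    write_tsv(st$assignment, file.path(config$outdir, "chromatin_states.tsv")),
    write_tsv(st$silhouette, file.path(config$outdir, "silhouette_scan.tsv")))
  cfg_path <- file.path(config$outdir, "config.yaml")
  cfg <- config
  cfg$k_scan <- as.integer(cfg$k_scan)
  yaml::write_yaml(cfg, cfg_path)
  outputs <- c(outputs, cfg_path)
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  invisible(list(sites = sites, links = links, deltas = deltas,
                 mixture_fit = fit, gene_classes = classes,
                 assignments = assign, mechanism_overlap = overlap,
                 states = st, manifest = manifest, truth = list(
                   landscape = land$truth, matrix = sim$truth,
                   expression = expr$truth, states = fm$truth,
                   planted = planted, isg_genes = isg_genes)))
}

# Plant gained (6h-only) and lost (0h-only) links between STAT1/2 sites and
# tiles at ISG gene promoters/bodies, so the regulation classifier has true
# distal-link categories to recover.
plant_demo_links <- function(layout, tss_table, isg_genes, sites, config,
                             seed) {
  with_seed(seed, {
    tiles <- layout$tiles
    pairs <- layout$pairs
    gi <- match(isg_genes, tss_table$gene)
    rows <- list()
    want <- config$n_planted_gained + config$n_planted_lost
    tssp <- tss_positions(tss_table)
    for (g in sample(seq_along(isg_genes))) {
      if (length(rows) >= want) break
      lo <- tss_table$start[gi[g]]; hi <- tss_table$end[gi[g]]
      ov <- tiles$chrom == tss_table$chrom[gi[g]] &
        tiles$start < hi & tiles$end > lo
      cand <- pairs[pairs$tile_id %in% tiles$id[ov], , drop = FALSE]
      if (nrow(cand) == 0L) next
      # prefer a distal partner site (outside this gene's promoter window)
      srow <- match(cand$site_id, sites$id)
      distal <- !(sites$chrom[srow] == tss_table$chrom[gi[g]] &
                    sites$start[srow] < tssp[gi[g]] + 1000 &
                    sites$end[srow] > tssp[gi[g]] - 1000)
      if (any(distal)) cand <- cand[distal, , drop = FALSE]
      pick <- cand[sample(nrow(cand), 1L), ]
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = pick$site_id, tile_id = pick$tile_id,
        effect = config$planted_effect,
        condition = if (length(rows) < config$n_planted_gained) "6h" else "0h",
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) return(NULL)
    unique(do.call(rbind, rows))
  })
}

# Demo ISG list: genes with a TSS near an overlap locus (promoter-bound
# ISGs) plus extras that have at least one candidate tile over their body
# (so distal links can reach them).
demo_isg_genes <- function(land, layout, config, seed) {
  with_seed(seed, {
    tt <- land$tss_table
    near <- land$truth$overlap_near_tss
    linkable <- vapply(seq_len(nrow(tt)), function(g) {
      ov <- layout$tiles$chrom == tt$chrom[g] &
        layout$tiles$start < tt$end[g] & layout$tiles$end > tt$start[g]
      any(ov)
    }, TRUE)
    others <- setdiff(tt$gene[linkable], near)
    far <- setdiff(tt$gene, c(near, others))
    n_extra <- min(length(others), max(4L, length(near)))
    extras <- if (n_extra > 0) sample(others, n_extra) else character(0)
    n_far <- min(length(far), 4L)
    sort(unique(c(near, extras,
                  if (n_far > 0) sample(far, n_far) else character(0))))
  })
}
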