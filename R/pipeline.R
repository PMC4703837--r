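#' Run the full synthetic-data analysis pipeline
#'
#' Generates every synthetic dataset, runs all analysis stages in
#' dependency order — peak classification (background model, relative
#' RPKM, MA normalization, change calls, consensus), gene-level labels,
#' enhancer-cluster catalog with seeding and composition, motif
#' activities, promoter methylation logic, and chromatin-state flows —
#' and collects a machine-readable summary. The run is a pure function
#' of (config, simconfig): identical seeds and configuration give a
#' byte-identical summary file.
#'
#' @param config A [pipeline_config()].
#' @param simconfig A [simulation_config()]; its seed defaults to
#'   `config$seed`.
#' @param output_dir Optional directory: writes `summary.json` plus
#'   per-stage TSV tables there.
#' @return The summary list, invisibly when writing, visibly otherwise.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         simconfig = simulation_config(seed = config$seed),
                         output_dir = NULL) {
  validate_config(config)
  seed <- simconfig$seed

  ann <- simulate_genome_annotation(simconfig, seed)

  # --- classification of the transcription-blockade experiment -------
  exp <- simulate_amanitin_experiment(simconfig, seed)
  cls <- classify_experiment(exp, config, mark = "H3K4me3")
  truth <- exp$truth
  tab <- merge(cls$table, truth, by = "peak_id", sort = TRUE)
  names(tab)[names(tab) == "label.x"] <- "label"
  names(tab)[names(tab) == "label.y"] <- "true_label"
  recall <- function(true_label, called) {
    n <- sum(tab$true_label == true_label)
    if (!n) return(NA_real_)
    sum(tab$true_label == true_label & tab$label == called) / n
  }
  classification <- list(
    n_peaks = nrow(tab),
    counts = as.list(table(tab$label)),
    mad_recall = recall("MaD", "MaD"),
    zyd_recall = recall("ZyD", "ZyD"),
    ambiguous_nd_rate = recall("ambiguous", "ND"),
    median_m_norm_common_rep1 = stats::median(
      tab$M_norm_rep1[tab$true_label == "MaD"]),
    normalization = cls$fits
  )

  # --- gene-level labels over simulated promoters --------------------
  # couple gene truth to the nearest classified peak per promoter
  gene_h3k4 <- classify_gene_h3k4me3(
    ann$tss, cbind(exp$peaks, label = cls$table$label),
    flank = config$promoter_h3k4me3)
  genes <- list(counts = as.list(table(gene_h3k4$label)))

  # --- enhancer clusters ---------------------------------------------
  p300 <- simulate_p300_stages(simconfig, seed)
  catalog <- build_catalog(p300$peaks, config$stitch_distance)
  final_stage <- p300$stages[length(p300$stages)]
  final <- catalog$per_stage[[final_stage]]
  ec_gr <- peaks_to_granges(final[final$is_ec, , drop = FALSE])
  truth_gr <- peaks_to_granges(p300$truth)
  found <- GenomicRanges::countOverlaps(truth_gr, ec_gr) > 0
  # MaD/ZyD labels for p300 peaks: cluster members ZyD, a random
  # minority of singleton peaks MaD (emulating the small maternal share
  # of p300 binding)
  last_peaks <- p300$peaks[p300$peaks$stage == final_stage, , drop = FALSE]
  last_peaks$label <- ifelse(is.na(last_peaks$cluster_id), "MaD", "ZyD")
  fr <- label_fraction_in_ecs(last_peaks, catalog)
  early_peaks <- p300$peaks[p300$peaks$stage == p300$stages[1], , drop = FALSE]
  early_peaks$label <- ifelse(is.na(early_peaks$cluster_id), "MaD", "ZyD")
  seeding <- seeding_analysis(catalog, early_peaks)
  comp <- ec_madzyd_composition(catalog, last_peaks)
  ng <- nearest_gene(catalog$total, ann$tss)
  enhancer_clusters <- list(
    n_total_regions = nrow(catalog$total),
    cluster_detection_rate = mean(found),
    stage_coverage = as.list(catalog$stage_coverage),
    zyd_fraction_in_ec = fr$fraction[fr$label == "ZyD"],
    mad_fraction_in_ec = fr$fraction[fr$label == "MaD"],
    zyd_enrichment_p = fr$p_over[fr$label == "ZyD"],
    seeded_fraction = mean(seeding$n_seeds > 0),
    median_zyd_composition = unname(comp$quartiles["ZyD", "q50"])
  )

  # --- motif activity -------------------------------------------------
  mo <- simulate_motif_dataset(simconfig, seed)
  lambda <- config$ridge_lambda
  if (is.na(lambda)) {
    lambda <- select_lambda(mo$N, mo$E, seed = seed)$lambda
  }
  model <- fit_activities(mo$N, mo$E, lambda)
  sig <- significant_motifs(model, config$z_threshold)
  act_idx <- rownames(mo$A_true) %in% mo$active
  r_active <- stats::cor(as.vector(model$A[act_idx, , drop = FALSE]),
                         as.vector(mo$A_true[act_idx, , drop = FALSE]))
  motif <- list(
    lambda = lambda,
    n_significant = nrow(sig),
    planted_recovered = setequal(sig$motif, mo$active),
    active_activity_correlation = r_active
  )

  # --- methylation logic ----------------------------------------------
  prom <- promoter_windows(ann$tss, 500L)
  meth_class <- ifelse(gene_h3k4$label == "MaD", "hypo",
                       ifelse(gene_h3k4$label == "ZyD", "hyper",
                              rep(c("hypo", "hyper"),
                                  length.out = nrow(gene_h3k4))))
  me <- simulate_methylome(simconfig, seed, promoters = prom,
                           meth_class = meth_class)
  pm <- promoter_methylation(me$cpg, prom)
  jt <- joint_table(gene_h3k4, pm,
                    hypo_cutoff = config$hypomethylation_level_cutoff)
  methylation <- list(
    joint_counts = as.list(as.data.frame(jt$counts)$Freq),
    mad_hypo = unname(jt$counts["MaD", "hypo"]),
    mad_hyper = unname(jt$counts["MaD", "hyper"]),
    zyd_hypo = unname(jt$counts["ZyD", "hypo"]),
    zyd_hyper = unname(jt$counts["ZyD", "hyper"])
  )

  # --- chromatin dynamics ---------------------------------------------
  st <- simulate_state_segmentations(simconfig, seed)
  lens <- stats::setNames(ann$scaffolds$length, ann$scaffolds$scaffold)
  # restrict grid to the simulated bin extent per scaffold
  per_scaf_bp <- tapply(st$bins$end, st$bins$scaffold, max)
  lens2 <- stats::setNames(as.numeric(per_scaf_bp), names(per_scaf_bp))
  sm <- state_matrix(st$segmentations, lens2, bin = config$state_bin_size,
                     states = simconfig$state_names)
  mask <- modified_genome_mask(sm$labels)
  covm <- coverage_per_stage(sm$labels, mask,
                             widths = sm$bins$end - sm$bins$start)
  fl <- transition_flows(sm$labels, mask,
                         widths = sm$bins$end - sm$bins$start)
  # conservation: per stage pair, outflow of each state equals coverage bp
  lw <- (sm$bins$end - sm$bins$start)[mask]
  total_bp <- sum(lw)
  out_ok <- TRUE
  for (j in seq_len(ncol(sm$labels) - 1)) {
    sub <- fl$flows[fl$flows$from_stage == colnames(sm$labels)[j], ]
    outflow <- tapply(sub$bp, sub$from, sum)
    covbp <- covm[names(outflow), j] * total_bp
    out_ok <- out_ok && all(abs(outflow - covbp) < 1e-6)
  }
  dynamics <- list(
    n_bins = nrow(sm$labels),
    modified_fraction = mean(mask),
    coverage_sums = unname(colSums(covm)),
    flow_conservation_ok = out_ok,
    total_flow_bp_per_pair = total_bp
  )

  summary <- list(
    seed = seed,
    config = unclass(config),
    classification = classification,
    genes = genes,
    enhancer_clusters = enhancer_clusters,
    motif = motif,
    methylation = methylation,
    dynamics = dynamics
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    utils::write.table(tab, file.path(output_dir, "peak_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gene_h3k4, file.path(output_dir, "gene_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fl$flows, file.path(output_dir, "state_flows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(summary))
  }
  summary
}
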