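#' Per-replicate change call for a peak
#'
#' Applies the published thresholds to one replicate pair. With M the
#' normalized log2 control/treated ratio and P the Audic-Claverie
#' p-value:
#' \itemize{
#'   \item lost: `M > m_cutoff`, `-log10(P)` above the mark's cutoff
#'     (5 for H3K27me3, 1.3 for H3K4me3 and p300), relative RPKM > 1 in
#'     stage-11 control (unless waived) and in the reference stage
#'     (10.5 for H3K4me3/p300, 12 for H3K27me3);
#'   \item increased: symmetric with `M < -m_cutoff` and stage-11
#'     treated relative RPKM > 1;
#'   \item unchanged: neither lost nor increased, relative RPKM > 1 in
#'     control, treated and reference;
#'   \item maintained: not lost, relative RPKM > 1 in control, treated
#'     and reference. Maintained and unchanged may co-hold; the four
#'     calls are returned as flags.
#' }
#'
#' @param m_norm Normalized M values.
#' @param neg_log10_p -log10 p-values.
#' @param rel_control,rel_treated,rel_reference Relative RPKM in
#'   stage-11 control, stage-11 alpha-amanitin and the mark's reference
#'   stage.
#' @param mark One of `"H3K4me3"`, `"H3K27me3"`, `"p300"`.
#' @param config A [pipeline_config()].
#' @param waive_control Skip the stage-11-control cutoff (the published
#'   analysis waives it for H3K27me3 replicate 1).
#' @return data.frame of logical flags `is_lost`, `is_increased`,
#'   `is_unchanged`, `is_maintained`.
#' @export
call_change <- function(m_norm, neg_log10_p, rel_control, rel_treated,
                        rel_reference, mark, config = pipeline_config(),
                        waive_control = FALSE) {
  if (!mark %in% names(config$neg_log10_p_cutoff)) {
    stop("unknown mark: ", mark)
  }
  for (nm in c("rel_control", "rel_treated", "rel_reference")) {
    v <- get(nm)
    if (is.null(v) || anyNA(v)) {
      stop("missing relative RPKM for required stage: ", nm)
    }
  }
  p_cut <- config$neg_log10_p_cutoff[[mark]]
  m_cut <- config$m_cutoff
  r_min <- config$rel_rpkm_min
  ctrl_ok <- waive_control | (rel_control > r_min)
  ref_ok <- rel_reference > r_min
  trt_ok <- rel_treated > r_min
  is_lost <- m_norm > m_cut & neg_log10_p > p_cut & ctrl_ok & ref_ok
  is_increased <- m_norm < -m_cut & neg_log10_p > p_cut & trt_ok & ref_ok
  is_unchanged <- !is_lost & !is_increased & ctrl_ok & trt_ok & ref_ok
  is_maintained <- !is_lost & ctrl_ok & trt_ok & ref_ok
  data.frame(is_lost = is_lost, is_increased = is_increased,
             is_unchanged = is_unchanged, is_maintained = is_maintained)
}

#' Cross-replicate consensus label
#'
#' MaD: the peak is present at or before stage 11 and maintained in
#' alpha-amanitin embryos in both replicates. ZyD: present at or before
#' stage 11 and lost in both replicates, or first appearing after
#' stage 11. Everything else (replicate-inconsistent or
#' threshold-failing) is ND.
#'
#' @param rep1,rep2 [call_change()] flag data.frames.
#' @param first_stage Earliest stage whose peak set contains the peak
#'   (stage label, `NA` if never confidently detected).
#' @return Character vector of `"MaD"`, `"ZyD"`, `"ND"`.
#' @export
consensus <- function(rep1, rep2, first_stage) {
  n <- nrow(rep1)
  stopifnot(nrow(rep2) == n, length(first_stage) == n)
  idx <- rep(NA_integer_, n)
  known <- !is.na(first_stage)
  if (any(known)) idx[known] <- stage_index(first_stage[known])
  st11 <- stage_index("11")
  early <- known & idx <= st11
  late <- known & idx > st11
  mad <- early & rep1$is_maintained & rep2$is_maintained
  zyd <- (early & rep1$is_lost & rep2$is_lost) | late
  ifelse(mad, "MaD", ifelse(zyd, "ZyD", "ND"))
}

#' End-to-end peak classification from a count experiment
#'
#' Runs the whole classification path on a counts object shaped like
#' [simulate_amanitin_experiment()] output: background model and
#' relative RPKM per sample, MA normalization and count p-values per
#' replicate (control vs alpha-amanitin), per-replicate change calls and
#' the cross-replicate consensus. Common (normalization) peaks are those
#' with relative RPKM > 1 in both samples of a replicate pair, standing
#' in for regions with called peaks in both samples.
#'
#' @param experiment List with `peaks`, `background`, `library_size` as
#'   returned by [simulate_amanitin_experiment()], or equivalent real
#'   data.
#' @param config A [pipeline_config()].
#' @param mark Mark whose thresholds apply (default `"H3K4me3"`).
#' @return List with `table` (peak_id, label, per-replicate flags,
#'   M/p/rel-RPKM columns), `fits` (per-replicate normalization),
#'   `background` (background model).
#' @export
classify_experiment <- function(experiment, config = pipeline_config(),
                                mark = "H3K4me3") {
  pk <- experiment$peaks
  samples <- c("ctrl_rep1", "ctrl_rep2", "aman_rep1", "aman_rep2", "ref")
  widths_bg <- experiment$background$end - experiment$background$start
  bg <- background_model(experiment$background[samples],
                         widths_bg, experiment$library_size,
                         config$background_percentile)
  widths <- pk$end - pk$start
  rel <- sapply(samples, function(s) {
    relative_rpkm(compute_rpkm(pk[[s]], widths, experiment$library_size),
                  bg$p95[[s]])
  })
  colnames(rel) <- paste0("rel_", samples)

  out <- data.frame(peak_id = pk$peak_id, stringsAsFactors = FALSE)
  out <- cbind(out, rel)
  fits <- list()
  calls <- list()
  waiver <- config$control_cutoff_waiver[[mark]]
  for (r in 1:2) {
    ctrl <- paste0("ctrl_rep", r); aman <- paste0("aman_rep", r)
    common <- rel[, paste0("rel_", ctrl)] > 1 & rel[, paste0("rel_", aman)] > 1
    mn <- run_manorm(pk[[ctrl]], pk[[aman]], common,
                     pseudocount = config$pseudocount, peak_id = pk$peak_id)
    fits[[paste0("rep", r)]] <- mn$fit
    out[[paste0("M_norm_rep", r)]] <- mn$table$M_norm
    out[[paste0("neg_log10_p_rep", r)]] <- mn$table$neg_log10_p
    calls[[r]] <- call_change(
      mn$table$M_norm, mn$table$neg_log10_p,
      rel_control = rel[, paste0("rel_", ctrl)],
      rel_treated = rel[, paste0("rel_", aman)],
      rel_reference = rel[, "rel_ref"],
      mark = mark, config = config,
      waive_control = identical(waiver, paste0("rep", r))
    )
    names(calls[[r]]) <- paste0(names(calls[[r]]), "_rep", r)
    out <- cbind(out, calls[[r]])
  }
  out$label <- consensus(
    stats::setNames(calls[[1]], sub("_rep1$", "", names(calls[[1]]))),
    stats::setNames(calls[[2]], sub("_rep2$", "", names(calls[[2]]))),
    pk$first_stage
  )
  list(table = out, fits = fits, background = bg)
}

#' Gene-level H3K4me3 classification
#'
#' The gene inherits the consensus label of peaks overlapping its
#' promoter window (strand-symmetric, +/-250 bp from the TSS by
#' default): maintained-in-both promoter peaks give MaD,
#' lost-in-both or post-stage-11 peaks give ZyD, conflicting MaD and ZyD
#' promoter labels give ND, no promoter peak gives "unmarked".
#'
#' @param tss TSS data.frame.
#' @param peaks Peak data.frame with a `label` column (consensus).
#' @param flank Promoter half-width in bp (default 250).
#' @return data.frame (gene_id, label, n_promoter_peaks).
#' @export
classify_gene_h3k4me3 <- function(tss, peaks, flank = 250L) {
  classify_gene_by_window(tss, peaks, flank, dominant = "conflict_nd")
}

#' Gene-level H3K27me3 classification
#'
#' MaD: at least one MaD peak within +/-2.5 kb of the TSS. ZyD: at
#' least one ZyD peak and no MaD peak in the window. Any other peak
#' configuration gives ND; genes without peaks are "unmarked".
#'
#' @inheritParams classify_gene_h3k4me3
#' @param flank Window half-width in bp (default 2500).
#' @return data.frame (gene_id, label, n_promoter_peaks).
#' @export
classify_gene_h3k27me3 <- function(tss, peaks, flank = 2500L) {
  classify_gene_by_window(tss, peaks, flank, dominant = "mad_dominates")
}

classify_gene_by_window <- function(tss, peaks, flank, dominant) {
  win <- promoter_windows(tss, flank)
  n_pk <- integer(nrow(tss))
  lab <- rep("unmarked", nrow(tss))
  if (nrow(peaks)) {
    hits <- GenomicRanges::findOverlaps(peaks_to_granges(win),
                                        peaks_to_granges(peaks))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    for (g in unique(q)) {
      ls <- peaks$label[s[q == g]]
      n_pk[g] <- length(ls)
      has_mad <- any(ls == "MaD"); has_zyd <- any(ls == "ZyD")
      lab[g] <- if (dominant == "mad_dominates") {
        if (has_mad) "MaD" else if (has_zyd) "ZyD" else "ND"
      } else {
        if (has_mad && has_zyd) "ND"
        else if (has_mad) "MaD"
        else if (has_zyd) "ZyD"
        else "ND"
      }
    }
  }
  data.frame(gene_id = tss$gene_id, label = lab, n_promoter_peaks = n_pk,
             stringsAsFactors = FALSE)
}

#' GREAT-style basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-aware basal domain (5 kb upstream, 1 kb
#' downstream of the TSS by default) extended in both directions to the
#' nearest neighbouring gene's basal domain, capped at `max_extension`
#' from the TSS and clipped to the scaffold.
#'
#' @param tss TSS data.frame (gene_id, scaffold, tss, strand).
#' @param scaffold_lengths Named vector of scaffold lengths.
#' @param basal_up,basal_down Basal extent up/downstream of the TSS (bp).
#' @param max_extension Maximum extension from the TSS (bp).
#' @return data.frame (gene_id, scaffold, basal_start, basal_end,
#'   start, end) with 0-based half-open coordinates.
#' @export
great_regions <- function(tss, scaffold_lengths, basal_up = 5000L,
                          basal_down = 1000L, max_extension = 1000000L) {
  if (anyDuplicated(tss$gene_id)) stop("duplicate gene ids in TSS table")
  plus <- tss$strand == "+"
  basal_start <- ifelse(plus, tss$tss - basal_up, tss$tss - basal_down)
  basal_end <- ifelse(plus, tss$tss + basal_down, tss$tss + basal_up)
  lim <- unname(scaffold_lengths[tss$scaffold])
  basal_start <- pmax(0, basal_start)
  basal_end <- pmin(lim, basal_end)
  n <- nrow(tss)
  ext_start <- numeric(n); ext_end <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(tss$scaffold == tss$scaffold[i])
    others <- setdiff(same, i)
    left_nb <- others[basal_end[others] <= basal_start[i]]
    right_nb <- others[basal_start[others] >= basal_end[i]]
    lo <- max(tss$tss[i] - max_extension, 0,
              if (length(left_nb)) max(basal_end[left_nb]) else -Inf)
    hi <- min(tss$tss[i] + max_extension, lim[i],
              if (length(right_nb)) min(basal_start[right_nb]) else Inf)
    ext_start[i] <- min(lo, basal_start[i])
    ext_end[i] <- max(hi, basal_end[i])
  }
  data.frame(gene_id = tss$gene_id, scaffold = tss$scaffold,
             basal_start = as.integer(basal_start),
             basal_end = as.integer(basal_end),
             start = as.integer(ext_start), end = as.integer(ext_end),
             stringsAsFactors = FALSE)
}

#' Count labelled peaks in regulatory domains
#'
#' Per-gene tallies of MaD/ZyD/ND peaks overlapping (>= 1 bp) the
#' gene's regulatory domain; a peak overlapping several domains counts
#' for each.
#'
#' @param domains [great_regions()] output.
#' @param peaks Peak data.frame with `label`.
#' @return data.frame (gene_id, n_MaD, n_ZyD, n_ND).
#' @export
count_peaks_in_domains <- function(domains, peaks) {
  out <- data.frame(gene_id = domains$gene_id, n_MaD = 0L, n_ZyD = 0L,
                    n_ND = 0L, stringsAsFactors = FALSE)
  if (!nrow(peaks)) return(out)
  hits <- GenomicRanges::findOverlaps(
    peaks_to_granges(domains[c("scaffold", "start", "end")]),
    peaks_to_granges(peaks))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  for (lb in c("MaD", "ZyD", "ND")) {
    cnt <- table(q[peaks$label[s] == lb])
    col <- paste0("n_", lb)
    out[[col]][as.integer(names(cnt))] <- as.integer(cnt)
  }
  out
}

#' Group strictly embryonic genes by stage of maximum expression
#'
#' Genes without detectable maternal mRNA (all maternal/pre-MBT columns
#' below `maternal_threshold`) are assigned to the developmental group
#' (blastula, gastrula, neurula, tailbud) containing their expression
#' maximum; ties go to the earlier stage. All-zero genes are excluded.
#'
#' @param expression Numeric matrix, genes x stages, with rownames =
#'   gene ids.
#' @param maternal_columns Column names measuring oocyte/pre-MBT
#'   expression.
#' @param stage_groups Named character vector mapping each embryonic
#'   column to its group.
#' @param maternal_threshold Maternal expression below which a gene
#'   counts as "not maternal" (default 1).
#' @return data.frame (gene_id, group) for eligible genes.
#' @export
group_genes_by_expression <- function(expression, maternal_columns,
                                      stage_groups,
                                      maternal_threshold = 1) {
  stopifnot(all(maternal_columns %in% colnames(expression)),
            all(names(stage_groups) %in% colnames(expression)))
  emb <- expression[, names(stage_groups), drop = FALSE]
  maternal <- expression[, maternal_columns, drop = FALSE]
  eligible <- apply(maternal, 1, max) < maternal_threshold
  nonzero <- apply(emb, 1, max) > 0
  keep <- which(eligible & nonzero)
  if (any(eligible & !nonzero)) {
    message("group_genes_by_expression: excluded ",
            sum(eligible & !nonzero), " all-zero gene(s)")
  }
  peak_col <- apply(emb[keep, , drop = FALSE], 1, which.max)  # first max = earlier stage
  data.frame(gene_id = rownames(expression)[keep],
             group = unname(stage_groups[peak_col]),
             stringsAsFactors = FALSE)
}

#' Summary of a gene set's MaD/ZyD composition
#'
#' @param gene_set Character vector of gene ids.
#' @param gene_labels data.frame (gene_id, label).
#' @param domain_counts Optional [count_peaks_in_domains()] output.
#' @param signal Optional named numeric vector (per-gene signal, e.g.
#'   H3K27me3 relative RPKM).
#' @return List with `counts` (label tally) and `medians` (median
#'   domain counts / signal over the set).
#' @export
summarize_gene_set <- function(gene_set, gene_labels,
                               domain_counts = NULL, signal = NULL) {
  known <- gene_set %in% gene_labels$gene_id
  if (any(!known)) {
    warning("skipping ", sum(!known), " unknown gene id(s)")
    gene_set <- gene_set[known]
  }
  if (!length(gene_set)) {
    return(list(counts = integer(0), medians = list()))
  }
  lab <- gene_labels$label[match(gene_set, gene_labels$gene_id)]
  counts <- table(factor(lab, levels = c("MaD", "ZyD", "ND", "unmarked")))
  medians <- list()
  if (!is.null(domain_counts)) {
    dc <- domain_counts[match(gene_set, domain_counts$gene_id), , drop = FALSE]
    medians$n_MaD <- stats::median(dc$n_MaD, na.rm = TRUE)
    medians$n_ZyD <- stats::median(dc$n_ZyD, na.rm = TRUE)
  }
  if (!is.null(signal)) {
    medians$signal <- stats::median(signal[gene_set], na.rm = TRUE)
  }
  list(counts = counts, medians = medians)
}
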