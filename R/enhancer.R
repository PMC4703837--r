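#' Stitch peaks into candidate enhancer clusters
#'
#' Maximal chains of peaks whose consecutive gaps are at most
#' `stitch_distance` (12.5 kb by default, the super-enhancer stitching
#' convention) are merged; singleton peaks form their own region. The
#' region signal is the sum of member signal x width (background-
#' corrected RPKM weighted by peak length).
#'
#' @param peaks Peak data.frame with `scaffold`, `start`, `end` and a
#'   `signal` column; any order (stitching is order-independent).
#' @param stitch_distance Maximum inter-peak gap in bp (gap equal to the
#'   distance is still stitched).
#' @return data.frame (region_id, scaffold, start, end, n_members,
#'   member_ids, signal) sorted by coordinate.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500L) {
  if (!nrow(peaks)) {
    return(data.frame(region_id = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), member_ids = character(),
                      signal = numeric(), stringsAsFactors = FALSE))
  }
  peaks <- peaks[order(peaks$scaffold, peaks$start, peaks$end), , drop = FALSE]
  gr <- peaks_to_granges(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  w <- peaks$end - peaks$start
  sig <- if (is.null(peaks$signal)) rep(1, nrow(peaks)) else peaks$signal
  ids <- if (is.null(peaks$peak_id)) as.character(seq_len(nrow(peaks))) else peaks$peak_id
  out <- granges_to_peaks(red)
  out$region_id <- sprintf("region_%05d", seq_len(nrow(out)))
  out$n_members <- lengths(revmap)
  out$member_ids <- vapply(revmap, function(i) paste(ids[i], collapse = ","), "")
  out$signal <- vapply(revmap, function(i) sum(sig[i] * w[i]), numeric(1))
  out[c("region_id", "scaffold", "start", "end", "n_members",
        "member_ids", "signal")]
}

#' Ranked-signal elbow cutoff
#'
#' Regions are ranked by ascending signal with both axes scaled to
#' [0, 1]; the cutoff sits where the tangent slope of the profile
#' equals 1, located as the rank maximizing `x - y` — the point where a
#' slope-1 line is tangent to the profile from below, which coincides
#' with the discrete slope-1 crossing on convex profiles but is robust
#' to local slope fluctuations in the steep tail. Regions above the
#' cutoff are enhancer clusters. Ties go to the highest rank (most
#' stringent cutoff); an all-equal or exactly linear profile is
#' degenerate and flags no region.
#'
#' @param signals Numeric signals (>= 3 values), any order.
#' @return List with `threshold` (signal value at the cutoff), `is_ec`
#'   (logical flags aligned to `signals`), `cutoff_rank_scaled` (scaled
#'   rank in [0,1], `NA` when degenerate).
#' @export
elbow_cutoff <- function(signals) {
  n <- length(signals)
  if (n < 3) stop("need at least 3 regions for the elbow cutoff")
  s <- sort(signals)
  if (s[n] == s[1]) {
    warning("all signals equal: no enhancer clusters called")
    return(list(threshold = Inf, is_ec = rep(FALSE, n),
                cutoff_rank_scaled = NA_real_))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  gap <- x - y
  if (max(gap) <= 1e-9) {
    # profile never drops below the diagonal: linear or concave, no elbow
    return(list(threshold = Inf, is_ec = rep(FALSE, n),
                cutoff_rank_scaled = NA_real_))
  }
  ci <- max(which(gap == max(gap)))
  threshold <- s[ci]
  list(threshold = threshold, is_ec = signals > threshold,
       cutoff_rank_scaled = x[ci])
}

#' Per-stage enhancer-cluster catalog
#'
#' Stitches and elbow-calls enhancer clusters per developmental stage,
#' merges the per-stage calls into the total EC region, and measures
#' each stage's coverage of the total region.
#'
#' @param per_stage_peaks data.frame with `stage`, `scaffold`, `start`,
#'   `end`, `signal` (and optionally `peak_id`).
#' @param stitch_distance Stitching gap in bp (default 12500).
#' @return List with `per_stage` (stitched regions + `is_ec` per stage),
#'   `total` (merged total EC regions with `ec_id`), `stage_coverage`
#'   (named fraction of total-region bp covered per stage),
#'   `ec_stage_coverage` (EC x stage coverage-fraction matrix).
#' @export
build_catalog <- function(per_stage_peaks, stitch_distance = 12500L) {
  stages <- unique(per_stage_peaks$stage)
  if (!length(stages)) stop("need at least one stage")
  per_stage <- lapply(stages, function(st) {
    pk <- per_stage_peaks[per_stage_peaks$stage == st, , drop = FALSE]
    reg <- stitch_peaks(pk, stitch_distance)
    if (nrow(reg) >= 3) {
      ec <- elbow_cutoff(reg$signal)
      reg$is_ec <- ec$is_ec
    } else {
      reg$is_ec <- rep(FALSE, nrow(reg))
    }
    reg
  })
  names(per_stage) <- stages
  ec_beds <- lapply(per_stage, function(r) r[r$is_ec, c("scaffold", "start", "end")])
  total <- merge_peak_sets(ec_beds)
  if (nrow(total)) total$ec_id <- sprintf("EC_%04d", seq_len(nrow(total)))
  total_bp <- sum(total$end - total$start)
  cover <- function(stage_ecs) {
    if (!nrow(stage_ecs) || !nrow(total)) return(list(global = 0, per_ec = numeric(nrow(total))))
    sg <- peaks_to_granges(stage_ecs)
    tg <- peaks_to_granges(total)
    hits <- GenomicRanges::findOverlaps(tg, sg)
    per_ec <- numeric(nrow(total))
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(tg)[S4Vectors::queryHits(hits)],
        IRanges::ranges(sg)[S4Vectors::subjectHits(hits)]))
      bp <- tapply(ov, S4Vectors::queryHits(hits), sum)
      per_ec[as.integer(names(bp))] <- as.numeric(bp)
    }
    list(global = sum(per_ec) / total_bp,
         per_ec = per_ec / (total$end - total$start))
  }
  covs <- lapply(ec_beds, cover)
  stage_coverage <- vapply(covs, `[[`, numeric(1), "global")
  ec_stage <- do.call(cbind, lapply(covs, `[[`, "per_ec"))
  if (nrow(total)) rownames(ec_stage) <- total$ec_id
  list(per_stage = per_stage, total = total,
       stage_coverage = stage_coverage, ec_stage_coverage = ec_stage,
       stages = stages)
}

#' Seeding peaks of enhancer clusters
#'
#' The seeding peaks of an EC are the earliest-stage peaks overlapping
#' its total region; the EC is classified by their consensus labels
#' (MaD seed present / ZyD seeds only / unseeded at that stage).
#'
#' @param catalog A [build_catalog()] result.
#' @param earliest_peaks Earliest-stage peak data.frame with a `label`
#'   column.
#' @return data.frame (ec_id, n_seeds, seed_class).
#' @export
seeding_analysis <- function(catalog, earliest_peaks) {
  total <- catalog$total
  out <- data.frame(ec_id = total$ec_id, n_seeds = 0L,
                    seed_class = "unseeded", stringsAsFactors = FALSE)
  if (!nrow(total) || !nrow(earliest_peaks)) return(out)
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(total),
                                      peaks_to_granges(earliest_peaks))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  for (i in unique(q)) {
    ls <- earliest_peaks$label[s[q == i]]
    out$n_seeds[i] <- length(ls)
    out$seed_class[i] <- if (any(ls == "MaD")) "MaD"
      else if (any(ls == "ZyD")) "ZyD" else "other"
  }
  out
}

#' Fraction of labelled peaks mapping to enhancer clusters
#'
#' For each consensus label, the fraction of peaks overlapping the total
#' EC region, with cumulative hypergeometric p-values for over- and
#' under-representation relative to all labelled peaks.
#'
#' @param peaks Peak data.frame with `label`.
#' @param catalog A [build_catalog()] result.
#' @param labels Labels to report (default MaD and ZyD).
#' @return data.frame (label, n, n_in_ec, fraction, p_over, p_under).
#' @export
label_fraction_in_ecs <- function(peaks, catalog,
                                  labels = c("MaD", "ZyD")) {
  in_ec <- rep(FALSE, nrow(peaks))
  if (nrow(catalog$total) && nrow(peaks)) {
    hits <- GenomicRanges::findOverlaps(peaks_to_granges(peaks),
                                        peaks_to_granges(catalog$total))
    in_ec[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  N <- nrow(peaks)
  K <- sum(in_ec)
  out <- lapply(labels, function(lb) {
    sel <- peaks$label == lb
    n <- sum(sel); k <- sum(sel & in_ec)
    if (n == 0) {
      return(data.frame(label = lb, n = 0L, n_in_ec = 0L,
                        fraction = NA_real_, p_over = NA_real_,
                        p_under = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(
      label = lb, n = n, n_in_ec = k, fraction = k / n,
      p_over = hypergeom_tail(k, K, N, n, upper = TRUE),
      p_under = hypergeom_tail(k, K, N, n, upper = FALSE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Cumulative hypergeometric tail probability
#'
#' Probability of drawing at least (`upper = TRUE`) or at most `k`
#' successes in `n` draws from a population of size `N` containing `K`
#' successes, computed exactly in log space.
#'
#' @param k Observed successes.
#' @param K Successes in the population.
#' @param N Population size.
#' @param n Draws.
#' @param upper Upper (over-representation) or lower tail.
#' @return Tail probability.
#' @export
hypergeom_tail <- function(k, K, N, n, upper = TRUE) {
  if (upper) {
    if (k == 0) return(1)
    exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  } else {
    exp(stats::phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
  }
}

#' MaD/ZyD base-pair composition of each enhancer cluster
#'
#' Per EC, the fraction of its region covered by peaks of each label
#' (union coverage — overlapping peaks are not double-counted), with
#' box-plot summary statistics of the distributions.
#'
#' @param catalog A [build_catalog()] result.
#' @param peaks Peak data.frame with `label`.
#' @return List with `per_ec` (ec_id, frac_MaD, frac_ZyD) and
#'   `quartiles` (rows MaD/ZyD, columns q25/q50/q75).
#' @export
ec_madzyd_composition <- function(catalog, peaks) {
  total <- catalog$total
  res <- data.frame(ec_id = total$ec_id, frac_MaD = 0, frac_ZyD = 0,
                    stringsAsFactors = FALSE)
  tg <- peaks_to_granges(total)
  for (lb in c("MaD", "ZyD")) {
    sub <- peaks[peaks$label == lb, , drop = FALSE]
    if (!nrow(sub) || !nrow(total)) next
    sg <- GenomicRanges::reduce(peaks_to_granges(sub))
    hits <- GenomicRanges::findOverlaps(tg, sg)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(tg)[S4Vectors::queryHits(hits)],
      IRanges::ranges(sg)[S4Vectors::subjectHits(hits)]))
    bp <- tapply(ov, S4Vectors::queryHits(hits), sum)
    res[[paste0("frac_", lb)]][as.integer(names(bp))] <-
      as.numeric(bp) / (total$end - total$start)[as.integer(names(bp))]
  }
  q <- t(vapply(c("MaD", "ZyD"), function(lb) {
    stats::quantile(res[[paste0("frac_", lb)]], c(0.25, 0.5, 0.75))
  }, numeric(3)))
  colnames(q) <- c("q25", "q50", "q75")
  list(per_ec = res, quartiles = q)
}

#' Nearest gene to each enhancer cluster
#'
#' Distance from the EC boundary to the TSS (0 when the TSS lies inside
#' the EC); ties report all equidistant genes, comma-separated.
#'
#' @param ecs data.frame of EC regions (scaffold, start, end, ec_id).
#' @param tss TSS data.frame.
#' @return data.frame (ec_id, gene_id, distance); `gene_id` is `NA`
#'   when the EC's scaffold has no TSS.
#' @export
nearest_gene <- function(ecs, tss) {
  out <- data.frame(ec_id = ecs$ec_id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ecs))) {
    cand <- tss[tss$scaffold == ecs$scaffold[i], , drop = FALSE]
    if (!nrow(cand)) next
    d <- pmax(0, pmax(ecs$start[i] - cand$tss, cand$tss - (ecs$end[i] - 1L)))
    dmin <- min(d)
    out$gene_id[i] <- paste(cand$gene_id[d == dmin], collapse = ",")
    out$distance[i] <- dmin
  }
  out
}
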